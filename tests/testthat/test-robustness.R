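test_that("Latin hypercube perturbation respects range, strata and seed", {
  centre <- c(a = 100, b = 0.5, c = -2)
  s <- lhs_perturb(centre, fraction = 0.1, n = 10, seed = 3)
  expect_equal(dim(s), c(10L, 3L))
  for (j in 1:3) {
    lo <- centre[j] * 0.9; hi <- centre[j] * 1.1
    rng <- range(c(lo, hi))
    expect_true(all(s[, j] >= rng[1] & s[, j] <= rng[2]))
    # each coordinate's samples occupy 10 distinct equal-width strata
    strata <- floor(10 * (s[, j] - min(c(lo, hi))) / abs(hi - lo))
    strata[strata == 10] <- 9
    expect_equal(sort(unique(strata)), 0:9)
  }
  expect_identical(s, lhs_perturb(centre, 0.1, 10, seed = 3))
})

test_that("relative differences compute exact percentages symmetrically", {
  expect_equal(relative_differences(100, 100), 0)
  expect_equal(relative_differences(119, 115), 100 * 4 / 119)
  expect_equal(relative_differences(c(10, 10), c(11, 9)),
               c(10, 10))  # sign-symmetric
  expect_error(relative_differences(0, 1), "0")
})

test_that("summary statistics reproduce the published cohort pairs", {
  # step-1 peak-pressure column of the packaged cohort table
  d <- cohort_fit_reldiffs()
  pmax1 <- d$rel_diff_pct[d$step == 1 & d$biomarker == "Pmax"]
  s <- summarise_rel_diffs(pmax1)
  expect_equal(round(s$mean, 1), 5.4)
  expect_equal(round(s$sd, 1), 3.4)
  expect_equal(s$n, 7L)
  # single value degenerates to itself with zero spread
  s1 <- summarise_rel_diffs(42)
  expect_equal(s1$mean, 42); expect_equal(s1$sd, 0)
  expect_error(summarise_rel_diffs(numeric(0)), "empty")
})

test_that("summary matches an independent two-pass oracle on arbitrary input", {
  set.seed(99)
  for (rep in 1:5) {
    x <- runif(sample(2:30, 1), 0, 50)
    s <- summarise_rel_diffs(x)
    # brute-force two-pass: mean first, then squared deviations
    m <- sum(x) / length(x)
    sd2 <- sqrt(sum((x - m)^2) / length(x))
    expect_equal(s$mean, m)
    expect_equal(s$sd, sd2)
    expect_equal(s$min, min(x)); expect_equal(s$max, max(x))
    # permutation invariance
    s2 <- summarise_rel_diffs(sample(x))
    expect_equal(unlist(s2), unlist(s))
  }
})

test_that("zero input noise reproduces the reference personalisation", {
  syn <- synthetic_clinical_data(noise_frac = 0, seed = 4)
  st <- run_uncertainty_study(syn$biomarkers, fraction = 1e-9, n = 2,
                              seed = 5)
  for (q in st$summaries$step1_params)
    expect_lt(q$mean, 1e-4)
  expect_equal(st$n_failed, 0L)
})

test_that("clinical-data uncertainty propagates without amplification blow-up", {
  syn <- synthetic_clinical_data(noise_frac = 0, seed = 4)
  st <- run_uncertainty_study(syn$biomarkers, fraction = 0.1, n = 4,
                              seed = 6)
  expect_equal(st$n_failed, 0L)
  # simulated biomarkers after recalibration stay within ~2x the input band
  m <- vapply(st$summaries$step1_biomarkers, `[[`, numeric(1), "mean")
  expect_lt(max(m), 20)
})

test_that("initial-guess variation reconverges to the same biomarkers", {
  syn <- synthetic_clinical_data(noise_frac = 0, seed = 4)
  st <- run_initial_guess_study(syn$biomarkers, fraction = 0.5, n = 3,
                                seed = 7)
  expect_equal(st$n_failed, 0L)
  # final biomarkers agree across initial guesses within the band implied
  # by the 0.1 convergence threshold (relative residuals ~ sqrt(0.1/6))
  m <- vapply(st$summaries$step1_biomarkers, `[[`, numeric(1), "mean")
  expect_lt(max(m), 100 * sqrt(0.1))
})

test_that("robustness tables export in the published layout", {
  syn <- synthetic_clinical_data(noise_frac = 0, seed = 4)
  st <- run_uncertainty_study(syn$biomarkers, fraction = 0.05, n = 2,
                              seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_robustness_csv(st, "step1_params", path)
  d <- utils::read.csv(path)
  expect_equal(d$statistic, c("original", "mean", "sd", "min", "max"))
  expect_true(all(c("Smax_ref", "Smax_ref_reldiff_pct") %in% names(d)))
})
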