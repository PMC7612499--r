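test_that("pressure biomarkers match analytic values on a triangular pulse", {
  p <- triangle_trace(peak = 100, t_peak = 100, t_end = 200, dt = 1)
  bm <- pressure_biomarkers(p, t_act = 0)
  expect_equal(bm$Pmax, 100)
  # linear decay from 100 at t=100 to 0 at t=200 crosses 10 at t=190
  expect_equal(bm$PTD90, 190, tolerance = 1e-9)
  expect_equal(bm$dPdt_max, 1)   # slope of the rise
  expect_equal(bm$dPdt_min, -1)  # slope of the decay (post-peak)
  # amplitude scaling: Pmax doubles, PTD90 unchanged
  bm2 <- pressure_biomarkers(trace(2 * p$values, dt = 1), t_act = 0)
  expect_equal(bm2$Pmax, 200)
  expect_equal(bm2$PTD90, bm$PTD90, tolerance = 1e-9)
  # never decaying -> biomarker-undefined error
  expect_error(pressure_biomarkers(trace(seq(0, 10, by = 1), dt = 1)),
               "never decays")
})

test_that("biomarker extrema agree with an exhaustive sample-scan oracle", {
  syn <- synthetic_clinical_data(seed = 9)
  p <- syn$P
  dp <- diff(p$values) / p$dt  # brute-force forward differences
  bm <- pressure_biomarkers(p, t_act = 0)
  expect_equal(bm$Pmax, max(p$values))
  # central-difference extrema bracketed by forward-difference scan
  expect_lt(abs(bm$dPdt_max - max(dp)), 0.2 * abs(max(dp)))
  i_pk <- which.max(p$values)
  expect_lt(abs(bm$dPdt_min - min(dp[i_pk:length(dp)])),
            0.2 * abs(min(dp[i_pk:length(dp)])))
})

test_that("volume biomarkers: coverage time equals tau for exact exponential", {
  tau <- 80
  tt <- seq(0, 400, by = 1)
  v <- trace(c(150 * exp(-tt / tau), rev(150 * exp(-tt / tau))), dt = 1)
  bm <- volume_biomarkers(v, c(0, 400), c(401, 801))
  expect_equal(bm$tauVD, tau, tolerance = 1.5 / tau)  # within ~a sample
  expect_equal(bm$SV, max(v$values) - min(v$values))
  expect_error(volume_biomarkers(trace(rep(5, 10), dt = 1), c(0, 9), c(0, 9)),
               "no volume change")
})

test_that("stroke volume is max minus min", {
  v <- trace(c(seq(150, 50, by = -10), seq(50, 150, by = 10)), dt = 10)
  bm <- volume_biomarkers(v, c(0, 100), c(100, 210))
  expect_equal(bm$SV, 100)
})

test_that("stress biomarkers: linear interpolation and scale invariance", {
  # rise 0 -> 10 kPa over 100 ms, fall to 0 over 300 ms
  sa <- triangle_trace(peak = 10, t_peak = 100, t_end = 400, dt = 1)
  bm <- stress_biomarkers(sa, t_act = 0)
  expect_equal(bm$Sa_max, 10)
  expect_equal(bm$STD50, 250, tolerance = 1e-9)  # midpoint of linear decay
  expect_true(bm$STD30 < bm$STD50 && bm$STD50 < bm$STD90)
  bm3 <- stress_biomarkers(trace(3 * sa$values, dt = 1), t_act = 0)
  expect_equal(bm3$Sa_max, 30)
  expect_equal(bm3$dSadt_max, 3 * bm$dSadt_max)
  expect_equal(c(bm3$STD30, bm3$STD50, bm3$STD90),
               c(bm$STD30, bm$STD50, bm$STD90), tolerance = 1e-9)
})

test_that("Tanh-model STD90 matches a root-finding oracle on the closed form", {
  p <- tanh_params(Smax_ref = 60, tauSR_ref = 40, tauSD = 60, tCR = 400)
  tt <- seq(0, 600, by = 0.1)
  sa <- trace(tanh_active_stress(tt, p), dt = 0.1)
  bm <- stress_biomarkers(sa, t_act = 0)
  f <- function(t) tanh_active_stress(t, p) - (1 - 0.9) * bm$Sa_max
  t_pk <- tt[which.max(sa$values)]
  oracle <- uniroot(f, c(t_pk, 400), tol = 1e-8)$root
  expect_equal(bm$STD90, oracle, tolerance = 1e-3)
})

test_that("calcium durations: piecewise-linear transient and degenerate input", {
  tt <- seq(0, 500, by = 1)
  ca <- trace(ifelse(tt <= 50, 0.1 + 0.9 * tt / 50,
                     1.0 - 0.9 * (tt - 50) / 450), dt = 1)
  bm <- calcium_durations(ca, t_act = 0)
  expect_equal(bm$CTD50, 275, tolerance = 1e-9)
  expect_true(bm$CTD50 < bm$CTD90)
  expect_error(calcium_durations(trace(rep(0.1, 10), dt = 1)), "no transient")
})

test_that("duration biomarkers are time-shift equivariant", {
  sa <- triangle_trace(peak = 10, t_peak = 100, t_end = 400, dt = 1)
  bm0 <- stress_biomarkers(sa, t_act = 0)
  shifted <- trace(sa$values, dt = 1, t0 = 37)
  bm1 <- stress_biomarkers(shifted, t_act = 37)
  expect_equal(bm1$STD50, bm0$STD50, tolerance = 1e-9)
  expect_equal(bm1$STD90, bm0$STD90, tolerance = 1e-9)
})

test_that("relative least-squares cost: exact values and error cases", {
  expect_equal(relative_least_squares_cost(c(a = 100), c(a = 100)), 0)
  expect_equal(relative_least_squares_cost(c(a = 100), c(a = 110)), 0.01)
  # five terms each off by 10% at the cell-scale weights -> 0.13
  tgt <- c(Sa_max = 50, dSadt_max = 1, STD30 = 300, STD50 = 350, STD90 = 500)
  expect_equal(relative_least_squares_cost(tgt, tgt * 1.1,
                                           weights = c(5, 1, 5, 1, 1)),
               0.13, tolerance = 1e-12)
  expect_error(relative_least_squares_cost(c(a = 0), c(a = 1)), "0")
  expect_gte(relative_least_squares_cost(tgt, tgt * runif(5, 0.5, 1.5)), 0)
})

test_that("biomarker sets serialise to flat JSON and back", {
  bm <- pressure_biomarkers(triangle_trace(), t_act = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_biomarkers_json(bm, path)
  bm2 <- read_biomarkers_json(path)
  expect_equal(unlist(bm2[names(bm)]), unlist(unclass(bm)))
})
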