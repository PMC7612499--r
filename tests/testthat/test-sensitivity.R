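test_that("the cross-sampling scheme has the expected layout", {
  lo <- c(a = 0, b = -1, c = 2); hi <- c(a = 1, b = 1, c = 4)
  d <- saltelli_sample(lo, hi, N = 64, seed = 3)
  expect_equal(nrow(d$samples), 64 * (3 + 2))
  expect_true(all(sweep(d$samples, 2, lo, ">=")))
  expect_true(all(sweep(d$samples, 2, hi, "<=")))
  d2 <- saltelli_sample(lo, hi, N = 64, seed = 3)
  expect_identical(d$samples, d2$samples)
  # AB_i differs from A only in column i
  A <- d$samples[1:64, ]; AB1 <- d$samples[(2 * 64 + 1):(3 * 64), ]
  expect_identical(A[, 2:3], AB1[, 2:3])
  expect_false(any(A[, 1] == AB1[, 1]))
})

test_that("indices of an additive linear model match the closed form", {
  # y = sum a_i x_i with independent uniforms: S1_i = ST_i =
  # a_i^2 Var(x_i) / Var(y), and the first-order indices sum to 1
  a <- c(4, 2, 1)
  lo <- rep(0, 3); hi <- rep(1, 3)
  d <- saltelli_sample(lo, hi, N = 1024, seed = 5)
  y <- as.matrix(d$samples) %*% a
  res <- sobol_indices(d, y, n_boot = 100, seed = 5)
  truth <- a^2 * (1 / 12) / sum(a^2 / 12)
  for (i in 1:3) {
    expect_lt(abs(res$S1[i, 1] - truth[i]),
              pmax(res$S1_conf[i, 1], 0.02))
    expect_lt(abs(res$ST[i, 1] - truth[i]),
              pmax(res$ST_conf[i, 1], 0.02))
  }
  expect_equal(sum(res$S1[, 1]), 1, tolerance = 0.05)
  expect_equal(res$ranking[1], "x1")
})

test_that("indices of the Ishigami function match the analytic decomposition", {
  a <- 7; b <- 0.1
  d <- saltelli_sample(rep(-pi, 3), rep(pi, 3), N = 1024, seed = 7)
  x <- d$samples
  y <- sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
  res <- sobol_indices(d, y, n_boot = 100, seed = 7)
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  s1_true <- c(V1 / V, V2 / V, 0)
  st_true <- c((V1 + V13) / V, V2 / V, V13 / V)
  for (i in 1:3) {
    expect_lt(abs(res$S1[i, 1] - s1_true[i]),
              pmax(3 * res$S1_conf[i, 1], 0.03))
    expect_lt(abs(res$ST[i, 1] - st_true[i]),
              pmax(3 * res$ST_conf[i, 1], 0.03))
  }
})

test_that("constant output raises an undefined-indices error", {
  d <- saltelli_sample(c(0, 0), c(1, 1), N = 16, seed = 1)
  y <- rep(3, nrow(d$samples))
  expect_error(sobol_indices(d, y, n_boot = 5), "zero output variance")
})

test_that("sample evaluation applies the relaxed exclusion and mean substitution", {
  def <- default_model_parameters()
  lo <- stats::setNames(def$fitted$lower, def$fitted$names)
  hi <- stats::setNames(def$fitted$upper, def$fitted$names)
  d <- saltelli_sample(lo[1:9], hi[1:9], N = 4, seed = 2)
  ev <- evaluate_samples(d$samples, dt = 0.5, max_beats = 8)
  expect_equal(nrow(ev$Y), nrow(d$samples))
  expect_false(anyNA(ev$Y))
  if (any(ev$excluded) && any(!ev$excluded)) {
    means <- colMeans(ev$Y[!ev$excluded, , drop = FALSE])
    expect_equal(unname(ev$Y[which(ev$excluded)[1], ]), unname(means))
  }
  # the default parameter point itself is physiological (not excluded)
  centre <- matrix((lo[1:9] + hi[1:9]) / 2, nrow = 1,
                   dimnames = list(NULL, names(lo)[1:9]))
  ev0 <- evaluate_samples(centre, dt = 0.2)
  expect_false(ev0$excluded[1])
})

test_that("parameter ranking sums total effects and is stable to column order", {
  res <- structure(list(
    ST = matrix(c(0.9, 0.1, 0.3, 0.8, 0.2, 0.3), nrow = 3,
                dimnames = list(c("p1", "p2", "p3"), c("b1", "b2")))),
    class = "sobol_result")
  expect_equal(rank_parameters(res), c("p1", "p3", "p2"))
  res2 <- res; res2$ST <- res$ST[, 2:1]
  expect_equal(rank_parameters(res2), rank_parameters(res))
  # ties break by original parameter order
  res3 <- res; res3$ST[] <- 0.5
  expect_equal(rank_parameters(res3), c("p1", "p2", "p3"))
})
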