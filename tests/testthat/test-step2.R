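test_that("constraint violations report magnitudes per constraint", {
  # feasible reference run: all-zero vector
  z <- quick_zerod(ap = 50)
  v <- constraint_violations(z$sa, z$ca, constraint_set())
  expect_equal(unname(v), rep(0, 5))
  # resting stress of 1 kPa on a 10 kPa peak exceeds the 2% band by 0.8
  sa_bad <- trace(c(1, 1, seq(1, 10, length.out = 50),
                    seq(10, 1, length.out = 50)), dt = 1)
  v <- constraint_violations(sa_bad, NULL,
                             constraint_set(calcium_active = FALSE))
  expect_equal(unname(v[["rest_stress"]]), 1 - 0.02 * 10, tolerance = 1e-9)
  # calcium transient too short: distance to the 120 ms bound
  tt <- seq(0, 900, by = 1)
  ca_fast <- trace(0.1 + 0.8 * exp(-(tt - 50)^2 / (2 * 30^2)), dt = 1)
  ctd <- calcium_durations(ca_fast, t_act = 0)
  v <- constraint_violations(z$sa, ca_fast, constraint_set())
  expect_equal(unname(v[["ctd50"]]), 120 - ctd$CTD50, tolerance = 1e-9)
  # negative stress reported by magnitude
  sa_neg <- trace(c(0, 5, 10, 5, -2, 0, 0), dt = 1)
  v <- constraint_violations(sa_neg, NULL,
                             constraint_set(calcium_active = FALSE))
  expect_equal(unname(v[["negative_stress"]]), 2)
})

test_that("penalised cost is zero at the truth and prices deviations", {
  sim <- quick_zerod(ap = 50)
  targets <- list(stress = stress_biomarkers(sim$sa, t_act = 0),
                  lambda_min = min(sim$lam$values))
  truth <- c(nTRPN = 3.22, beta1 = -1.21, nTm = 5.47, Ca50_ref = 0.501,
             kUW = 0.046, Ca_res = 0.076, Ca_max = 0.9, tauCR = 164.4,
             tauCD = 149.0, a_p = 50)
  expect_equal(penalised_cost(truth, targets, dt = 0.2), 0, tolerance = 1e-8)
  # a 1% mismatch in the stretch target costs wlam * 0.01^2
  t2 <- targets; t2$lambda_min <- targets$lambda_min / 0.99
  expect_equal(penalised_cost(truth, t2, dt = 0.2), 100 * 0.01^2,
               tolerance = 1e-5)
  # with wlam = 0 the stretch target does not matter
  w0 <- list(wSa = c(5, 1, 5, 1, 1), wlam = 0)
  expect_equal(penalised_cost(truth, t2, weights = w0, dt = 0.2),
               penalised_cost(truth, targets, weights = w0, dt = 0.2))
  # simulation failure maps to the large finite sentinel
  bad <- truth; bad[["Ca_res"]] <- 0.89; bad[["Ca_max"]] <- 0.9
  v <- penalised_cost(bad, targets, dt = 0.2)
  expect_true(is.finite(v))
})

test_that("differential evolution solves standard test problems deterministically", {
  # convex quadratic in 3D
  sphere <- function(x) sum((x - c(1, -2, 0.5))^2)
  r <- differential_evolution(sphere, lower = rep(-5, 3), upper = rep(5, 3),
                              tol = 0, maxiter = 200, seed = 4)
  expect_lt(r$value, 1e-6)
  expect_equal(unname(r$par), c(1, -2, 0.5), tolerance = 1e-3)
  # 2-D Rosenbrock on [-2, 2]^2: minimum at (1, 1)
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  r2 <- differential_evolution(rosen, lower = c(-2, -2), upper = c(2, 2),
                               tol = 0, maxiter = 400, seed = 4)
  expect_equal(unname(r2$par), c(1, 1), tolerance = 1e-3)
  # same seed gives identical trajectories
  r3 <- differential_evolution(rosen, lower = c(-2, -2), upper = c(2, 2),
                               tol = 0, maxiter = 50, seed = 9)
  r4 <- differential_evolution(rosen, lower = c(-2, -2), upper = c(2, 2),
                               tol = 0, maxiter = 50, seed = 9)
  expect_identical(r3$history, r4$history)
  expect_identical(r3$par, r4$par)
})

test_that("the incumbent cost never increases and candidates stay in bounds", {
  tracked <- function(x) {
    expect_true(all(x >= -3 - 1e-12) && all(x <= 3 + 1e-12))
    sum(abs(x))
  }
  r <- differential_evolution(tracked, lower = rep(-3, 4), upper = rep(3, 4),
                              tol = 0, maxiter = 40, seed = 2)
  expect_true(all(diff(r$history) <= 0))
  expect_true(all(r$population >= -3 & r$population <= 3))
})

test_that("stretch targets across the organ-scale range are matched by the stiffness alone", {
  # one-parameter calibration: a_p against lambda_min, other parameters fixed
  for (target in c(0.82, 0.86)) {
    obj <- function(x) {
      z <- tryCatch(quick_zerod(ap = x[1]), error = function(e) NULL)
      if (is.null(z)) return(1e8)
      100 * ((target - min(z$lam$values)) / target)^2
    }
    r <- differential_evolution(obj, lower = 21, upper = 95, popsize = 8,
                                tol = 0, maxiter = 25, seed = 3)
    z <- quick_zerod(ap = r$par[1])
    expect_equal(min(z$lam$values), target, tolerance = 0.005)
  }
})

test_that("cell-scale calibration in fixed-calcium mode recovers biomarkers", {
  # the stress and stretch traces come from known parameters; the median
  # calcium trace is the fixed input (6 fitted parameters)
  sim <- quick_zerod(land = land_params(nTRPN = 3.0, kUW = 0.05), ap = 55)
  fit <- calibrate_step2(median_sa = sim$sa, median_lam = sim$lam,
                         median_ca = sim$ca,
                         de_config = list(seed = 11, maxiter = 60,
                                          popsize = 45),
                         n_stages = 2, dt = 0.2)
  tv <- unlist(fit$targets$stress)
  sv <- unlist(fit$biomarkers)[names(tv)]
  expect_lt(max(abs(sv - tv) / tv), 0.05)
  expect_lt(abs(fit$lambda_min - fit$targets$lambda_min) /
              fit$targets$lambda_min, 0.02)
  expect_equal(max(fit$violations), 0)
  expect_named(coef(fit), c("nTRPN", "beta1", "nTm", "Ca50_ref", "kUW",
                            "a_p"))
})
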