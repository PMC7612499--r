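# Variance-based Sobol global sensitivity analysis with Saltelli
# cross-sampling: first-order indices S1 (variance attributed to one input
# alone) and total-effect indices ST (including all interactions), estimated
# from N * (D + 2) model runs. Applied to the 0D electromechanics model to
# rank the crossbridge and calcium parameters by their influence on the
# active stress biomarkers.

#' Saltelli cross-sample for first-order and total-effect Sobol indices
#'
#' Draws two independent base matrices A and B of size N x D (uniform within
#' bounds) and builds the D radial matrices AB_i in which column i of A is
#' replaced by column i of B. The returned matrix stacks A, B, AB_1 ... AB_D
#' (N * (D + 2) rows), the layout expected by [sobol_indices()].
#'
#' @param lower,upper finite bound vectors (length D).
#' @param N base sample size; a power of 2 is conventional.
#' @param seed integer seed.
#' @return List `(samples, N, D)` where `samples` is the stacked matrix.
#' @export
saltelli_sample <- function(lower, upper, N = 1024, seed = 1) {
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))),
            all(upper > lower), N >= 2)
  D <- length(lower)
  set.seed(seed)
  unit <- matrix(stats::runif(N * 2 * D), nrow = N)
  scale_cols <- function(u) sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  A <- scale_cols(unit[, 1:D, drop = FALSE])
  B <- scale_cols(unit[, (D + 1):(2 * D), drop = FALSE])
  AB <- lapply(seq_len(D), function(i) { M <- A; M[, i] <- B[, i]; M })
  samples <- do.call(rbind, c(list(A, B), AB))
  colnames(samples) <- names(lower)
  list(samples = samples, N = N, D = D)
}

#' Evaluate a Saltelli sample on the 0D electromechanics model
#'
#' Runs the 0D model once per sample row and extracts the five active stress
#' biomarkers. Samples that produce non-physiological stress traces are
#' excluded: the exclusion criteria mirror the step-2 trace constraints with
#' one relaxation -- the resting stress may reach up to 10% of the peak
#' stress (this keeps more samples in the analysis). Simulation failures and
#' undefined biomarkers also count as non-physiological. Because the
#' estimators need a complete output matrix, biomarkers of excluded rows are
#' substituted by the means over the physiological rows.
#'
#' @param samples stacked sample matrix with named columns (fitted-parameter
#'   names as in [calibrate_step2()]).
#' @param lam0 initial stretch (default 1.1).
#' @param a_p passive stiffness (kPa, default 42) when `a_p` is not sampled.
#' @param cycle_length cycle length (ms, default 1000).
#' @param base_land,base_rice baselines for parameters not sampled.
#' @param dt,max_beats 0D simulation controls.
#' @return List `(Y, excluded, n_excluded)`: `Y` is the rows x biomarkers
#'   output matrix (excluded rows mean-substituted), `excluded` the logical
#'   mask.
#' @export
evaluate_samples <- function(samples, lam0 = 1.1, a_p = 42,
                             cycle_length = 1000,
                             base_land = land_params(),
                             base_rice = rice_params(), dt = 0.2,
                             max_beats = 20) {
  bm_names <- c("Sa_max", "dSadt_max", "STD30", "STD50", "STD90")
  n <- nrow(samples)
  Y <- matrix(NA_real_, n, length(bm_names), dimnames = list(NULL, bm_names))
  excluded <- logical(n)
  for (r in seq_len(n)) {
    theta <- samples[r, ]
    mods <- .assemble_models(theta, base_land, base_rice, base_ap = a_p)
    sim <- tryCatch(
      solve_stretch_equilibrium(mods$land, mods$passive, calcium = mods$rice,
                                lam0 = lam0, cycle_length = cycle_length,
                                dt = dt, max_beats = max_beats,
                                beat_tol = 1e-3),
      error = function(e) NULL)
    ok <- FALSE
    if (!is.null(sim)) {
      sa <- sim$sa
      peak <- max(sa$values)
      viol <- constraint_violations(sa, ca = NULL,
                                    constraint_set(calcium_active = FALSE))
      rest_ok <- abs(sa$values[1]) <= 0.1 * peak  # relaxed resting criterion
      if (peak > 0 && rest_ok && viol[["negative_stress"]] == 0 &&
          viol[["rate_after_peak"]] == 0) {
        bm <- tryCatch(stress_biomarkers(sa, t_act = 0),
                       error = function(e) NULL)
        if (!is.null(bm)) {
          Y[r, ] <- unlist(bm)[bm_names]
          ok <- TRUE
        }
      }
    }
    excluded[r] <- !ok
  }
  if (all(excluded))
    stop("sensitivity analysis impossible: every sample was excluded",
         call. = FALSE)
  means <- colMeans(Y[!excluded, , drop = FALSE])
  for (j in seq_along(bm_names)) Y[excluded, j] <- means[j]
  list(Y = Y, excluded = excluded, n_excluded = sum(excluded))
}

#' Sobol first-order and total-effect indices from a Saltelli design
#'
#' Estimators on the stacked (A, B, AB_i) evaluations: the Saltelli-2010
#' first-order estimator `S1_i = mean(f_B * (f_ABi - f_A)) / V` and the
#' Jansen total-effect estimator `ST_i = mean((f_A - f_ABi)^2) / (2 V)`,
#' with `V` the variance over the A and B rows. Bootstrap confidence
#' half-widths resample the N design rows.
#'
#' @param design list from [saltelli_sample()] (for `N` and `D`).
#' @param outputs numeric matrix (rows aligned with the stacked samples;
#'   one column per model output) or a vector.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level for the half-widths (default 0.95).
#' @param seed seed for the bootstrap resampling.
#' @return Object of class `sobol_result` with matrices `S1`, `ST`,
#'   `S1_conf`, `ST_conf` (D x outputs) and the ST-based `ranking`.
#' @export
sobol_indices <- function(design, outputs, n_boot = 200, conf = 0.95,
                          seed = 1) {
  Y <- as.matrix(outputs)
  N <- design$N; D <- design$D
  stopifnot(nrow(Y) == N * (D + 2))
  pnames <- colnames(design$samples)
  if (is.null(pnames)) pnames <- paste0("x", seq_len(D))
  est <- function(idx) {
    fA <- Y[idx, , drop = FALSE]
    fB <- Y[N + idx, , drop = FALSE]
    V <- apply(rbind(fA, fB), 2, stats::var)
    if (any(V <= 0))
      stop("Sobol indices undefined: zero output variance", call. = FALSE)
    S1 <- matrix(0, D, ncol(Y)); ST <- matrix(0, D, ncol(Y))
    for (i in seq_len(D)) {
      fABi <- Y[(1 + i) * N + idx, , drop = FALSE]
      S1[i, ] <- colMeans(fB * (fABi - fA)) / V
      ST[i, ] <- colMeans((fA - fABi)^2) / (2 * V)
    }
    list(S1 = S1, ST = ST)
  }
  point <- est(seq_len(N))
  set.seed(seed)
  bS1 <- array(NA_real_, c(D, ncol(Y), n_boot))
  bST <- array(NA_real_, c(D, ncol(Y), n_boot))
  for (b in seq_len(n_boot)) {
    e <- tryCatch(est(sample.int(N, N, replace = TRUE)),
                  error = function(err) NULL)
    if (!is.null(e)) { bS1[, , b] <- e$S1; bST[, , b] <- e$ST }
  }
  z <- stats::qnorm(0.5 + conf / 2)
  hw <- function(a) z * apply(a, c(1, 2), stats::sd, na.rm = TRUE)
  dn <- list(pnames, colnames(Y))
  res <- structure(list(S1 = structure(point$S1, dimnames = dn),
                        ST = structure(point$ST, dimnames = dn),
                        S1_conf = structure(hw(bS1), dimnames = dn),
                        ST_conf = structure(hw(bST), dimnames = dn)),
                   class = "sobol_result")
  res$ranking <- rank_parameters(res)
  res
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result>\n  total-effect indices (ST):\n")
  print(round(x$ST, 3))
  cat("  ranking by summed ST: ", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Rank parameters by total-effect influence
#'
#' Sums the total-effect indices of each parameter over all model outputs
#' and orders the parameters by the sum, descending. Ties are broken by the
#' original parameter order.
#'
#' @param res a `sobol_result`.
#' @return Character vector of parameter names, most influential first.
#' @export
rank_parameters <- function(res) {
  s <- rowSums(res$ST)
  names(s)[order(-s, seq_along(s))]
}
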