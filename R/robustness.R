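# Robustness protocols: propagate clinical-data uncertainty (+/-10% LHS
# perturbation of the biomarker targets) and initial-guess variation
# (+/-50% LHS perturbation of the starting parameters) through the
# personalisation workflow, and summarise the resulting parameter/biomarker
# spread as relative-difference statistics (mean, SD, min, max).

#' Latin hypercube perturbation around a centre vector
#'
#' Draws `n` Latin hypercube samples, coordinate-wise uniform in
#' `[center * (1 - fraction), center * (1 + fraction)]`; each coordinate's n
#' samples occupy n distinct equal-width strata. Deterministic under a fixed
#' seed.
#'
#' @param center numeric vector (biomarker values or parameters).
#' @param fraction relative half-range (> 0), e.g. 0.1 for +/-10%.
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return n x length(center) matrix (named columns).
#' @export
lhs_perturb <- function(center, fraction, n, seed = 1) {
  stopifnot(fraction > 0, n >= 1)
  center <- unlist(center)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(center))
  lo <- center * (1 - fraction)
  hi <- center * (1 + fraction)
  out <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(out) <- names(center)
  out
}

#' Relative differences in percent
#'
#' `100 * |candidate - reference| / |reference|`, elementwise.
#'
#' @param reference nonzero reference values.
#' @param candidates values to compare.
#' @return Numeric vector of percentages.
#' @export
relative_differences <- function(reference, candidates) {
  reference <- unlist(reference); candidates <- unlist(candidates)
  if (any(reference == 0))
    stop("relative difference undefined for a reference of 0", call. = FALSE)
  100 * abs(candidates - reference) / abs(reference)
}

#' Summary statistics of relative differences
#'
#' Mean, standard deviation, minimum and maximum of a set of relative
#' differences (%). The SD is the population standard deviation (divisor
#' n): this convention reproduces the published summary pairs this summary
#' format follows.
#'
#' @param diffs numeric vector of relative differences (%), n >= 1.
#' @return List of class `rel_diff_summary` with `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
summarise_rel_diffs <- function(diffs) {
  diffs <- unlist(diffs)
  if (length(diffs) < 1L) stop("empty input", call. = FALSE)
  structure(list(mean = mean(diffs),
                 sd = sqrt(mean((diffs - mean(diffs))^2)),
                 min = min(diffs), max = max(diffs), n = length(diffs)),
            class = "rel_diff_summary")
}

#' @export
print.rel_diff_summary <- function(x, ...) {
  cat(sprintf("mean %.1f%%, SD %.1f%%, min %.1f%%, max %.1f%% (n = %d)\n",
              x$mean, x$sd, x$min, x$max, x$n))
  invisible(x)
}

#' Packaged cohort goodness-of-fit table
#'
#' Per-case relative differences (%) between simulated and clinical pressure
#' and volume biomarkers for a seven-case cohort, for both personalisation
#' steps. Values below the 0.1% reporting resolution are stored as 0.
#'
#' @return Data frame with columns `case`, `step` (1 or 2), `biomarker`,
#'   `rel_diff_pct`.
#' @export
cohort_fit_reldiffs <- function() {
  utils::read.csv(system.file("extdata", "cohort_fit_reldiff.csv",
                              package = "myofit"))
}

#' Clinical-data uncertainty study on the surrogate workflow
#'
#' Perturbs the clinical biomarker targets by `+/-fraction` (coordinate-wise
#' LHS), reruns the step-1 calibration per sample, and summarises the spread
#' of the estimated parameters and the resulting simulated biomarkers as
#' relative differences to the unperturbed ("original") personalisation.
#' With `run_step2 = TRUE` the cell-scale calibration is run per sample as
#' well (median traces from the per-sample step-1 beat) and its parameter
#' spread is summarised too. Failed samples are recorded and excluded from
#' the summaries rather than aborting the study.
#'
#' @param b_clin clinical biomarker targets (as for [calibrate_step1()]).
#' @param fraction relative perturbation (default 0.1).
#' @param n number of samples (default 10).
#' @param seed integer seed.
#' @param p0,valves0,cfg,wk step-1 setup.
#' @param run_step2 also rerun the cell-scale fit per sample (slower).
#' @param step2_args list of extra arguments for [calibrate_step2()].
#' @param dt forward-simulation step (ms).
#' @return Object of class `robustness_study`: `reference` (original fit
#'   results), `samples` (per-sample parameter/biomarker tables),
#'   `summaries` (a `rel_diff_summary` per quantity), `n_failed`.
#' @export
run_uncertainty_study <- function(b_clin, fraction = 0.1, n = 10, seed = 1,
                                  p0 = tanh_params(),
                                  valves0 = valve_params(),
                                  cfg = surrogate_lv_config(),
                                  wk = windkessel_params(),
                                  run_step2 = FALSE, step2_args = list(),
                                  dt = 0.5) {
  ref <- .personalise_once(b_clin, p0, valves0, cfg, wk, run_step2,
                           step2_args, dt, seed)
  pert <- lhs_perturb(b_clin, fraction, n, seed = seed)
  .robustness_core(ref, function(i) {
    bi <- as.list(pert[i, ])
    class(bi) <- "biomarker_set"
    .personalise_once(bi, p0, valves0, cfg, wk, run_step2, step2_args, dt,
                      seed + i)
  }, n)
}

#' Initial-guess variation study on the surrogate workflow
#'
#' Perturbs the step-1 initial parameter guesses by `+/-fraction` (LHS,
#' default 0.5) and reruns the calibration per sample against fixed
#' clinical targets; differences are reported relative to the results
#' produced by the default initial guesses. With `run_step2 = TRUE` the
#' DE seed of the cell-scale fit is varied per sample as well (its initial
#' population is an LHS of the bounds by construction).
#'
#' @inheritParams run_uncertainty_study
#' @param fraction relative perturbation of the initial guesses (default
#'   0.5).
#' @param n number of samples (default 5).
#' @return Object of class `robustness_study`.
#' @export
run_initial_guess_study <- function(b_clin, fraction = 0.5, n = 5, seed = 1,
                                    p0 = tanh_params(),
                                    valves0 = valve_params(),
                                    cfg = surrogate_lv_config(),
                                    wk = windkessel_params(),
                                    run_step2 = FALSE, step2_args = list(),
                                    dt = 0.5) {
  ref <- .personalise_once(b_clin, p0, valves0, cfg, wk, run_step2,
                           step2_args, dt, seed)
  centre <- c(unlist(p0[c("Smax_ref", "tauSR_ref", "tauSD", "tCR")]),
              unlist(valves0[c("R_AVf", "R_MVf")]))
  pert <- lhs_perturb(centre, fraction, n, seed = seed)
  .robustness_core(ref, function(i) {
    p <- pert[i, ]
    p0i <- tanh_params(Smax_ref = p[["Smax_ref"]],
                       tauSR_ref = p[["tauSR_ref"]],
                       tauSD = p[["tauSD"]], tCR = p[["tCR"]])
    v0i <- valves0
    v0i$R_AVf <- p[["R_AVf"]]; v0i$R_MVf <- p[["R_MVf"]]
    .personalise_once(b_clin, p0i, v0i, cfg, wk, run_step2, step2_args, dt,
                      seed + i)
  }, n)
}

# one full personalisation (step 1, optionally step 2) against the surrogate
.personalise_once <- function(b_clin, p0, valves0, cfg, wk, run_step2,
                              step2_args, dt, seed) {
  s1 <- calibrate_step1(b_clin, p0 = p0, valves0 = valves0, cfg = cfg,
                        wk = wk, dt = dt)
  out <- list(step1_params = coef(s1),
              step1_biomarkers = unlist(s1$biomarkers),
              step1 = s1)
  if (run_step2) {
    beat <- simulate_beat(cfg, s1$tanh_p, s1$valves, wk, dt = dt)
    ens <- nodal_ensemble(beat, n_nodes = 25, seed = seed)
    med_sa <- align_and_median(ens$sa, ens$activation_times)
    med_lam <- align_and_median(ens$lam, ens$activation_times)
    s2 <- do.call(calibrate_step2,
                  c(list(median_sa = med_sa, median_lam = med_lam,
                         de_config = utils::modifyList(
                           list(seed = seed),
                           if (!is.null(step2_args$de_config))
                             step2_args$de_config else list())),
                    step2_args[setdiff(names(step2_args), "de_config")]))
    out$step2_params <- coef(s2)
    out$step2 <- s2
  }
  out
}

.robustness_core <- function(ref, run_sample, n) {
  samples <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    samples[[i]] <- tryCatch(run_sample(i), error = function(e) {
      warning("sample ", i, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(samples[[i]])) failed <- failed + 1L
  }
  ok <- !vapply(samples, is.null, logical(1))
  summarise_block <- function(field) {
    refv <- ref[[field]]
    if (is.null(refv)) return(NULL)
    mat <- do.call(rbind, lapply(samples[ok], `[[`, field))
    lapply(stats::setNames(colnames(mat), colnames(mat)), function(cn)
      summarise_rel_diffs(relative_differences(rep(refv[[cn]], sum(ok)),
                                               mat[, cn])))
  }
  structure(list(reference = ref,
                 samples = samples,
                 summaries = list(step1_params = summarise_block("step1_params"),
                                  step1_biomarkers =
                                    summarise_block("step1_biomarkers"),
                                  step2_params = summarise_block("step2_params")),
                 n_failed = failed, n = n),
            class = "robustness_study")
}

#' @export
print.robustness_study <- function(x, ...) {
  cat(sprintf("<robustness_study> %d samples (%d failed)\n", x$n, x$n_failed))
  for (blk in names(x$summaries)) {
    s <- x$summaries[[blk]]
    if (is.null(s)) next
    cat("  ", blk, " (mean relative difference, %):\n", sep = "")
    m <- vapply(s, `[[`, numeric(1), "mean")
    print(round(m, 1))
  }
  invisible(x)
}

#' Export a robustness study as a table-style CSV
#'
#' One row per statistic (original, mean, SD, min, max) and quantity, with
#' the relative-difference statistics (%) in companion columns.
#'
#' @param x a `robustness_study`.
#' @param block which summary block to export.
#' @param path file path.
#' @export
write_robustness_csv <- function(x, block = "step1_params", path) {
  s <- x$summaries[[block]]
  if (is.null(s)) stop("no such summary block", call. = FALSE)
  refv <- x$reference[[block]]
  ok <- !vapply(x$samples, is.null, logical(1))
  mat <- do.call(rbind, lapply(x$samples[ok], `[[`, block))
  stat_rows <- rbind(original = refv,
                     mean = colMeans(mat),
                     sd = apply(mat, 2, function(v) sqrt(mean((v - mean(v))^2))),
                     min = apply(mat, 2, min),
                     max = apply(mat, 2, max))
  rel <- rbind(original = rep(0, length(refv)),
               mean = vapply(s, `[[`, numeric(1), "mean"),
               sd = vapply(s, `[[`, numeric(1), "sd"),
               min = vapply(s, `[[`, numeric(1), "min"),
               max = vapply(s, `[[`, numeric(1), "max"))
  colnames(rel) <- paste0(colnames(stat_rows), "_reldiff_pct")
  utils::write.csv(cbind(data.frame(statistic = rownames(stat_rows)),
                         stat_rows, rel),
                   path, row.names = FALSE)
  invisible(path)
}
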