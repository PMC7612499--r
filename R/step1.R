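# Step 1: organ-scale personalisation of the phenomenological active-stress
# model and the valve resistances by fixed-point iteration on pressure and
# volume biomarkers. Each parameter is updated multiplicatively by the ratio
# of the clinical to the simulated biomarker it is most directly tied to;
# a fixed point of the update map is exactly a parameter set whose simulated
# biomarkers match the clinical ones.

#' One fixed-point update of the Tanh and valve parameters
#'
#' Multiplicative updates:
#' `Smax_ref *= Pmax_clin / Pmax_sim`,
#' `tauSR_ref *= dPdt_max_sim / dPdt_max_clin`,
#' `tauSD *= dPdt_min_sim / dPdt_min_clin`,
#' `tCR *= PTD90_clin / PTD90_sim`,
#' and, when volume biomarkers are present,
#' `R_AVf *= tauVD_clin / tauVD_sim`, `R_MVf *= tauVR_clin / tauVR_sim`.
#' A higher clinical peak pressure calls for more stress; a steeper clinical
#' upstroke calls for a shorter rise time constant; and so on. Optional
#' clipping bounds each multiplicative factor to `[0.2, 5]` per iteration to
#' damp oscillations on extreme ratios (off by default).
#'
#' @param tanh_p a [tanh_params()].
#' @param valves a [valve_params()] or `NULL` (pressure-only calibration).
#' @param b_sim simulated biomarkers (as from [beat_biomarkers()]).
#' @param b_clin clinical/target biomarkers (same names).
#' @param clip_factors logical; clip update factors to `[0.2, 5]`.
#' @return List with updated `tanh_p` and `valves`.
#' @export
fixed_point_update <- function(tanh_p, valves, b_sim, b_clin,
                               clip_factors = FALSE) {
  need <- c("Pmax", "dPdt_max", "dPdt_min", "PTD90")
  if (any(vapply(b_sim[need], function(x) x == 0, logical(1))))
    stop("update undefined: simulated biomarker value of 0", call. = FALSE)
  cl <- function(f) if (clip_factors) min(max(f, 0.2), 5) else f
  tanh_p$Smax_ref <- tanh_p$Smax_ref * cl(b_clin$Pmax / b_sim$Pmax)
  tanh_p$tauSR_ref <- tanh_p$tauSR_ref * cl(b_sim$dPdt_max / b_clin$dPdt_max)
  tanh_p$tauSD <- tanh_p$tauSD * cl(b_sim$dPdt_min / b_clin$dPdt_min)
  tanh_p$tCR <- tanh_p$tCR * cl(b_clin$PTD90 / b_sim$PTD90)
  if (!is.null(valves) && !is.null(b_clin$tauVD)) {
    if (b_sim$tauVD == 0 || b_sim$tauVR == 0)
      stop("update undefined: simulated biomarker value of 0", call. = FALSE)
    valves$R_AVf <- valves$R_AVf * cl(b_clin$tauVD / b_sim$tauVD)
    valves$R_MVf <- valves$R_MVf * cl(b_clin$tauVR / b_sim$tauVR)
  }
  list(tanh_p = tanh_p, valves = valves)
}

#' Step-1 organ-scale calibration by fixed-point iteration
#'
#' Loops simulate -> extract biomarkers -> relative-least-squares cost (unit
#' weights) -> fixed-point update until the cost falls below `threshold`
#' (default 0.1) or `max_iter` is reached. A forward-model failure mid-loop
#' aborts the iteration and the best parameters seen so far are returned
#' (flagged `aborted`).
#'
#' @param b_clin clinical biomarker targets: `Pmax`, `dPdt_max`, `dPdt_min`,
#'   `PTD90` and (optionally, to include the valve models) `tauVD`, `tauVR`.
#' @param p0 initial [tanh_params()].
#' @param valves0 initial [valve_params()], or `NULL` to calibrate pressure
#'   biomarkers only.
#' @param forward beat simulator `(tanh_p, valves) -> beat_result`; defaults
#'   to [simulate_beat()] on `cfg`/`wk`.
#' @param cfg,wk surrogate configuration and afterload for the default
#'   forward model.
#' @param threshold convergence threshold on the cost (default 0.1).
#' @param max_iter maximum iterations (default 15).
#' @param clip_factors passed to [fixed_point_update()].
#' @param dt forward-simulation time step (ms).
#' @return Object of class `step1_fit`: `tanh_p`, `valves` (final), `cost`
#'   (per-iteration costs), `params_trace` (per-iteration parameter list),
#'   `biomarkers` (final simulated), `converged`, `aborted`, `n_iterations`.
#' @export
calibrate_step1 <- function(b_clin, p0 = tanh_params(),
                            valves0 = valve_params(), forward = NULL,
                            cfg = surrogate_lv_config(),
                            wk = windkessel_params(), threshold = 0.1,
                            max_iter = 15, clip_factors = FALSE, dt = 0.5) {
  stopifnot(threshold > 0)
  use_volume <- !is.null(valves0) && !is.null(b_clin$tauVD)
  targets <- c("Pmax", "dPdt_max", "dPdt_min", "PTD90")
  if (use_volume) targets <- c(targets, "tauVD", "tauVR")
  if (is.null(forward))
    forward <- function(tp, vv)
      simulate_beat(cfg, tp, if (is.null(vv)) valve_params() else vv, wk,
                    dt = dt)
  tp <- p0; vv <- valves0
  costs <- numeric(0)
  params_trace <- list()
  aborted <- FALSE
  best <- list(cost = Inf, tanh_p = tp, valves = vv, biomarkers = NULL)
  i <- 0
  repeat {
    b_sim <- tryCatch({
      beat <- forward(tp, vv)
      beat_biomarkers(beat, t_act = cfg$t_act)
    }, error = function(e) e)
    if (inherits(b_sim, "error")) {
      aborted <- TRUE
      warning("forward model failed at iteration ", i + 1, ": ",
              conditionMessage(b_sim), "; returning best-so-far",
              call. = FALSE)
      break
    }
    cost <- relative_least_squares_cost(b_clin[targets], b_sim[targets])
    costs <- c(costs, cost)
    params_trace[[i + 1]] <- list(tanh_p = tp, valves = vv, cost = cost)
    if (cost < best$cost)
      best <- list(cost = cost, tanh_p = tp, valves = vv, biomarkers = b_sim)
    if (cost < threshold || i >= max_iter) break
    up <- fixed_point_update(tp, if (use_volume) vv else NULL, b_sim, b_clin,
                             clip_factors = clip_factors)
    tp <- up$tanh_p
    if (use_volume) vv <- up$valves
    i <- i + 1
  }
  structure(list(tanh_p = best$tanh_p, valves = best$valves,
                 cost = costs, params_trace = params_trace,
                 biomarkers = best$biomarkers, targets = b_clin,
                 converged = length(costs) > 0 &&
                   costs[length(costs)] < threshold,
                 aborted = aborted, threshold = threshold,
                 n_iterations = length(costs)),
            class = "step1_fit")
}

#' @export
print.step1_fit <- function(x, ...) {
  cat(sprintf(
    "<step1_fit> %d iteration(s), final cost %.4g (threshold %g), %s\n",
    x$n_iterations,
    if (length(x$cost)) x$cost[length(x$cost)] else NA_real_,
    x$threshold,
    if (x$aborted) "aborted" else if (x$converged) "converged"
    else "not converged"))
  invisible(x)
}

#' @export
coef.step1_fit <- function(object, ...) {
  out <- unlist(object$tanh_p[c("Smax_ref", "tauSR_ref", "tauSD", "tCR")])
  if (!is.null(object$valves))
    out <- c(out, unlist(object$valves[c("R_AVf", "R_MVf")]))
  out
}

#' @export
summary.step1_fit <- function(object, ...) {
  cat("Organ-scale fixed-point calibration\n")
  print(object)
  cat("\nEstimated parameters:\n")
  print(coef(object))
  if (!is.null(object$biomarkers)) {
    cat("\nBiomarker fit (relative difference, %):\n")
    nm <- intersect(names(object$targets), names(object$biomarkers))
    rd <- relative_differences(unlist(object$targets[nm]),
                               unlist(object$biomarkers[nm]))
    print(round(rd, 2))
  }
  invisible(object)
}

#' @export
plot.step1_fit <- function(x, ...) {
  graphics::plot(seq_along(x$cost) - 1, x$cost, type = "b", log = "y",
                 xlab = "iteration", ylab = "relative least-squares cost",
                 main = "Fixed-point calibration", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
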