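# Biomarker extractors for pressure, volume, stress, calcium and stretch
# traces. Duration biomarkers use linear interpolation between bracketing
# samples, so they are deterministic and sub-sample accurate; all durations
# are measured from the electrical activation time t_act.

# first time after index `from` at which the trace crosses below `level`,
# linearly interpolated between the bracketing samples
.first_crossing_below <- function(x, level, from = 1L) {
  v <- x$values
  n <- length(v)
  idx <- which(v[(from + 1L):n] <= level)
  if (length(idx) == 0L) return(NA_real_)
  k <- from + idx[1L]                       # first sample at/below level
  t_k <- x$t0 + (k - 1L) * x$dt
  if (k == from || v[k - 1L] <= level) return(t_k)
  frac <- (v[k - 1L] - level) / (v[k - 1L] - v[k])
  t_k - x$dt + frac * x$dt
}

# duration from t_act until decay to (1 - frac) of (peak - base) above base
.decay_duration <- function(x, t_act, frac, base) {
  i_pk <- which.max(x$values)
  peak <- x$values[i_pk]
  if (peak - base <= 0)
    stop("biomarker undefined: trace has no transient above baseline",
         call. = FALSE)
  level <- peak - frac * (peak - base)
  tc <- .first_crossing_below(x, level, from = i_pk)
  if (is.na(tc))
    stop(sprintf(
      "biomarker undefined: trace never decays to the %g%% level", 100 * frac),
      call. = FALSE)
  tc - t_act
}

#' Pressure biomarkers of one beat
#'
#' Extracts the four pressure biomarkers used as step-1 calibration targets:
#' peak pressure `Pmax` (mmHg), the extrema of the pressure rate
#' `dPdt_max` / `dPdt_min` (mmHg/ms, from [time_derivative()]), and the
#' pressure transient duration `PTD90` (ms). `dPdt_min` is taken over the
#' segment after the time of peak pressure, i.e. it is the
#' isovolumetric-relaxation rate in the clinical sense; for smooth clinical
#' beats this coincides with the global minimum, while on lumped-model
#' traces it is insensitive to valve-switching transients during early
#' ejection. `PTD90` is measured from the activation time until the
#' pressure has decayed by 90% of (`Pmax` - baseline); the baseline
#' convention is the pressure at `t_act` (override with `p_base`).
#'
#' @param p pressure [trace()] (mmHg) covering one beat.
#' @param t_act electrical activation time (ms).
#' @param p_base diastolic baseline pressure (mmHg); default `p` at `t_act`.
#' @return A list of class `pressure_biomarkers` with fields `Pmax`,
#'   `dPdt_max`, `dPdt_min`, `PTD90`.
#' @export
pressure_biomarkers <- function(p, t_act = 0, p_base = NULL) {
  stopifnot(inherits(p, "trace"))
  if (is.null(p_base)) p_base <- trace_at(p, t_act)
  dp <- time_derivative(p)
  i_pk <- which.max(p$values)
  bm <- list(Pmax = max(p$values),
             dPdt_max = max(dp$values),
             dPdt_min = min(dp$values[i_pk:length(dp$values)]),
             PTD90 = .decay_duration(p, t_act, 0.9, p_base))
  class(bm) <- c("pressure_biomarkers", "biomarker_set")
  bm
}

#' Volume biomarkers of one beat
#'
#' Stroke volume `SV = max(V) - min(V)` (mL) plus phase time "constants":
#' `tauVD` is the time from the start of the ejection window until the volume
#' has covered a fraction (1 - 1/e) of that window's total decrease, and
#' `tauVR` is the analogue for the filling window's increase. The coverage
#' time is used instead of an exponential fit: it is fit-free, deterministic,
#' equals the true time constant for an exact exponential, and is monotone in
#' it. Crossing times are linearly interpolated.
#'
#' @param v volume [trace()] (mL).
#' @param ejection_window numeric `c(t_start, t_end)` in ms containing the
#'   ejection (volume-decay) phase.
#' @param filling_window numeric `c(t_start, t_end)` in ms containing the
#'   filling (volume-rise) phase.
#' @return A list of class `volume_biomarkers` with fields `SV`, `tauVD`,
#'   `tauVR`.
#' @export
volume_biomarkers <- function(v, ejection_window, filling_window) {
  stopifnot(inherits(v, "trace"))
  cover_time <- function(win, rising) {
    t <- seq(max(win[1], v$t0), min(win[2], trace_end(v)), by = v$dt / 2)
    y <- trace_at(v, t)
    total <- if (rising) y[length(y)] - y[1] else y[1] - y[length(y)]
    if (total <= 0)
      stop("biomarker undefined: no volume change in window", call. = FALSE)
    target <- (1 - exp(-1)) * total
    covered <- if (rising) y - y[1] else y[1] - y
    k <- which(covered >= target)[1]
    if (k == 1L) return(0)
    frac <- (target - covered[k - 1]) / (covered[k] - covered[k - 1])
    (t[k - 1] + frac * (t[k] - t[k - 1])) - t[1]
  }
  bm <- list(SV = max(v$values) - min(v$values),
             tauVD = cover_time(ejection_window, rising = FALSE),
             tauVR = cover_time(filling_window, rising = TRUE))
  class(bm) <- c("volume_biomarkers", "biomarker_set")
  bm
}

#' Active stress biomarkers
#'
#' Peak active stress `Sa_max` (kPa), maximum stress rise rate `dSadt_max`
#' (kPa/ms) and the transient durations `STD30`, `STD50`, `STD90` (ms) at
#' 30/50/90% decay from the peak, measured from the activation time. The
#' resting level is taken as 0 kPa (stress traces are assumed to start from
#' rest).
#'
#' @param sa active stress [trace()] (kPa).
#' @param t_act electrical activation time (ms).
#' @return A list of class `stress_biomarkers` with fields `Sa_max`,
#'   `dSadt_max`, `STD30`, `STD50`, `STD90`.
#' @export
stress_biomarkers <- function(sa, t_act = 0) {
  stopifnot(inherits(sa, "trace"))
  dsa <- time_derivative(sa)
  bm <- list(Sa_max = max(sa$values),
             dSadt_max = max(dsa$values),
             STD30 = .decay_duration(sa, t_act, 0.3, 0),
             STD50 = .decay_duration(sa, t_act, 0.5, 0),
             STD90 = .decay_duration(sa, t_act, 0.9, 0))
  class(bm) <- c("stress_biomarkers", "biomarker_set")
  bm
}

#' Calcium transient durations
#'
#' `CTD50` and `CTD90` (ms): durations from the electrical activation time
#' until the intracellular calcium has decayed by 50% / 90% of
#' (peak - resting) from the peak, where the resting level is the minimum of
#' the trace.
#'
#' @param ca calcium [trace()] (uM).
#' @param t_act electrical activation time (ms).
#' @return A list of class `calcium_durations` with fields `CTD50`, `CTD90`.
#' @export
calcium_durations <- function(ca, t_act = 0) {
  stopifnot(inherits(ca, "trace"))
  base <- min(ca$values)
  bm <- list(CTD50 = .decay_duration(ca, t_act, 0.5, base),
             CTD90 = .decay_duration(ca, t_act, 0.9, base))
  class(bm) <- c("calcium_durations", "biomarker_set")
  bm
}

#' Stretch biomarker
#'
#' The per-beat minimum fibre stretch `lambda_min` (dimensionless). Matching
#' this single number is sufficient to transfer the stretch environment from
#' the organ scale to the cell-scale calibration.
#'
#' @param lam stretch [trace()].
#' @return A list of class `stretch_biomarker` with field `lambda_min`.
#' @export
stretch_biomarker <- function(lam) {
  stopifnot(inherits(lam, "trace"))
  bm <- list(lambda_min = min(lam$values))
  class(bm) <- c("stretch_biomarker", "biomarker_set")
  bm
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (n in names(x)) cat(sprintf("  %-9s %g\n", n, x[[n]]))
  invisible(x)
}

#' Weighted relative least-squares cost between biomarker sets
#'
#' `sum_j w_j * ((target_j - simulated_j) / target_j)^2`. Relative (rather
#' than absolute) residuals are used because the biomarkers vary by orders of
#' magnitude; absolute residuals would weight the terms unintentionally.
#'
#' @param target named numeric vector or `biomarker_set` of target values
#'   (all nonzero).
#' @param simulated matching numeric vector or `biomarker_set`.
#' @param weights nonnegative weights, recycled to the number of biomarkers
#'   (default all 1).
#' @return Nonnegative scalar cost.
#' @examples
#' relative_least_squares_cost(c(a = 100), c(a = 110))  # 0.01
#' @export
relative_least_squares_cost <- function(target, simulated, weights = 1) {
  tv <- unlist(target, use.names = TRUE)
  sv <- unlist(simulated, use.names = TRUE)
  if (!is.null(names(tv)) && !is.null(names(sv)) &&
      all(names(tv) %in% names(sv)))
    sv <- sv[names(tv)]
  if (length(tv) != length(sv))
    stop("target and simulated biomarker sets differ in length", call. = FALSE)
  if (any(tv == 0))
    stop("relative cost undefined: target biomarker value of 0", call. = FALSE)
  w <- rep_len(weights, length(tv))
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sum(w * ((tv - sv) / tv)^2)
}

#' Serialise / read a biomarker set as flat JSON
#'
#' @param bm a `biomarker_set`.
#' @param path file path.
#' @return `read_biomarkers_json()` returns a named list (classed
#'   `biomarker_set`).
#' @export
write_biomarkers_json <- function(bm, path) {
  jsonlite::write_json(unclass(bm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_biomarkers_json
#' @export
read_biomarkers_json <- function(path) {
  bm <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(bm) <- "biomarker_set"
  bm
}
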