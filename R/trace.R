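#' Uniformly sampled time series
#'
#' A `trace` holds one scalar signal sampled on a uniform time grid. It is the
#' common container for cavity pressure (mmHg), cavity volume (mL), cellular
#' active stress (kPa), intracellular calcium (uM) and fibre stretch
#' (dimensionless) throughout the package. Time is always in milliseconds.
#'
#' @param values numeric vector of samples (length >= 2).
#' @param dt sampling interval in ms (> 0).
#' @param t0 time of the first sample in ms.
#' @return An object of class `trace` with fields `t0`, `dt`, `values`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 101)), dt = 10)
#' range(trace_times(tr))
#' @export
trace <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("dt must be a positive finite number", call. = FALSE)
  if (anyNA(values))
    stop("trace values must not contain NA", call. = FALSE)
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples, dt = %g ms, t in [%g, %g] ms\n",
              length(x$values), x$dt, x$t0, trace_end(x)))
  cat(sprintf("  range of values: [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Time axis of a trace
#' @param x a [trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(x) x$t0 + x$dt * (seq_along(x$values) - 1)

trace_end <- function(x) x$t0 + x$dt * (length(x$values) - 1)

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), value = x$values)
}

#' Linear interpolation of a trace at arbitrary times
#'
#' Values outside the support are held at the boundary samples.
#'
#' @param x a [trace()].
#' @param t numeric vector of query times (ms).
#' @return Numeric vector of interpolated values.
#' @export
trace_at <- function(x, t) {
  stats::approx(trace_times(x), x$values, xout = t, rule = 2)$y
}

#' Read / write traces as two-column CSV
#'
#' The on-disk format is a headered CSV with columns `time_ms` and `value`.
#' The time axis must be uniform; `read_trace_csv()` checks this.
#'
#' @param path file path.
#' @return `read_trace_csv()` returns a [trace()]; `write_trace_csv()` returns
#'   `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_ms", "value") %in% names(d)))
    stop("trace CSV must have columns 'time_ms' and 'value'", call. = FALSE)
  dts <- diff(d$time_ms)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-8 * max(abs(dts), 1)))
    stop("trace CSV must be uniformly sampled", call. = FALSE)
  trace(d$value, dt = dts[1], t0 = d$time_ms[1])
}

#' @param x a [trace()].
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Central-difference time derivative of a trace
#'
#' Second-order central differences in the interior, one-sided first-order
#' differences at the two ends. The result lives on the same time grid.
#' No smoothing is applied: inputs are assumed pre-smoothed.
#'
#' @param x a [trace()] with at least 3 samples.
#' @return A [trace()] of the derivative (units of `x` per ms).
#' @examples
#' r <- trace(2 * seq(0, 100, by = 1), dt = 1)   # ramp, slope 2 per ms
#' range(time_derivative(r)$values)              # exactly 2 everywhere
#' @export
time_derivative <- function(x) {
  stopifnot(inherits(x, "trace"))
  n <- length(x$values)
  if (n < 3L) stop("time_derivative needs at least 3 samples", call. = FALSE)
  v <- x$values
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / x$dt
  d[n] <- (v[n] - v[n - 1]) / x$dt
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * x$dt)
  trace(d, dt = x$dt, t0 = x$t0)
}

#' Align an ensemble of traces by activation time and take the pointwise median
#'
#' Each trace is shifted so that its electrical activation time becomes t = 0;
#' the pointwise median is then taken over the overlapping support of the
#' shifted ensemble. The median (rather than the mean) is used because it is
#' robust against outlier traces, e.g. nodes with extreme stretch histories.
#'
#' Activation times are rounded to the common sampling grid before shifting so
#' that no resampling is needed.
#'
#' @param ensemble list of [trace()] objects sharing the same `dt`.
#' @param activation_times numeric vector of activation times (ms), one per
#'   trace.
#' @return A [trace()] with `t0` equal to the start of the overlapping support
#'   (activation at t = 0).
#' @export
align_and_median <- function(ensemble, activation_times) {
  if (length(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  if (length(activation_times) != length(ensemble))
    stop("one activation time per trace is required", call. = FALSE)
  dts <- vapply(ensemble, function(x) x$dt, numeric(1))
  if (any(abs(dts - dts[1]) > 1e-10))
    stop("all traces must share the same dt", call. = FALSE)
  dt <- dts[1]
  # start/end of each shifted trace on the common grid
  starts <- vapply(seq_along(ensemble), function(i)
    ensemble[[i]]$t0 - round(activation_times[i] / dt) * dt, numeric(1))
  ends <- starts + dt * (vapply(ensemble, length, integer(1)) - 1L)
  lo <- max(starts); hi <- min(ends)
  if (hi - lo < dt)
    stop("shifted traces have no overlapping support", call. = FALSE)
  tq <- seq(lo, hi, by = dt)
  m <- vapply(seq_along(ensemble), function(i) {
    k0 <- round((lo - starts[i]) / dt)
    ensemble[[i]]$values[k0 + seq_along(tq)]
  }, numeric(length(tq)))
  trace(apply(m, 1, stats::median), dt = dt, t0 = lo)
}
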