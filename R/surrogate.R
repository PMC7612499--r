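# Lumped (0D) left-ventricle surrogate: a thin-walled incompressible
# spherical shell maps fibre stress to cavity pressure (Laplace law,
# P = 2 h (Sa + Sp) / r with h r^2 fixed by the wall volume, equivalently
# P = 2 Vw / (3 V) * S), coupled to diode valve models and a three-element
# Windkessel afterload. It is a deliberately simple stand-in for an
# organ-scale finite-element ventricle: the one property the calibration
# relies on -- monotone parameter-to-biomarker relationships -- is preserved,
# absolute pressures and volumes are not meant to reproduce any patient.
#
# Unit conventions: time ms, pressure mmHg, volume mL, stress kPa,
# resistances mmHg ms/mL, compliance mL/mmHg.

KPA_PER_MMHG <- 0.133322
MMHG_PER_KPA <- 1 / KPA_PER_MMHG

#' Three-element Windkessel parameters
#'
#' Characteristic resistance `R1`, peripheral resistance `R2` (both
#' mmHg ms/mL) and arterial compliance `C` (mL/mmHg) of the afterload
#' circuit.
#'
#' @param R1,R2,C circuit elements, all positive.
#' @return Named list of class `windkessel_params`.
#' @export
windkessel_params <- function(R1 = 40, R2 = 1100, C = 1.0) {
  stopifnot(R1 > 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C), class = "windkessel_params")
}

#' Diode valve parameters
#'
#' Forward and backward resistances of the aortic and mitral valve diodes.
#' Backward resistances default to 1000 mmHg ms/mL, which suppresses (but,
#' being finite, does not annihilate) backflow across a closed valve.
#' `convert_resistance_s_to_ms()` converts table-style values quoted in
#' mmHg s/mL.
#'
#' @param R_AVf,R_MVf forward resistances (mmHg ms/mL).
#' @param R_AVb,R_MVb backward resistances (mmHg ms/mL); must exceed the
#'   forward values.
#' @return Named list of class `valve_params`.
#' @export
valve_params <- function(R_AVf = 60, R_MVf = 40, R_AVb = 1000,
                         R_MVb = 1000) {
  stopifnot(R_AVf > 0, R_MVf > 0, R_AVb > R_AVf, R_MVb > R_MVf)
  structure(list(R_AVf = R_AVf, R_MVf = R_MVf, R_AVb = R_AVb, R_MVb = R_MVb),
            class = "valve_params")
}

#' @param R_s resistance in mmHg s/mL.
#' @rdname valve_params
#' @export
convert_resistance_s_to_ms <- function(R_s) R_s * 1000

#' Configuration of the surrogate ventricle
#'
#' @param V0 rest (unloaded) cavity volume in mL; fibre stretch is
#'   `lambda = (V / V0)^(1/3)` (the radius ratio of the spherical shell).
#' @param Vw wall volume in mL (incompressible wall).
#' @param P_la constant left-atrial (preload) pressure in mmHg driving
#'   diastolic filling; no atrial kick is modelled.
#' @param P_ed target end-diastolic pressure in mmHg (used to initialise the
#'   cavity volume before the limit cycle settles).
#' @param cycle_length cycle length in ms.
#' @param t_act electrical activation time within the cycle (ms).
#' @param ap_lv passive stiffness scale of the wall (kPa): the parallel
#'   elastic branch is `ap_lv * expm1(b_stiff * x) / b_stiff` in extension
#'   (`x = lambda - 1 >= 0`, setting the end-diastolic volume) and linear
#'   `ap_lv * x` in compression, plus the series spring-dashpot branch of
#'   the three-element element scaled by `ap_lv`.
#' @param b_stiff dimensionless stiffening exponent of the wall.
#' @param ld organ-scale length-dependence slope of the Tanh active stress:
#'   the factor `max(0, 1 + ld * (lambda - 1))` multiplies the transient.
#'   Without it a lumped sphere driven by a length-independent stress has no
#'   Frank-Starling mechanism and ejects without bound. Applies to the Tanh
#'   model only (the Land model carries its own length dependence).
#' @return Named list of class `surrogate_lv_config`.
#' @export
surrogate_lv_config <- function(V0 = 70, Vw = 80, P_la = 14, P_ed = 14,
                                cycle_length = 1000, t_act = 0, ap_lv = 10,
                                b_stiff = 10, ld = 4) {
  stopifnot(V0 > 0, Vw > 0, cycle_length > 0, P_la > 0, ap_lv > 0,
            b_stiff > 0, t_act >= 0, t_act < cycle_length)
  structure(list(V0 = V0, Vw = Vw, P_la = P_la, P_ed = P_ed,
                 cycle_length = cycle_length, t_act = t_act, ap_lv = ap_lv,
                 b_stiff = b_stiff, ld = ld),
            class = "surrogate_lv_config")
}

#' Simulate one (periodic) beat of the surrogate ventricle
#'
#' Integrates the lumped ventricle over repeated cycles until the state at
#' the cycle boundary is periodic, and returns the final beat: pressure,
#' volume, stretch, active stress and calcium traces plus valve phase
#' markers. The active model is either the Tanh model (`active` a
#' [tanh_params()]) or the Land model driven by the phenomenological calcium
#' transient (`active` a [land_params()], `calcium` a [rice_params()]).
#'
#' @param cfg a [surrogate_lv_config()].
#' @param active a [tanh_params()] or [land_params()].
#' @param valves a [valve_params()].
#' @param wk a [windkessel_params()].
#' @param calcium a [rice_params()] (Land active model only).
#' @param dt time step in ms (default 0.5).
#' @param max_beats,beat_tol limit-cycle controls.
#' @return Object of class `beat_result`: traces `P` (mmHg), `V` (mL),
#'   `lam`, `sa` (kPa, the cellular active stress: for the Tanh model this
#'   is the length-neutral transient, the organ-scale length-dependence
#'   factor enters the pressure map only), `ca` (uM); `markers` (valve
#'   open/close times in ms); `n_beats`; `net_volume_change` (mL over the
#'   final cycle).
#' @export
simulate_beat <- function(cfg, active, valves = valve_params(),
                          wk = windkessel_params(), calcium = rice_params(),
                          dt = 0.5, max_beats = 12, beat_tol = 1e-3) {
  stopifnot(inherits(cfg, "surrogate_lv_config"),
            inherits(valves, "valve_params"),
            inherits(wk, "windkessel_params"))
  use_land <- inherits(active, "land_params")
  if (!use_land && !inherits(active, "tanh_params"))
    stop("active model must be tanh_params or land_params", call. = FALSE)
  k_el <- 7; eta_l <- 200; eta_s <- 20   # series-branch constants
  # parallel elastic branch: exponential stiffening in extension (sets the
  # end-diastolic volume), linear in compression (ejection is terminated by
  # afterload and the length dependence of active stress, not by a wall)
  spar <- function(x) if (x >= 0) cfg$ap_lv * expm1(cfg$b_stiff * x) /
    cfg$b_stiff else cfg$ap_lv * x
  nstep <- round(cfg$cycle_length / dt)

  lam_of <- function(V) (V / cfg$V0)^(1 / 3)
  # initial state: modest diastolic distension, relaxed series branch,
  # arterial pressure at a typical diastolic value; the limit cycle settles
  # the true end-diastolic state
  lam <- 1.05
  V <- cfg$V0 * lam^3
  Pc <- 70
  cd <- (1 + 1 / k_el) * (lam - 1)
  cell <- if (use_land)
    land_rest_state(active, calcium$Ca_res, lam)[1:6]
  else NULL
  dlam <- 0

  for (b in seq_len(max_beats)) {
    start <- c(V = V, Pc = Pc, cd = cd, cell)
    P_tr <- V_tr <- lam_tr <- sa_tr <- ca_tr <- qav_tr <- qmv_tr <-
      numeric(nstep + 1)
    for (k in 0:nstep) {
      t <- k * dt
      ts <- t - cfg$t_act
      ca_now <- if (use_land) rice_calcium(ts, calcium) else 0
      # cellular active stress: the Land model carries its own length
      # dependence; the Tanh cell model is length-neutral and the organ
      # coupling applies the Frank-Starling factor on top of it
      sa <- if (use_land) .sa_at(cell, lam, active)
      else tanh_active_stress(ts, active, lam)
      sa_eff <- if (use_land) sa
      else sa * max(0, 1 + cfg$ld * (lam - 1))
      sp <- spar(lam - 1) + cfg$ap_lv * k_el * (lam - 1 - cd)
      P <- MMHG_PER_KPA * (2 * cfg$Vw / (3 * V)) * (sa_eff + sp)
      Pao <- Pc                       # proximal node before R1
      dP_av <- P - Pao
      q_av <- if (dP_av > 0) dP_av / (valves$R_AVf + wk$R1)
      else dP_av / valves$R_AVb
      dP_mv <- cfg$P_la - P
      q_mv <- if (dP_mv > 0) dP_mv / valves$R_MVf else dP_mv / valves$R_MVb
      P_tr[k + 1] <- P; V_tr[k + 1] <- V; lam_tr[k + 1] <- lam
      sa_tr[k + 1] <- sa; ca_tr[k + 1] <- ca_now
      qav_tr[k + 1] <- q_av; qmv_tr[k + 1] <- q_mv
      if (k == nstep) break
      # advance
      V_new <- V + dt * (q_mv - q_av)
      Pc <- Pc + dt * (q_av - Pc / wk$R2) / wk$C
      eta <- if (lam - 1 - cd < 0) eta_l else eta_s
      cd <- cd + dt * k_el * (lam - 1 - cd) / eta
      if (use_land) {
        dstep <- function(s) land_active_rhs(s, max(ca_now, 1e-6), lam,
                                             dlam, active)$dstate
        k1 <- dstep(cell); k2 <- dstep(cell + dt / 2 * k1)
        k3 <- dstep(cell + dt / 2 * k2); k4 <- dstep(cell + dt * k3)
        cell <- cell + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      lam_new <- lam_of(V_new)
      dlam <- (lam_new - lam) / dt
      lam <- lam_new
      V <- V_new
      if (!all(is.finite(c(V, Pc, cd, lam))))
        stop("surrogate LV state became non-finite", call. = FALSE)
    }
    if (max(abs(c(V = V, Pc = Pc, cd = cd, cell) - start)) < beat_tol) break
  }

  # phase markers: the contiguous forward-flow segment containing the peak
  # flow of each valve (weak secondary openings, e.g. a brief suction at the
  # start of the cycle, do not define the phase)
  main_segment <- function(q) {
    fwd <- q > 0
    if (!any(fwd)) return(NULL)
    runs <- rle(fwd)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ipk <- which.max(q)
    seg <- which(runs$values & starts <= ipk & ends >= ipk)
    if (length(seg) == 0L) seg <- which(runs$values)[1]
    c(starts[seg], ends[seg])
  }
  seg_av <- main_segment(qav_tr)
  if (is.null(seg_av) || max(P_tr) < 1.5 * cfg$P_la)
    stop("degenerate beat: aortic valve never opened (active stress too low)",
         call. = FALSE)
  seg_mv <- main_segment(qmv_tr)
  markers <- list(av_open = (seg_av[1] - 1) * dt,
                  av_close = (seg_av[2] - 1) * dt,
                  mv_open = (seg_mv[1] - 1) * dt,
                  mv_close = (seg_mv[2] - 1) * dt)
  structure(list(P = trace(P_tr, dt = dt), V = trace(V_tr, dt = dt),
                 lam = trace(lam_tr, dt = dt), sa = trace(sa_tr, dt = dt),
                 ca = trace(ca_tr, dt = dt), markers = markers,
                 n_beats = b,
                 net_volume_change = sum(qmv_tr - qav_tr) * dt),
            class = "beat_result")
}

#' @export
print.beat_result <- function(x, ...) {
  cat(sprintf("<beat_result> cycle of %g ms (settled after %d beats)\n",
              trace_end(x$P), x$n_beats))
  cat(sprintf("  Pmax = %.1f mmHg, EDV = %.1f mL, SV = %.1f mL, lam_min = %.3f\n",
              max(x$P$values), max(x$V$values),
              max(x$V$values) - min(x$V$values), min(x$lam$values)))
  invisible(x)
}

#' Export a beat result as multi-column CSV
#'
#' Columns `time_ms`, `P_mmHg`, `V_mL`, `lambda`, `Sa_kPa`, `Ca_uM`.
#' @param x a `beat_result`.
#' @param path file path.
#' @export
write_beat_csv <- function(x, path) {
  utils::write.csv(data.frame(time_ms = trace_times(x$P),
                              P_mmHg = x$P$values, V_mL = x$V$values,
                              lambda = x$lam$values, Sa_kPa = x$sa$values,
                              Ca_uM = x$ca$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Pressure and volume biomarkers of a simulated beat
#'
#' Convenience wrapper: extracts the four pressure biomarkers (activation
#' time from the configuration) and the three volume biomarkers (ejection
#' and filling windows from the valve markers) of a [simulate_beat()] result.
#'
#' @param beat a `beat_result`.
#' @param t_act activation time (ms).
#' @return Named list of class `biomarker_set` with `Pmax`, `dPdt_max`,
#'   `dPdt_min`, `PTD90`, `SV`, `tauVD`, `tauVR`.
#' @export
beat_biomarkers <- function(beat, t_act = 0) {
  bp <- pressure_biomarkers(beat$P, t_act = t_act)
  # filling runs from main mitral opening to the end of the cycle (a
  # trailing diastasis plateau does not affect the coverage time)
  bv <- volume_biomarkers(beat$V,
                          ejection_window = c(beat$markers$av_open,
                                              beat$markers$av_close),
                          filling_window = c(beat$markers$mv_open,
                                             trace_end(beat$V)))
  bm <- c(unclass(bp), unclass(bv))
  class(bm) <- "biomarker_set"
  bm
}

#' Heterogeneous nodal ensembles from a simulated beat
#'
#' Emulates the spread of per-node cellular traces in a ventricular wall:
#' each node gets an activation delay (uniform on `[0, act_spread]`), a
#' lognormal amplitude scaling of its stress and calcium transients (median
#' 1, so the aligned pointwise median recovers the underlying beat), and an
#' additive offset of its stretch trace. Reproducible under a fixed seed.
#'
#' @param beat a `beat_result`.
#' @param n_nodes number of nodes (>= 1).
#' @param heterogeneity list with `act_spread` (ms), `amp_cv` (lognormal
#'   sigma of the amplitude factor) and `stretch_sd` (additive stretch
#'   offset SD); zeros give an ensemble of identical copies.
#' @param seed integer seed.
#' @return List with trace lists `sa`, `ca`, `lam` and the numeric vector
#'   `activation_times` (ms).
#' @export
nodal_ensemble <- function(beat, n_nodes = 101,
                           heterogeneity = list(act_spread = 40,
                                                amp_cv = 0.1,
                                                stretch_sd = 0.02),
                           seed = 1) {
  stopifnot(n_nodes >= 1)
  h <- utils::modifyList(list(act_spread = 0, amp_cv = 0, stretch_sd = 0),
                         as.list(heterogeneity))
  dt <- beat$P$dt
  set.seed(seed)
  delays <- round(stats::runif(n_nodes, 0, h$act_spread) / dt) * dt
  amps <- if (h$amp_cv > 0) stats::rlnorm(n_nodes, 0, h$amp_cv)
  else rep(1, n_nodes)
  offs <- if (h$stretch_sd > 0) stats::rnorm(n_nodes, 0, h$stretch_sd)
  else rep(0, n_nodes)
  shift <- function(x, delay_ms, scale = 1, offset = 0) {
    k <- round(delay_ms / dt)
    v <- c(rep(x$values[1], k), x$values[seq_len(length(x$values) - k)])
    trace(v * scale + offset, dt = dt, t0 = x$t0)
  }
  list(sa = lapply(seq_len(n_nodes), function(i)
         shift(beat$sa, delays[i], scale = amps[i])),
       ca = lapply(seq_len(n_nodes), function(i) {
         base <- min(beat$ca$values)
         tr <- shift(beat$ca, delays[i])
         trace(base + (tr$values - base) * amps[i], dt = dt, t0 = tr$t0)
       }),
       lam = lapply(seq_len(n_nodes), function(i)
         shift(beat$lam, delays[i], offset = offs[i])),
       activation_times = delays)
}

#' Synthetic clinical pressure/volume data with known truth
#'
#' Simulates a periodic beat of the surrogate ventricle with known "true"
#' Tanh and valve parameters, extracts the pressure and volume biomarkers,
#' and (optionally) perturbs each biomarker independently by a uniform
#' relative error in `[-noise_frac, +noise_frac]`. The perturbed biomarkers
#' play the role of clinically measured calibration targets; the clean beat
#' and biomarkers are returned alongside for reference.
#'
#' @param true_tanh a [tanh_params()] (the ground truth).
#' @param true_valves a [valve_params()].
#' @param cfg a [surrogate_lv_config()].
#' @param wk a [windkessel_params()].
#' @param noise_frac nonnegative relative perturbation (0.1 = +/-10%).
#' @param seed integer seed.
#' @param dt simulation time step (ms).
#' @return List with `P`, `V` ([trace()]s), `biomarkers` (perturbed targets),
#'   `clean_biomarkers`, and `beat` (the full `beat_result`).
#' @export
synthetic_clinical_data <- function(true_tanh = tanh_params(),
                                    true_valves = valve_params(),
                                    cfg = surrogate_lv_config(),
                                    wk = windkessel_params(),
                                    noise_frac = 0, seed = 1, dt = 0.5) {
  stopifnot(noise_frac >= 0)
  beat <- simulate_beat(cfg, true_tanh, true_valves, wk, dt = dt)
  clean <- beat_biomarkers(beat, t_act = cfg$t_act)
  bm <- clean
  if (noise_frac > 0) {
    set.seed(seed)
    fac <- 1 + stats::runif(length(bm), -noise_frac, noise_frac)
    for (i in seq_along(bm)) bm[[i]] <- bm[[i]] * fac[i]
  }
  list(P = beat$P, V = beat$V, biomarkers = bm, clean_biomarkers = clean,
       beat = beat)
}
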