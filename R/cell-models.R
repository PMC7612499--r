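# 0D cellular models: phenomenological Tanh active stress (low-fidelity),
# phenomenological double-exponential calcium transient (Rice-type),
# biophysically detailed Land-type crossbridge active stress (high-fidelity),
# and the three-element viscoelastic passive element.
#
# Units: time ms, stress kPa, calcium uM, stretch dimensionless.

#' Parameters of the Tanh active-stress model
#'
#' The low-fidelity model: a stress transient shaped by two squared
#' hyperbolic tangents,
#' `Sa(ts) = Smax * tanh^2(ts / tauSR) * tanh^2((tCR - ts) / tauSD)`
#' for `0 <= ts <= tCR` (time since activation) and 0 outside. Length
#' dependence is neutral by default: `Smax(lam) = Smax_ref * (1 +
#' ld_smax * (lam - 1))` and `tauSR(lam) = tauSR_ref * (1 + ld_tau *
#' (1 - lam))`, with both coefficients 0 unless supplied.
#'
#' @param Smax_ref reference peak active stress (kPa).
#' @param tauSR_ref reference rise time constant (ms).
#' @param tauSD decay time constant (ms).
#' @param tCR transient duration (ms), must exceed `tauSR_ref`.
#' @param ld_smax,ld_tau length-dependence coefficients (default 0: neutral).
#' @return Named list of class `tanh_params`.
#' @export
tanh_params <- function(Smax_ref = 38, tauSR_ref = 110, tauSD = 45,
                        tCR = 500, ld_smax = 0, ld_tau = 0) {
  stopifnot(Smax_ref > 0, tauSR_ref > 0, tauSD > 0, tCR > 0)
  if (tCR <= tauSR_ref)
    stop("tCR must exceed tauSR_ref", call. = FALSE)
  structure(list(Smax_ref = Smax_ref, tauSR_ref = tauSR_ref, tauSD = tauSD,
                 tCR = tCR, ld_smax = ld_smax, ld_tau = ld_tau),
            class = "tanh_params")
}

#' Tanh active stress at a given time since activation
#'
#' @param t_since_act time since electrical activation (ms); may be a vector.
#' @param p a [tanh_params()].
#' @param lam fibre stretch (default 1; only matters with non-neutral length
#'   dependence).
#' @return Active stress (kPa), 0 outside `[0, tCR]`, never negative.
#' @export
tanh_active_stress <- function(t_since_act, p, lam = 1) {
  smax <- p$Smax_ref * (1 + p$ld_smax * (lam - 1))
  tausr <- p$tauSR_ref * (1 + p$ld_tau * (1 - lam))
  s <- smax * tanh(pmax(t_since_act, 0) / tausr)^2 *
    tanh(pmax(p$tCR - t_since_act, 0) / p$tauSD)^2
  s[t_since_act < 0 | t_since_act > p$tCR] <- 0
  pmax(s, 0)
}

#' Parameters of the phenomenological calcium transient
#'
#' A double-exponential intracellular calcium transient (Rice-type):
#' `Ca(ts) = Ca_res + (Ca_max - Ca_res) * g(ts)` where
#' `g(ts) = |exp(-ts/tauCD) - exp(-ts/tauCR)|` normalised so that its peak is
#' exactly 1. The normalisation pins the trace maximum to `Ca_max`, which
#' makes `Ca_max` an interpretable bound during fitting. The equal-time-
#' constant case is handled by the analytic limit `ts/tau * exp(1 - ts/tau)`.
#'
#' @param Ca_res resting calcium (uM), `0 < Ca_res < Ca_max`.
#' @param Ca_max peak calcium (uM).
#' @param tauCR rise time constant (ms).
#' @param tauCD decay time constant (ms).
#' @return Named list of class `rice_params`.
#' @export
rice_params <- function(Ca_res = 0.076, Ca_max = 0.9,
                        tauCR = 164.4, tauCD = 149.0) {
  stopifnot(Ca_res > 0, Ca_max > Ca_res, tauCR > 0, tauCD > 0)
  structure(list(Ca_res = Ca_res, Ca_max = Ca_max,
                 tauCR = tauCR, tauCD = tauCD), class = "rice_params")
}

#' Calcium transient value at a given time since activation
#'
#' @param t_since_act time since electrical activation (ms); vectorised.
#'   Negative times return `Ca_res`.
#' @param p a [rice_params()].
#' @return Calcium concentration (uM).
#' @export
rice_calcium <- function(t_since_act, p) {
  ts <- pmax(t_since_act, 0)
  t1 <- p$tauCD; t2 <- p$tauCR
  if (abs(t1 - t2) < 1e-9 * max(t1, t2)) {
    g <- ts / t2 * exp(1 - ts / t2)
  } else {
    tpk <- log(t1 / t2) * t1 * t2 / (t1 - t2)
    gpk <- abs(exp(-tpk / t1) - exp(-tpk / t2))
    g <- abs(exp(-ts / t1) - exp(-ts / t2)) / gpk
  }
  out <- p$Ca_res + (p$Ca_max - p$Ca_res) * g
  out[t_since_act < 0] <- p$Ca_res
  out
}

#' Parameters of the Land-type crossbridge active-stress model
#'
#' Biophysically detailed high-fidelity model with troponin binding,
#' tropomyosin blocking and weak/strong crossbridge states with distortion
#' variables. Fitted parameters default to a representative personalised set;
#' the remaining kinetic constants are the published reference values of the
#' human model. Calcium sensitivity is length dependent through
#' `Ca50(lam) = Ca50_ref * (1 + beta1 * (lam - 1))` and tension through the
#' factor `h(lam) = max(0, 1 + beta0 * (lam + min(lam, 0.87) - 1.87))`, with
#' `lam` capped at 1.2 inside the model.
#'
#' @param Tref reference tension scale (kPa).
#' @param Ca50_ref reference calcium sensitivity (uM).
#' @param nTRPN troponin Hill coefficient (>= 1).
#' @param kTRPN troponin rate (1/ms).
#' @param nTm tropomyosin Hill coefficient (>= 1).
#' @param kUW weak-crossbridge attachment rate (1/ms).
#' @param kWS weak-to-strong transition rate (1/ms).
#' @param beta0 length dependence of tension.
#' @param beta1 length dependence of Ca50.
#' @param TRPN50,ku,rw,rs,TotA,gammaW,gammaS,phi remaining kinetic constants.
#' @return Named list of class `land_params`.
#' @export
land_params <- function(Tref = 120, Ca50_ref = 0.501, nTRPN = 3.22,
                        kTRPN = 0.1, nTm = 5.47, kUW = 0.046, kWS = 0.012,
                        beta0 = 2.3, beta1 = -1.21, TRPN50 = 0.35,
                        ku = 0.04, rw = 0.5, rs = 0.25, TotA = 25,
                        gammaW = 0.615, gammaS = 0.0085, phi = 2.23) {
  stopifnot(Tref > 0, Ca50_ref > 0, nTRPN >= 1, nTm >= 1,
            kTRPN > 0, kUW > 0, kWS > 0, rw > 0, rw < 1, rs > 0, rs < 1)
  structure(list(Tref = Tref, Ca50_ref = Ca50_ref, nTRPN = nTRPN,
                 kTRPN = kTRPN, nTm = nTm, kUW = kUW, kWS = kWS,
                 beta0 = beta0, beta1 = beta1, TRPN50 = TRPN50, ku = ku,
                 rw = rw, rs = rs, TotA = TotA, gammaW = gammaW,
                 gammaS = gammaS, phi = phi), class = "land_params")
}

#' Parameters of the three-element passive element
#'
#' A nonlinear parallel spring plus a spring-dashpot branch:
#' `Sp = a_p * (expm1(b * C) + k * (C - Cd))` with `C = lam - 1` and internal
#' (dashpot) strain `Cd` evolving as `dCd/dt = k * (C - Cd) / eta`, where
#' `eta = eta_l` when `(C - Cd) < 0` (lengthening of the dashpot) and `eta_s`
#' otherwise.
#' At `lam = 1` with `Cd = 0` the element is stress free. The stiffness scale
#' `a_p` is the single knob used to control the minimum stretch of the 0D
#' electromechanics model; it absorbs organ-scale boundary-condition effects
#' and need not be physiological as a single-cell stiffness.
#'
#' @param a_p stiffness scale (kPa).
#' @param b stiffening exponent of the parallel elastic branch.
#' @param k dimensionless stiffness ratio of the series branch.
#' @param eta_l,eta_s viscous time scales (ms) for lengthening / shortening
#'   of the dashpot.
#' @return Named list of class `land_passive_params`.
#' @export
land_passive_params <- function(a_p = 42, b = 9.1, k = 7, eta_l = 200,
                                eta_s = 20) {
  stopifnot(a_p > 0, b > 0, k > 0, eta_l > 0, eta_s > 0)
  structure(list(a_p = a_p, b = b, k = k, eta_l = eta_l, eta_s = eta_s),
            class = "land_passive_params")
}

#' Resting cell state for the coupled Land + passive model
#'
#' Troponin occupancy is initialised at its steady state for the resting
#' calcium, the tropomyosin blocked fraction at its corresponding balance,
#' crossbridge fractions and distortions at 0, and the passive internal
#' strain `Cd` such that the passive element carries zero stress at the
#' initial stretch (`Cd = C0 + expm1(b * C0) / k` with `C0 = lam0 - 1`), so
#' the force balance is consistent at t = 0.
#'
#' @param p a [land_params()].
#' @param ca_rest resting calcium (uM).
#' @param lam0 initial stretch.
#' @param pp a [land_passive_params()].
#' @return Named numeric vector `(XS, XW, CaTRPN, TmB, ZetaS, ZetaW, Cd)`.
#' @export
land_rest_state <- function(p, ca_rest, lam0 = 1,
                            pp = land_passive_params()) {
  ca50 <- p$Ca50_ref * (1 + p$beta1 * (min(lam0, 1.2) - 1))
  r <- (ca_rest / ca50)^p$nTRPN
  catrpn <- max(r / (1 + r), 1e-8)
  kb <- p$ku * p$TRPN50^p$nTm / (1 - p$rs - (1 - p$rs) * p$rw)
  bu <- kb * min(100, catrpn^(-p$nTm / 2))   # blocking rate * XU
  ub <- p$ku * catrpn^(p$nTm / 2)            # unblocking rate * TmB
  tmb <- bu / (bu + ub)
  c(XS = 0, XW = 0, CaTRPN = catrpn, TmB = tmb, ZetaS = 0, ZetaW = 0,
    Cd = (lam0 - 1) + expm1(pp$b * (lam0 - 1)) / pp$k)
}

# derived rate constants of the Land model
.land_rates <- function(p) {
  list(kwu = p$kUW * (1 / p$rw - 1) - p$kWS,
       ksu = p$kWS * p$rw * (1 / p$rs - 1),
       Aw = p$TotA * p$rs / ((1 - p$rs) * p$rw + p$rs),
       As = p$TotA * p$rs / ((1 - p$rs) * p$rw + p$rs),
       cw = p$phi * p$kUW * ((1 - p$rs) * (1 - p$rw)) / ((1 - p$rs) * p$rw),
       cs = p$phi * p$kWS * ((1 - p$rs) * p$rw) / p$rs,
       kb = p$ku * p$TRPN50^p$nTm / (1 - p$rs - (1 - p$rs) * p$rw))
}

#' Right-hand side of the Land active-stress ODEs
#'
#' Computes the time derivative of the active cell state and the current
#' active stress, given instantaneous calcium, stretch and stretch rate.
#' Active stress is returned as computed (it can transiently be negative with
#' extreme distortions); physiological-range checking is the calibration
#' constraints' job, not the model's.
#'
#' @param state named numeric vector as from [land_rest_state()] (the `Cd`
#'   entry, if present, is ignored here).
#' @param ca intracellular calcium (uM).
#' @param lam fibre stretch.
#' @param dlam_dt stretch rate (1/ms).
#' @param p a [land_params()].
#' @return List with `dstate` (named derivative vector over the six active
#'   states) and `Sa` (kPa).
#' @export
land_active_rhs <- function(state, ca, lam, dlam_dt, p) {
  if (!all(is.finite(c(state, ca, lam, dlam_dt))))
    stop("non-finite input to land_active_rhs", call. = FALSE)
  r <- .land_rates(p)
  lams <- min(lam, 1.2)
  ca50 <- p$Ca50_ref * (1 + p$beta1 * (lams - 1))
  XS <- state[["XS"]]; XW <- state[["XW"]]
  catrpn <- max(state[["CaTRPN"]], 1e-8)
  tmb <- state[["TmB"]]
  zs <- state[["ZetaS"]]; zw <- state[["ZetaW"]]
  XU <- 1 - tmb - XS - XW
  gwu <- p$gammaW * abs(zw)
  gsu <- p$gammaS * max(zs * (zs > 0), (-zs - 1) * (zs < -1))
  dXS <- p$kWS * XW - r$ksu * XS - gsu * XS
  dXW <- p$kUW * XU - r$kwu * XW - p$kWS * XW - gwu * XW
  dca <- p$kTRPN * ((ca / ca50)^p$nTRPN * (1 - catrpn) - catrpn)
  dtmb <- r$kb * min(100, catrpn^(-p$nTm / 2)) * XU -
    p$ku * catrpn^(p$nTm / 2) * tmb
  dzs <- r$As * dlam_dt - r$cs * zs
  dzw <- r$Aw * dlam_dt - r$cw * zw
  h <- max(0, 1 + p$beta0 * (lams + min(lams, 0.87) - 1.87))
  sa <- h * p$Tref / p$rs * (XS * (zs + 1) + XW * zw)
  list(dstate = c(XS = dXS, XW = dXW, CaTRPN = dca, TmB = dtmb,
                  ZetaS = dzs, ZetaW = dzw),
       Sa = sa)
}

#' Three-element passive stress and internal-state derivative
#'
#' @param state named numeric vector containing `Cd` (internal strain).
#' @param lam fibre stretch (> 0).
#' @param pp a [land_passive_params()].
#' @return List with `dCd` and `Sp` (kPa).
#' @export
land_passive <- function(state, lam, pp) {
  stopifnot(lam > 0)
  C <- lam - 1
  cd <- state[["Cd"]]
  eta <- if (C - cd < 0) pp$eta_l else pp$eta_s
  list(dCd = pp$k * (C - cd) / eta,
       Sp = pp$a_p * (expm1(pp$b * C) + pp$k * (C - cd)))
}

#' Limit-cycle (steady-state) initialisation of a periodic cell simulation
#'
#' Repeats beats of a one-beat simulator until the cell state at the beat
#' boundary stops changing (max-norm below `tol`). Models are always started
#' from the steady state for the cycle length at hand; whenever parameters
#' change, the steady state must be recomputed.
#'
#' @param beat_fn function `(state) -> list(state = end-of-beat state, ...)`
#'   simulating exactly one cycle.
#' @param state0 initial state vector.
#' @param tol max-norm tolerance on the beat-boundary state difference.
#' @param max_beats maximum number of beats.
#' @return List `(state, n_beats, residuals, converged, last)` where `last`
#'   is the full return value of the final `beat_fn` call.
#' @export
limit_cycle <- function(beat_fn, state0, tol = 1e-6, max_beats = 50) {
  state <- state0
  residuals <- numeric(0)
  out <- NULL
  for (b in seq_len(max_beats)) {
    out <- beat_fn(state)
    res <- max(abs(out$state - state))
    residuals <- c(residuals, res)
    state <- out$state
    if (res < tol)
      return(list(state = state, n_beats = b, residuals = residuals,
                  converged = TRUE, last = out))
  }
  stop(sprintf(
    "limit cycle did not converge in %d beats (last residual %.3g)",
    max_beats, residuals[length(residuals)]), call. = FALSE)
}

#' Default model parameters, bounds and fitted-parameter registry
#'
#' Reads the packaged JSON of default parameter values for every model
#' (`"tanh"`, `"rice"`, `"land"`, `"land-passive"`) together with the default
#' fitted-parameter subset and its bounds (plus/minus 50% of the defaults).
#'
#' @return Nested list mirroring the packaged JSON.
#' @export
default_model_parameters <- function() {
  jsonlite::read_json(system.file("extdata", "default_parameters.json",
                                  package = "myofit"),
                      simplifyVector = TRUE)
}
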