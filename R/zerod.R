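# 0D cellular electromechanics: the stretch trajectory of a cardiomyocyte is
# obtained from the equilibrium of active and passive stress,
#   Sa(Ca, lambda, dlambda/dt, t) + Sp(lambda, t) = 0,  lambda(0) = lambda0.
# The stretch rate entering the active model is lagged by one time step
# (staggered, stabilised update); each step then solves a scalar nonlinear
# equation for lambda by safeguarded Newton with bisection fallback,
# tolerance 1e-6 kPa on the force-balance residual.

.land_vec <- function(p) unlist(p[c("Tref", "Ca50_ref", "nTRPN", "kTRPN",
                                    "nTm", "kUW", "kWS", "beta0", "beta1",
                                    "TRPN50", "ku", "rw", "rs", "TotA",
                                    "gammaW", "gammaS", "phi")])

#' Solve the 0D stretch-equilibrium electromechanics model
#'
#' Integrates the coupled cell model over repeated cycles (activation at the
#' start of each cycle) until the state is periodic at the beat boundary, and
#' returns the final beat. With `max_beats = 1` a single transient beat from
#' `lam0` is returned. Calcium is either generated by the phenomenological
#' transient model (`calcium` a [rice_params()]) or prescribed as a [trace()]
#' aligned so that activation is at t = 0.
#'
#' @param active active-stress model parameters: a [land_params()] (compiled
#'   fast path) or a [tanh_params()] (pure R).
#' @param passive a [land_passive_params()].
#' @param calcium a [rice_params()] or a calcium [trace()]; ignored for a
#'   Tanh active model.
#' @param lam0 initial stretch (> 0).
#' @param cycle_length cycle length T in ms.
#' @param dt output time step in ms (default 0.1).
#' @param max_beats maximum number of beats for the limit cycle (default 30).
#' @param beat_tol max-norm tolerance on the beat-boundary state difference.
#' @param newton_tol force-balance residual tolerance in kPa.
#' @param engine `"cpp"` (default, Land only) or `"r"` (reference
#'   implementation used for cross-checking).
#' @return An object of class `zerod_result`: traces `lam`, `dlam_dt`, `sa`,
#'   `ca`, plus `residual_max` (kPa), `n_beats`, `converged`.
#' @export
solve_stretch_equilibrium <- function(active, passive, calcium = rice_params(),
                                      lam0 = 1.1, cycle_length = 1000,
                                      dt = 0.1, max_beats = 30,
                                      beat_tol = 1e-4, newton_tol = 1e-6,
                                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(lam0 > 0, cycle_length > 0, dt > 0)
  if (inherits(active, "tanh_params"))
    return(.zerod_tanh(active, passive, lam0, cycle_length, dt,
                       max_beats, beat_tol, newton_tol))
  stopifnot(inherits(active, "land_params"),
            inherits(passive, "land_passive_params"))
  ca_rest <- if (inherits(calcium, "trace")) calcium$values[1] else calcium$Ca_res
  state0 <- land_rest_state(active, ca_rest, lam0, passive)
  if (engine == "cpp") {
    if (inherits(calcium, "trace")) {
      ca_vals <- calcium$values; ca_dt <- calcium$dt; ca_t0 <- calcium$t0
      rice <- c(Ca_res = 0, Ca_max = 1, tauCR = 1, tauCD = 1)
    } else {
      ca_vals <- numeric(0); ca_dt <- 1; ca_t0 <- 0
      rice <- unlist(calcium[c("Ca_res", "Ca_max", "tauCR", "tauCD")])
    }
    out <- .zerod_simulate_cpp(.land_vec(active), rice,
                               unlist(passive[c("a_p", "b", "k", "eta_l", "eta_s")]),
                               unname(state0), lam0, cycle_length, dt,
                               as.integer(max_beats), beat_tol, newton_tol,
                               ca_vals, ca_dt, ca_t0)
  } else {
    out <- .zerod_r_engine(active, passive, calcium, state0, lam0,
                           cycle_length, dt, max_beats, beat_tol, newton_tol)
  }
  structure(list(lam = trace(out$lam, dt = dt),
                 dlam_dt = trace(out$dlam_dt, dt = dt),
                 sa = trace(out$sa, dt = dt),
                 ca = trace(out$ca, dt = dt),
                 residual_max = out$residual_max,
                 n_beats = out$n_beats,
                 converged = out$converged),
            class = "zerod_result")
}

#' @export
print.zerod_result <- function(x, ...) {
  cat(sprintf(
    "<zerod_result> %d beats to limit cycle (converged: %s)\n",
    x$n_beats, x$converged))
  cat(sprintf("  lambda_min = %.4f, Sa_max = %.2f kPa, residual_max = %.2g kPa\n",
              min(x$lam$values), max(x$sa$values), x$residual_max))
  invisible(x)
}

#' Export a 0D electromechanics result as multi-column CSV
#'
#' Columns: `time_ms`, `lambda`, `dlambda_dt`, `Sa_kPa`, `Ca_uM`.
#'
#' @param x a `zerod_result`.
#' @param path file path.
#' @export
write_zerod_csv <- function(x, path) {
  utils::write.csv(data.frame(time_ms = trace_times(x$lam),
                              lambda = x$lam$values,
                              dlambda_dt = x$dlam_dt$values,
                              Sa_kPa = x$sa$values,
                              Ca_uM = x$ca$values),
                   path, row.names = FALSE)
  invisible(path)
}

# pure-R reference integrator, mirroring the compiled core: RK4 on the slow
# states (crossbridge fractions, troponin, tropomyosin, passive internal
# strain) with stretch frozen at the previous step, distortion states
# advanced by implicit Euler as functions of the new stretch inside the
# per-step equilibrium solve (the stabilisation that keeps the massless
# force balance well posed), safeguarded Newton with bisection fallback.
.zerod_r_engine <- function(active, passive, calcium, state0, lam0,
                            cycle_length, dt, max_beats, beat_tol,
                            newton_tol) {
  ca_at <- function(ts) {
    if (inherits(calcium, "trace")) trace_at(calcium, ts)
    else rice_calcium(ts, calcium)
  }
  r <- .land_rates(active)
  nstep <- round(cycle_length / dt)
  slow_names <- c("XS", "XW", "CaTRPN", "TmB", "Cd")
  deriv <- function(s, zs, zw, ca, lam) {
    full <- c(s[1:4], ZetaS = zs, ZetaW = zw)
    a <- land_active_rhs(full, ca, lam, 0, active)
    p <- land_passive(s, lam, passive)
    c(a$dstate[c("XS", "XW", "CaTRPN", "TmB")], Cd = p$dCd)
  }
  zs_of <- function(zs0, lam, lam_prev)
    (zs0 + r$As * (lam - lam_prev)) / (1 + r$cs * dt)
  zw_of <- function(zw0, lam, lam_prev)
    (zw0 + r$Aw * (lam - lam_prev)) / (1 + r$cw * dt)
  sa_of <- function(s, zs0, zw0, lam, lam_prev)
    .sa_at(c(XS = s[["XS"]], XW = s[["XW"]],
             ZetaS = zs_of(zs0, lam, lam_prev),
             ZetaW = zw_of(zw0, lam, lam_prev)), lam, active)
  sa_now <- function(s, zs, zw, lam)
    .sa_at(c(XS = s[["XS"]], XW = s[["XW"]], ZetaS = zs, ZetaW = zw),
           lam, active)
  s <- state0[slow_names]
  zs <- state0[["ZetaS"]]; zw <- state0[["ZetaW"]]
  lam <- lam0; dlam <- 0
  converged <- FALSE; beats <- 0; residual_max <- 0
  for (b in seq_len(max_beats)) {
    start <- c(s, zs = zs, zw = zw, lam = lam)
    lam_tr <- dlam_tr <- sa_tr <- ca_tr <- numeric(nstep + 1)
    lam_tr[1] <- lam; dlam_tr[1] <- dlam
    sa_tr[1] <- sa_now(s, zs, zw, lam); ca_tr[1] <- ca_at(0)
    residual_max <- 0
    for (k in seq_len(nstep)) {
      t <- (k - 1) * dt
      k1 <- deriv(s, zs, zw, ca_at(t), lam)
      k2 <- deriv(s + dt / 2 * k1, zs, zw, ca_at(t + dt / 2), lam)
      k3 <- deriv(s + dt / 2 * k2, zs, zw, ca_at(t + dt / 2), lam)
      k4 <- deriv(s + dt * k3, zs, zw, ca_at(t + dt), lam)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      f <- function(l) sa_of(s, zs, zw, l, lam) +
        land_passive(s, l, passive)$Sp
      lam_new <- .safe_root(f, lam, 0.3, 1.8, newton_tol)
      residual_max <- max(residual_max, abs(f(lam_new)))
      zs <- zs_of(zs, lam_new, lam)
      zw <- zw_of(zw, lam_new, lam)
      dlam <- (lam_new - lam) / dt
      lam <- lam_new
      lam_tr[k + 1] <- lam; dlam_tr[k + 1] <- dlam
      sa_tr[k + 1] <- sa_now(s, zs, zw, lam)
      ca_tr[k + 1] <- ca_at(t + dt)
    }
    beats <- b
    if (max(abs(c(s, zs = zs, zw = zw, lam = lam) - start)) < beat_tol) {
      converged <- TRUE; break
    }
  }
  list(lam = lam_tr, dlam_dt = dlam_tr, sa = sa_tr, ca = ca_tr,
       residual_max = residual_max, n_beats = beats, converged = converged)
}

# instantaneous active stress at fixed state (lambda enters via its length
# dependence only)
.sa_at <- function(s, lam, p) {
  lams <- min(lam, 1.2)
  h <- max(0, 1 + p$beta0 * (lams + min(lams, 0.87) - 1.87))
  h * p$Tref / p$rs * (s[["XS"]] * (s[["ZetaS"]] + 1) +
                         s[["XW"]] * s[["ZetaW"]])
}

# bisection-safeguarded scalar root solve on [lo, hi]; f(lo) <= 0 <= f(hi)
.safe_root <- function(f, guess, lo, hi, tol) {
  flo <- f(lo); fhi <- f(hi)
  if (!(flo <= 0 && fhi >= 0))
    stop("stretch equilibrium leaves the admissible bracket", call. = FALSE)
  lam <- if (guess > lo && guess < hi) guess else (lo + hi) / 2
  for (it in 1:200) {
    fv <- f(lam)
    if (abs(fv) < tol) return(lam)
    if (fv > 0) hi <- lam else lo <- lam
    lam <- (lo + hi) / 2
  }
  lam
}

# Tanh active model has no internal state: the equilibrium at each time is a
# scalar solve with only the passive internal strain as dynamic state
.zerod_tanh <- function(active, passive, lam0, cycle_length, dt,
                        max_beats, beat_tol, newton_tol) {
  nstep <- round(cycle_length / dt)
  s <- c(Cd = (lam0 - 1) + expm1(passive$b * (lam0 - 1)) / passive$k)
  lam <- lam0
  converged <- FALSE; beats <- 0; residual_max <- 0
  for (b in seq_len(max_beats)) {
    start <- c(s, lam = lam)
    lam_tr <- dlam_tr <- sa_tr <- numeric(nstep + 1)
    lam_tr[1] <- lam
    sa_tr[1] <- tanh_active_stress(0, active, lam)
    residual_max <- 0
    for (k in seq_len(nstep)) {
      t <- k * dt
      p0 <- land_passive(s, lam, passive)
      s[["Cd"]] <- s[["Cd"]] + dt * p0$dCd
      f <- function(l) tanh_active_stress(t, active, l) +
        land_passive(s, l, passive)$Sp
      lam_new <- .safe_root(f, lam, 0.3, 1.8, newton_tol)
      residual_max <- max(residual_max, abs(f(lam_new)))
      dlam_tr[k + 1] <- (lam_new - lam) / dt
      lam <- lam_new
      lam_tr[k + 1] <- lam
      sa_tr[k + 1] <- tanh_active_stress(t, active, lam)
    }
    beats <- b
    if (max(abs(c(s, lam = lam) - start)) < beat_tol) {
      converged <- TRUE; break
    }
  }
  structure(list(lam = trace(lam_tr, dt = dt),
                 dlam_dt = trace(dlam_tr, dt = dt),
                 sa = trace(sa_tr, dt = dt),
                 ca = trace(rep(0, nstep + 1), dt = dt),
                 residual_max = residual_max, n_beats = beats,
                 converged = converged),
            class = "zerod_result")
}
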