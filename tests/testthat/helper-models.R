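# shared fixtures: small, fast model configurations used across tests

default_truth <- function() {
  list(tanh = tanh_params(), valves = valve_params(),
       cfg = surrogate_lv_config(), wk = windkessel_params())
}

# quick 0D cell run at reduced resolution (dt in ms)
quick_zerod <- function(land = land_params(), ap = 42, rice = rice_params(),
                        dt = 0.2, ...) {
  solve_stretch_equilibrium(land, land_passive_params(a_p = ap), rice,
                            dt = dt, ...)
}

# triangular pulse trace: base -> peak -> base, linear segments
triangle_trace <- function(peak = 100, t_peak = 100, t_end = 200, dt = 1,
                           base = 0, total = t_end) {
  tt <- seq(0, total, by = dt)
  v <- ifelse(tt <= t_peak, base + (peak - base) * tt / t_peak,
              pmax(base, peak - (peak - base) * (tt - t_peak) /
                     (t_end - t_peak)))
  trace(v, dt = dt)
}
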