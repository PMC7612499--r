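#' Two-step multi-fidelity personalisation of active mechanics
#'
#' The package's main fitting function. Step 1 calibrates the
#' phenomenological Tanh active-stress model and the valve forward
#' resistances at the organ scale ([calibrate_step1()]) against pressure and
#' volume biomarkers extracted from the supplied traces (or supplied
#' directly). Step 2 then generates a heterogeneous nodal ensemble from the
#' personalised beat, forms median traces aligned by nodal activation time,
#' and calibrates the detailed crossbridge and calcium models plus the
#' passive stiffness at the cell scale ([calibrate_step2()]).
#'
#' @param pressure clinical-style pressure [trace()] (mmHg), or `NULL` when
#'   `biomarkers` is given.
#' @param volume clinical-style volume [trace()] (mL), or `NULL`.
#' @param biomarkers optional precomputed biomarker targets (`Pmax`,
#'   `dPdt_max`, `dPdt_min`, `PTD90`, and optionally `tauVD`, `tauVR`);
#'   overrides trace extraction.
#' @param cfg surrogate ventricle configuration ([surrogate_lv_config()]).
#' @param wk afterload ([windkessel_params()]).
#' @param p0,valves0 step-1 initial guesses.
#' @param threshold step-1 convergence threshold (default 0.1).
#' @param n_nodes ensemble size for the median traces.
#' @param heterogeneity ensemble heterogeneity (see [nodal_ensemble()]).
#' @param seed integer seed for the ensemble and the DE optimiser.
#' @param step2 logical; run the cell-scale step (default TRUE).
#' @param step2_args extra arguments passed to [calibrate_step2()].
#' @param ejection_window,filling_window phase windows (ms) for volume
#'   biomarker extraction from a supplied volume trace; required when
#'   `volume` is given without `biomarkers`.
#' @param dt surrogate simulation step (ms).
#' @return Object of class `lv_personalisation` with components `step1`
#'   (`step1_fit`), `step2` (`step2_fit` or `NULL`), `medians` (list of
#'   median traces), `targets`, `cfg`, `wk`, `seed`.
#' @seealso [simulate.lv_personalisation()], [residuals.lv_personalisation()]
#' @examples
#' \donttest{
#' syn <- synthetic_clinical_data(noise_frac = 0.05, seed = 7)
#' fit <- personalise_lv(biomarkers = syn$biomarkers, step2 = FALSE)
#' coef(fit)
#' }
#' @export
personalise_lv <- function(pressure = NULL, volume = NULL, biomarkers = NULL,
                           cfg = surrogate_lv_config(),
                           wk = windkessel_params(),
                           p0 = tanh_params(), valves0 = valve_params(),
                           threshold = 0.1, n_nodes = 51,
                           heterogeneity = list(act_spread = 40,
                                                amp_cv = 0.1,
                                                stretch_sd = 0.02),
                           seed = 1, step2 = TRUE, step2_args = list(),
                           ejection_window = NULL, filling_window = NULL,
                           dt = 0.5) {
  if (is.null(biomarkers)) {
    if (is.null(pressure))
      stop("either traces or biomarker targets must be supplied",
           call. = FALSE)
    biomarkers <- unclass(pressure_biomarkers(pressure, t_act = cfg$t_act))
    if (!is.null(volume)) {
      if (is.null(ejection_window) || is.null(filling_window))
        stop("ejection_window and filling_window are required with a volume trace",
             call. = FALSE)
      biomarkers <- c(biomarkers,
                      unclass(volume_biomarkers(volume, ejection_window,
                                                filling_window)))
    }
  }
  s1 <- calibrate_step1(biomarkers, p0 = p0, valves0 = valves0, cfg = cfg,
                        wk = wk, threshold = threshold, dt = dt)
  medians <- NULL
  s2 <- NULL
  if (step2) {
    beat <- simulate_beat(cfg, s1$tanh_p, s1$valves, wk, dt = dt)
    ens <- nodal_ensemble(beat, n_nodes = n_nodes,
                          heterogeneity = heterogeneity, seed = seed)
    medians <- list(
      sa = align_and_median(ens$sa, ens$activation_times),
      ca = align_and_median(ens$ca, ens$activation_times),
      lam = align_and_median(ens$lam, ens$activation_times))
    s2 <- do.call(calibrate_step2, c(
      list(median_sa = medians$sa, median_lam = medians$lam,
           cycle_length = cfg$cycle_length,
           de_config = utils::modifyList(
             list(seed = seed),
             if (!is.null(step2_args$de_config)) step2_args$de_config
             else list())),
      step2_args[setdiff(names(step2_args), "de_config")]))
  }
  structure(list(step1 = s1, step2 = s2, medians = medians,
                 targets = biomarkers, cfg = cfg, wk = wk, seed = seed),
            class = "lv_personalisation")
}

#' @export
print.lv_personalisation <- function(x, ...) {
  cat("Two-step active-mechanics personalisation\n")
  cat("Step 1 (organ scale): "); print(x$step1)
  if (!is.null(x$step2)) {
    cat("Step 2 (cell scale):  "); print(x$step2)
  } else cat("Step 2 (cell scale):  not run\n")
  invisible(x)
}

#' @export
summary.lv_personalisation <- function(object, ...) {
  summary(object$step1)
  if (!is.null(object$step2)) { cat("\n"); summary(object$step2) }
  invisible(object)
}

#' @export
coef.lv_personalisation <- function(object, ...) {
  out <- list(step1 = coef(object$step1))
  if (!is.null(object$step2)) out$step2 <- coef(object$step2)
  out
}

#' Simulate from a personalised model
#'
#' Re-runs the organ-scale surrogate beat with the fitted step-1 parameters
#' (`what = "beat"`), or the cell-scale 0D electromechanics model with the
#' fitted step-2 parameters (`what = "cell"`).
#'
#' @param object an `lv_personalisation`.
#' @param nsim,seed unused (the model is deterministic at fixed parameters);
#'   present for the generic's signature.
#' @param what `"beat"` or `"cell"`.
#' @param ... passed to [simulate_beat()] / [solve_stretch_equilibrium()].
#' @return A `beat_result` or a `zerod_result`.
#' @export
simulate.lv_personalisation <- function(object, nsim = 1, seed = NULL,
                                        what = c("beat", "cell"), ...) {
  what <- match.arg(what)
  if (what == "beat")
    return(simulate_beat(object$cfg, object$step1$tanh_p,
                         object$step1$valves, object$wk, ...))
  if (is.null(object$step2)) stop("step 2 was not run", call. = FALSE)
  mods <- .assemble_models(coef(object$step2))
  solve_stretch_equilibrium(mods$land, mods$passive, calcium = mods$rice,
                            lam0 = object$medians$lam$values[1],
                            cycle_length = object$cfg$cycle_length, ...)
}

#' Biomarker residuals of a personalised model
#'
#' Relative residuals `(simulated - target) / target` of the step-1
#' pressure/volume biomarkers and, when step 2 was run, of the stress
#' biomarkers and the minimum stretch.
#'
#' @param object an `lv_personalisation`.
#' @param ... unused.
#' @return Named numeric vector of relative residuals.
#' @export
residuals.lv_personalisation <- function(object, ...) {
  nm <- intersect(names(object$targets), names(object$step1$biomarkers))
  r1 <- (unlist(object$step1$biomarkers[nm]) - unlist(object$targets[nm])) /
    unlist(object$targets[nm])
  names(r1) <- paste0("step1.", nm)
  out <- r1
  if (!is.null(object$step2)) {
    tv <- unlist(object$step2$targets$stress)
    sv <- unlist(object$step2$biomarkers)[names(tv)]
    r2 <- (sv - tv) / tv
    names(r2) <- paste0("step2.", names(tv))
    rl <- (object$step2$lambda_min - object$step2$targets$lambda_min) /
      object$step2$targets$lambda_min
    out <- c(out, r2, step2.lambda_min = rl)
  }
  out
}

#' @export
plot.lv_personalisation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$step2)) 1 else 2))
  on.exit(graphics::par(op))
  plot(x$step1)
  if (!is.null(x$step2)) plot(x$step2)
  invisible(x)
}

#' Run the full personalisation workflow from a JSON configuration
#'
#' Thin orchestration of the whole pipeline: generate (or read) the
#' clinical-style data, run step 1, generate the nodal median traces, run
#' step 2, and write all artifacts (`step1.json`, `medians.csv`,
#' `step2.json`, `report.json`) into the output directory. Byte-identical
#' results under fixed seeds.
#'
#' Configuration fields: `out_dir` (required); `seed` (default 1);
#' `threshold` (default 0.1); `n_nodes`; `noise_frac`; optional
#' `pressure_csv` / `biomarkers_json` to supply clinical data instead of
#' the synthetic generator; optional `de` (DE controls).
#'
#' @param config path to a JSON file or an equivalent named list.
#' @return (Invisibly) the `lv_personalisation` object; artifacts on disk.
#' @export
run_full_workflow <- function(config) {
  cfgl <- if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config, call. = FALSE)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (is.null(cfgl$out_dir))
    stop("configuration is missing 'out_dir'", call. = FALSE)
  for (f in c("pressure_csv", "biomarkers_json"))
    if (!is.null(cfgl[[f]]) && !file.exists(cfgl[[f]]))
      stop("configured file does not exist: ", cfgl[[f]], call. = FALSE)
  seed <- if (is.null(cfgl$seed)) 1L else as.integer(cfgl$seed)
  dir.create(cfgl$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfgl$out_dir, "workflow.log.jsonl")
  log_line <- function(stage, ...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, seed = seed, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }
  lv_cfg <- surrogate_lv_config()
  if (!is.null(cfgl$biomarkers_json)) {
    bm <- read_biomarkers_json(cfgl$biomarkers_json)
  } else if (!is.null(cfgl$pressure_csv)) {
    p <- read_trace_csv(cfgl$pressure_csv)
    bm <- unclass(pressure_biomarkers(p, t_act = lv_cfg$t_act))
  } else {
    syn <- synthetic_clinical_data(
      noise_frac = if (is.null(cfgl$noise_frac)) 0 else cfgl$noise_frac,
      seed = seed, cfg = lv_cfg)
    bm <- syn$biomarkers
    write_trace_csv(syn$P, file.path(cfgl$out_dir, "pressure.csv"))
    write_trace_csv(syn$V, file.path(cfgl$out_dir, "volume.csv"))
  }
  log_line("data", biomarkers = unclass(bm))
  fit <- tryCatch(
    personalise_lv(biomarkers = bm, cfg = lv_cfg, seed = seed,
                   threshold = if (is.null(cfgl$threshold)) 0.1
                   else cfgl$threshold,
                   n_nodes = if (is.null(cfgl$n_nodes)) 51
                   else cfgl$n_nodes,
                   step2_args = list(
                     de_config = if (is.null(cfgl$de)) list() else cfgl$de)),
    error = function(e)
      stop("workflow failed in personalisation stage: ",
           conditionMessage(e), call. = FALSE))
  jsonlite::write_json(
    list(params = as.list(coef(fit$step1)), cost = fit$step1$cost,
         converged = fit$step1$converged,
         n_iterations = fit$step1$n_iterations),
    file.path(cfgl$out_dir, "step1.json"), auto_unbox = TRUE, digits = NA)
  log_line("step1", n_iterations = fit$step1$n_iterations,
           converged = fit$step1$converged)
  if (!is.null(fit$medians)) {
    m <- fit$medians
    utils::write.csv(data.frame(time_ms = trace_times(m$sa),
                                Sa_kPa = m$sa$values,
                                Ca_uM = trace_at(m$ca, trace_times(m$sa)),
                                lambda = trace_at(m$lam, trace_times(m$sa))),
                     file.path(cfgl$out_dir, "medians.csv"),
                     row.names = FALSE)
  }
  if (!is.null(fit$step2)) {
    jsonlite::write_json(
      list(params = as.list(coef(fit$step2)), value = fit$step2$value,
           n_evaluations = fit$step2$n_evaluations,
           violations = as.list(fit$step2$violations)),
      file.path(cfgl$out_dir, "step2.json"), auto_unbox = TRUE, digits = NA)
    log_line("step2", n_evaluations = fit$step2$n_evaluations)
  }
  jsonlite::write_json(
    list(seed = seed,
         step1_iterations = fit$step1$n_iterations,
         step2_evaluations = if (is.null(fit$step2)) NULL
         else fit$step2$n_evaluations,
         residuals = as.list(residuals(fit))),
    file.path(cfgl$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  log_line("report")
  invisible(fit)
}
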