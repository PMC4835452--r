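# Declarative parameter-sweep runner: builds a drive per swept value,
# simulates, extracts AMP/ISI/FR, and returns one summary row per value.

SWEEPABLE <- c("b_field", "gamma", "freq", "duty_cycle", "rep_freq")

# Stated parameter ranges for each sweepable quantity; values outside are
# refused unless allow_extrapolation is set.
PARAM_RANGES <- list(b_field = c(0.5, 7),      # T
                     gamma = c(1, 100),        # W/cm^2
                     freq = c(200e3, 700e3),   # Hz
                     duty_cycle = c(0.05, 0.95),
                     rep_freq = c(1, 100))     # Hz

#' Define a parameter sweep
#'
#' A sweep varies exactly one stimulation parameter over a list of values
#' while all others stay at the `fixed` drive settings.
#'
#' @param parameter One of `"b_field"`, `"gamma"`, `"freq"`,
#'   `"duty_cycle"`, `"rep_freq"`.
#' @param values Numeric vector of swept values (sorted internally).
#' @param fixed A [drive_spec()] providing every non-swept parameter.
#'   Sweeping `duty_cycle` or `rep_freq` requires a pulsed `fixed` drive.
#' @param sim A [sim_config()], or `NULL` to choose the duration
#'   automatically: 500 ms for continuous drives and
#'   `max(500, 3 repetition periods)` ms for pulsed drives, so even slow
#'   gates see at least three bursts.
#' @param allow_extrapolation Permit values outside the standard
#'   stimulation ranges (0.5-7 T, 1-100 W/cm^2, 200-700 kHz, 5-95% DC,
#'   1-100 Hz RF).
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec("b_field", c(1, 4, 7),
#'            fixed = drive_spec(gamma = 3, b_field = 3, freq = 5e5))
#' @export
sweep_spec <- function(parameter, values, fixed, sim = NULL,
                       allow_extrapolation = FALSE) {
  parameter <- match.arg(parameter, SWEEPABLE)
  stopifnot(inherits(fixed, "drive_spec"))
  if (!is.numeric(values) || length(values) == 0L || !all(is.finite(values))) {
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  }
  values <- sort(unique(values))
  if (!allow_extrapolation) {
    rng <- PARAM_RANGES[[parameter]]
    bad <- values[values < rng[1] | values > rng[2]]
    if (length(bad) > 0) {
      stop(sprintf(
        "swept '%s' value(s) %s outside the standard range [%g, %g]; ",
        parameter, paste(signif(bad, 4), collapse = ", "), rng[1], rng[2]),
        "set allow_extrapolation = TRUE to override", call. = FALSE)
    }
  }
  if (parameter %in% c("duty_cycle", "rep_freq") && fixed$mode != "pulsed") {
    stop(sprintf("sweeping '%s' requires a pulsed 'fixed' drive", parameter),
         call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(parameter = parameter, values = values, fixed = fixed,
                 sim = sim), class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("Sweep of '%s' over %d values: %s\n", x$parameter,
              length(x$values),
              paste(signif(x$values, 4), collapse = ", ")))
  invisible(x)
}

modify_drive <- function(fixed, parameter, value) {
  drive_spec(gamma = if (parameter == "gamma") value else fixed$gamma,
             b_field = if (parameter == "b_field") value else fixed$b_field,
             freq = if (parameter == "freq") value else fixed$freq,
             mode = fixed$mode,
             duty_cycle = if (parameter == "duty_cycle") value else fixed$duty_cycle,
             rep_freq = if (parameter == "rep_freq") value else fixed$rep_freq,
             waveform = fixed$waveform,
             tissue = fixed$tissue)
}

sweep_sim_config <- function(drive, sim) {
  if (!is.null(sim)) return(sim)
  duration <- 500
  if (drive$mode == "pulsed") {
    duration <- max(500, 3 * 1000 / drive$rep_freq)
  }
  sim_config(duration = duration)
}

#' Run a parameter sweep
#'
#' For each swept value: build the drive, simulate, detect spikes, and
#' summarise the firing pattern.  Rows are ordered by the swept value and
#' the whole run is deterministic.
#'
#' @param spec A [sweep_spec()].
#' @param params An [hh_params()].
#' @param verbose Print one progress line per swept value.
#' @return A data frame with one row per swept value and columns
#'   `b_field_T`, `gamma_W_cm2`, `freq_Hz`, `mode`, `duty_cycle`,
#'   `rep_freq_Hz`, `amp_mV`, `isi_ms`, `fr_per_cycle`, `n_spikes`.
#' @examples
#' \donttest{
#' sp <- sweep_spec("b_field", c(4, 7),
#'                  fixed = drive_spec(gamma = 3, b_field = 3, freq = 5e5))
#' run_sweep(sp)
#' }
#' @export
run_sweep <- function(spec, params = hh_params(), verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$values))
  for (i in seq_along(spec$values)) {
    value <- spec$values[i]
    row <- tryCatch({
      drive <- modify_drive(spec$fixed, spec$parameter, value)
      cfg <- sweep_sim_config(drive, spec$sim)
      t0 <- proc.time()[["elapsed"]]
      sim <- simulate_hh(drive, cfg, params = params)
      stats <- summarize_firing(sim)
      if (verbose) {
        message(sprintf("  %s = %g: %d spikes [%.1f s]", spec$parameter,
                        value, stats$n_spikes,
                        proc.time()[["elapsed"]] - t0))
      }
      data.frame(b_field_T = drive$b_field, gamma_W_cm2 = drive$gamma,
                 freq_Hz = drive$freq, mode = drive$mode,
                 duty_cycle = if (is.null(drive$duty_cycle)) NA_real_ else drive$duty_cycle,
                 rep_freq_Hz = if (is.null(drive$rep_freq)) NA_real_ else drive$rep_freq,
                 amp_mV = stats$amp_mV, isi_ms = stats$isi_ms,
                 fr_per_cycle = stats$fr_per_cycle,
                 n_spikes = stats$n_spikes)
    }, error = function(e) {
      stop(sprintf("sweep failed at %s = %g: %s", spec$parameter, value,
                   conditionMessage(e)), call. = FALSE)
    })
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in sweep presets
#'
#' The six standard stimulation experiments, one per swept parameter
#' regime.  Continuous-wave presets: `"b_field"` (0.5-7 T at 3 W/cm^2,
#' 500 kHz), `"gamma_cw"` (1-100 W/cm^2 at 3 T), `"freq"` (200-700 kHz).
#' Pulsed presets (3 T, 500 kHz carrier): `"gamma_pulsed"` (1-100 W/cm^2
#' at DC 50%, RF 10 Hz), `"duty_cycle"` (5-95% at 3 W/cm^2, RF 10 Hz),
#' `"rep_freq"` (RF sweep at 3 W/cm^2, DC 50%).
#'
#' `smoke = TRUE` (default) uses a reduced grid of 3-5 points per sweep so
#' a full suite runs in minutes; `smoke = FALSE` gives the full grids
#' (e.g. 14 field values, 19 duty cycles).
#'
#' @param name Preset name (see above).
#' @param smoke Use the reduced grid.
#' @return A [sweep_spec()].
#' @examples
#' tmas_preset("b_field")
#' tmas_preset("duty_cycle", smoke = FALSE)
#' @export
tmas_preset <- function(name = c("b_field", "gamma_cw", "freq",
                                 "gamma_pulsed", "duty_cycle", "rep_freq"),
                        smoke = TRUE) {
  name <- match.arg(name)
  cw <- drive_spec(gamma = 3, b_field = 3, freq = 5e5)
  pulsed <- drive_spec(gamma = 3, b_field = 3, freq = 5e5, mode = "pulsed",
                       duty_cycle = 0.5, rep_freq = 10)
  switch(name,
    b_field = sweep_spec("b_field",
                         if (smoke) c(0.5, 1, 4, 7) else seq(0.5, 7, by = 0.5),
                         fixed = cw),
    gamma_cw = sweep_spec("gamma",
                          if (smoke) c(1, 10, 60, 100)
                          else c(1, 5, 10, 20, 40, 60, 80, 100),
                          fixed = cw),
    freq = sweep_spec("freq",
                      if (smoke) c(200e3, 500e3, 700e3)
                      else seq(200e3, 700e3, by = 100e3),
                      fixed = cw),
    gamma_pulsed = sweep_spec("gamma",
                              if (smoke) c(1, 10, 30, 60, 100)
                              else c(1, 5, 10, 20, 30, 40, 60, 80, 100),
                              fixed = pulsed),
    duty_cycle = sweep_spec("duty_cycle",
                            if (smoke) c(0.05, 0.5, 0.95)
                            else seq(0.05, 0.95, by = 0.05),
                            fixed = pulsed),
    rep_freq = sweep_spec("rep_freq",
                          if (smoke) c(5, 20, 100)
                          else c(1, 2, 5, 10, 20, 50, 100),
                          fixed = pulsed))
}

#' Carrier-waveform comparison: pure sine vs. offset sine
#'
#' Simulates the same stimulation parameters with a zero-mean sine carrier
#' and with the offset-sine carrier, and reports spike counts and peak
#' sodium-current magnitude for each.  At suprathreshold intensities the
#' pure sine — averaged out by the membrane at hundreds of kHz — elicits no
#' spikes, while the offset sine (whose mean is the full current-density
#' amplitude) does.
#'
#' @param gamma Ultrasonic power intensity, W/cm^2.
#' @param b_field Magnetostatic field, T.
#' @param freq Carrier frequency, Hz.
#' @param duration Simulation length, ms.
#' @param params An [hh_params()].
#' @param dt Integration step, ms.
#' @return A two-row data frame with columns `waveform`, `n_spikes`,
#'   `peak_na_uA_cm2` (peak inward-sodium-current magnitude).
#' @examples
#' \donttest{
#' compare_carrier_waveforms(duration = 100)
#' }
#' @export
compare_carrier_waveforms <- function(gamma = 3, b_field = 3, freq = 5e5,
                                   duration = 200, params = hh_params(),
                                   dt = 5e-5) {
  one <- function(wf) {
    drive <- drive_spec(gamma = gamma, b_field = b_field, freq = freq,
                        waveform = wf)
    sim <- simulate_hh(drive, sim_config(duration = duration, dt = dt),
                       params = params)
    i_na <- params$g_na * sim$m^3 * sim$h * (sim$v - params$v_na)
    data.frame(waveform = wf,
               n_spikes = length(detect_spikes(sim)$times),
               peak_na_uA_cm2 = max(abs(i_na)))
  }
  rbind(one("sine"), one("offset_sine"))
}

config_schema <- list(
  sweep = c("preset", "smoke", "parameter", "values", "fixed", "sim",
            "allow_extrapolation", "output_path"),
  simulate = c("drive", "sim", "output_path"),
  drive = c("gamma", "b_field", "freq", "mode", "duty_cycle", "rep_freq",
            "waveform", "sigma", "rho", "c0"),
  sim = c("duration", "dt", "record_stride")
)

check_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  }
}

drive_from_list <- function(d, path = "drive.") {
  check_keys(d, config_schema$drive, path)
  tissue <- tissue_constants(
    sigma = if (is.null(d$sigma)) 0.5 else d$sigma,
    rho = if (is.null(d$rho)) 1120 else d$rho,
    c0 = if (is.null(d$c0)) 1540 else d$c0)
  drive_spec(gamma = d$gamma, b_field = d$b_field, freq = d$freq,
             mode = if (is.null(d$mode)) "continuous" else d$mode,
             duty_cycle = d$duty_cycle, rep_freq = d$rep_freq,
             waveform = if (is.null(d$waveform)) "offset_sine" else d$waveform,
             tissue = tissue)
}

sim_from_list <- function(s, path = "sim.") {
  check_keys(s, config_schema$sim, path)
  if (is.null(s$duration)) {
    stop(sprintf("config key %sduration is required", path), call. = FALSE)
  }
  sim_config(duration = s$duration,
             dt = if (is.null(s$dt)) 5e-5 else s$dt,
             record_stride = s$record_stride)
}

#' Load a run configuration from a YAML file
#'
#' The file must contain exactly one top-level block: `sweep:` (a preset
#' name or an explicit parameter/values/fixed description) or `simulate:`
#' (a drive plus a simulation grid).  Unknown keys are rejected with their
#' full key path; omitted optional keys take the package defaults.
#'
#' @param path Path to a YAML config file.
#' @return A [sweep_spec()] (with attribute `output_path` if given) or a
#'   list with elements `drive`, `sim`, `output_path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("sweep", "simulate"), "")
  if (!xor(is.null(cfg$sweep), is.null(cfg$simulate))) {
    stop("config must contain exactly one of 'sweep' or 'simulate'",
         call. = FALSE)
  }
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    check_keys(sw, config_schema$sweep, "sweep.")
    if (!is.null(sw$preset)) {
      spec <- tmas_preset(sw$preset,
                          smoke = if (is.null(sw$smoke)) TRUE else sw$smoke)
    } else {
      if (is.null(sw$parameter) || is.null(sw$values) || is.null(sw$fixed)) {
        stop("an explicit sweep needs 'parameter', 'values', and 'fixed'",
             call. = FALSE)
      }
      spec <- sweep_spec(
        sw$parameter, unlist(sw$values),
        fixed = drive_from_list(sw$fixed, "sweep.fixed."),
        sim = if (is.null(sw$sim)) NULL else sim_from_list(sw$sim, "sweep.sim."),
        allow_extrapolation = isTRUE(sw$allow_extrapolation))
    }
    attr(spec, "output_path") <- sw$output_path
    return(spec)
  }
  si <- cfg$simulate
  check_keys(si, config_schema$simulate, "simulate.")
  if (is.null(si$drive) || is.null(si$sim)) {
    stop("a 'simulate' config needs 'drive' and 'sim' blocks", call. = FALSE)
  }
  list(drive = drive_from_list(si$drive, "simulate.drive."),
       sim = sim_from_list(si$sim, "simulate.sim."),
       output_path = si$output_path)
}
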