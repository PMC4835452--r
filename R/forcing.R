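# Acousto-electric forcing: converts ultrasonic intensity and a magnetostatic
# field into the membrane current density that drives the neuron, and computes
# the diagnostic-ultrasound safety indices (MI, TI).

# Unit conversions live here and nowhere else.  User-facing acoustic intensity
# is in W/cm^2 and current density in uA/cm^2 (the Hodgkin-Huxley model's
# native unit); all internal acoustics are SI.
W_PER_CM2_TO_W_PER_M2 <- 1e4
A_PER_M2_TO_UA_PER_CM2 <- 100

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (allow_zero && x < 0) {
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  if (!allow_zero && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' Tissue acoustic and electrical constants
#'
#' Bundles the three tissue constants that fix the acousto-electric coupling:
#' electrical conductivity, mass density, and sound speed.  Defaults are the
#' typical soft-tissue values used throughout the simulations.
#'
#' @param sigma Electrical conductivity, S/m.
#' @param rho Mass density, kg/m^3.
#' @param c0 Speed of sound, m/s.
#' @return An object of class `tissue_constants`.
#' @examples
#' tissue_constants()
#' @export
tissue_constants <- function(sigma = 0.5, rho = 1120, c0 = 1540) {
  check_positive(sigma, "sigma")
  check_positive(rho, "rho")
  check_positive(c0, "c0")
  structure(list(sigma = sigma, rho = rho, c0 = c0),
            class = "tissue_constants")
}

#' @export
print.tissue_constants <- function(x, ...) {
  cat("Tissue constants: sigma =", x$sigma, "S/m, rho =", x$rho,
      "kg/m^3, c0 =", x$c0, "m/s\n")
  invisible(x)
}

#' Specify a TMAS stimulus
#'
#' Describes the full transcranial magneto-acoustical stimulus: ultrasonic
#' power intensity, magnetostatic field strength, carrier frequency, the
#' fundamental waveform, and (for pulsed mode) the square-wave gate.
#'
#' The physiologically effective waveform is the offset sine
#' `sin(2*pi*f*t) + 1`: a zero-mean carrier at hundreds of kHz is averaged
#' out by the membrane and elicits no spikes, whereas the offset form carries
#' a rectified (non-negative) current.  The pure `"sine"` and `"cosine"`
#' waveforms are retained so that this contrast can be demonstrated (see
#' [compare_carrier_waveforms()]).
#'
#' @param gamma Ultrasonic power intensity, W/cm^2 (typical range 1-100).
#' @param b_field Magnetostatic field intensity, T (typical range 0.5-7).
#' @param freq Ultrasound carrier frequency, Hz (typical range 200-700 kHz).
#' @param mode `"continuous"` or `"pulsed"`.
#' @param duty_cycle On-fraction of each repetition period, in (0, 1].
#'   Required for pulsed mode.
#' @param rep_freq Repetition frequency of the square-wave gate, Hz.
#'   Required for pulsed mode and must be far below `freq`.
#' @param waveform Fundamental waveform of the carrier: `"offset_sine"`
#'   (default), `"sine"`, or `"cosine"`.
#' @param tissue A [tissue_constants()] object.
#' @return An object of class `drive_spec`.
#' @examples
#' drive_spec(gamma = 3, b_field = 3, freq = 5e5)
#' drive_spec(gamma = 3, b_field = 3, freq = 5e5, mode = "pulsed",
#'            duty_cycle = 0.5, rep_freq = 10)
#' @export
drive_spec <- function(gamma, b_field, freq,
                       mode = c("continuous", "pulsed"),
                       duty_cycle = NULL, rep_freq = NULL,
                       waveform = c("offset_sine", "sine", "cosine"),
                       tissue = tissue_constants()) {
  mode <- match.arg(mode)
  waveform <- match.arg(waveform)
  stopifnot(inherits(tissue, "tissue_constants"))
  check_positive(gamma, "gamma")
  check_positive(b_field, "b_field")
  check_positive(freq, "freq")
  if (mode == "pulsed") {
    if (is.null(duty_cycle) || is.null(rep_freq)) {
      stop("pulsed mode requires both 'duty_cycle' and 'rep_freq'",
           call. = FALSE)
    }
    check_positive(duty_cycle, "duty_cycle")
    if (duty_cycle > 1) {
      stop(sprintf("'duty_cycle' must be in (0, 1] (got %g)", duty_cycle),
           call. = FALSE)
    }
    check_positive(rep_freq, "rep_freq")
    if (rep_freq > freq / 100) {
      stop("'rep_freq' must be far below the carrier frequency ",
           sprintf("(rep_freq = %g Hz, freq = %g Hz)", rep_freq, freq),
           call. = FALSE)
    }
  } else {
    duty_cycle <- NULL
    rep_freq <- NULL
  }
  structure(list(tissue = tissue, gamma = gamma, b_field = b_field,
                 freq = freq, mode = mode, duty_cycle = duty_cycle,
                 rep_freq = rep_freq, waveform = waveform),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat("TMAS drive:", x$mode, "ultrasound,", x$waveform, "carrier\n")
  cat(sprintf("  gamma = %g W/cm^2, B = %g T, f = %g kHz\n",
              x$gamma, x$b_field, x$freq / 1e3))
  if (x$mode == "pulsed") {
    cat(sprintf("  duty cycle = %g%%, repetition frequency = %g Hz\n",
                100 * x$duty_cycle, x$rep_freq))
  }
  cat(sprintf("  current density amplitude J0 = %.4g uA/cm^2\n",
              current_density_amplitude(x)$ua_per_cm2))
  invisible(x)
}

#' Constant external current drive
#'
#' A direct constant current density injected into the membrane, used for
#' threshold searches and convergence checks rather than modelling a
#' physical ultrasound stimulus.
#'
#' @param i_ext Constant external current density, uA/cm^2 (may be 0).
#' @return An object of class `constant_drive`.
#' @export
constant_drive <- function(i_ext) {
  if (!is.numeric(i_ext) || length(i_ext) != 1L || !is.finite(i_ext)) {
    stop("'i_ext' must be a single finite number", call. = FALSE)
  }
  structure(list(i_ext = i_ext), class = "constant_drive")
}

#' @export
print.constant_drive <- function(x, ...) {
  cat("Constant current drive: i_ext =", x$i_ext, "uA/cm^2\n")
  invisible(x)
}

#' Particle speed amplitude of the acoustic wave
#'
#' Amplitude `w` of the oscillatory particle speed produced in tissue by a
#' plane wave of intensity `gamma`, from the plane-wave relations
#' `P = rho*c0*w` and `gamma = P^2/(2*rho*c0)`:
#' `w = sqrt(2*gamma / (rho*c0))` with `gamma` converted to W/m^2.
#'
#' @param gamma Ultrasonic power intensity, W/cm^2.
#' @param tissue A [tissue_constants()] object.
#' @return Particle speed amplitude, m/s.
#' @examples
#' particle_speed_amplitude(3)  # ~0.187 m/s in soft tissue
#' @export
particle_speed_amplitude <- function(gamma, tissue = tissue_constants()) {
  check_positive(gamma, "gamma")
  stopifnot(inherits(tissue, "tissue_constants"))
  sqrt(2 * gamma * W_PER_CM2_TO_W_PER_M2 / (tissue$rho * tissue$c0))
}

#' Acoustic pressure amplitude
#'
#' Pressure amplitude of the plane wave, `P = rho*c0*w`.
#'
#' @inheritParams particle_speed_amplitude
#' @return Pressure amplitude, Pa.
#' @examples
#' pressure_amplitude(3)  # ~3.2e5 Pa
#' @export
pressure_amplitude <- function(gamma, tissue = tissue_constants()) {
  tissue$rho * tissue$c0 * particle_speed_amplitude(gamma, tissue)
}

#' Lorentz-force current density amplitude
#'
#' Amplitude of the acousto-electric current density induced when tissue
#' ions oscillating at particle speed `w` cross a magnetostatic field `B`:
#' `J0 = sigma * B * w`.  This is the coefficient multiplying the carrier
#' waveform in the membrane drive.
#'
#' @param spec A [drive_spec()].
#' @return A list with the amplitude in both unit systems:
#'   `a_per_m2` (A/m^2) and `ua_per_cm2` (uA/cm^2).
#' @examples
#' sp <- drive_spec(gamma = 3, b_field = 3, freq = 5e5)
#' current_density_amplitude(sp)  # ~0.28 A/m^2 = 28 uA/cm^2
#' @export
current_density_amplitude <- function(spec) {
  stopifnot(inherits(spec, "drive_spec"))
  w <- particle_speed_amplitude(spec$gamma, spec$tissue)
  j_si <- spec$tissue$sigma * spec$b_field * w
  list(a_per_m2 = j_si, ua_per_cm2 = j_si * A_PER_M2_TO_UA_PER_CM2)
}

waveform_value <- function(waveform, phase) {
  switch(waveform,
         offset_sine = sin(phase) + 1,
         sine = sin(phase),
         cosine = cos(phase),
         stop("unknown waveform '", waveform, "'", call. = FALSE))
}

#' Continuous-wave drive current
#'
#' Current density applied to the membrane at time `t` under continuous-wave
#' ultrasound.  With the default offset-sine carrier,
#' `J(t) = J0 * (sin(2*pi*f*t) + 1)`, which is non-negative with time
#' average `J0` over whole acoustic periods.
#'
#' @param t Time, ms (vectorised).
#' @param spec A [drive_spec()].
#' @return Current density, uA/cm^2, same length as `t`.
#' @examples
#' sp <- drive_spec(gamma = 3, b_field = 3, freq = 5e5)
#' continuous_drive(c(0, 5e-4, 1e-3), sp)
#' @export
continuous_drive <- function(t, spec) {
  stopifnot(inherits(spec, "drive_spec"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  j0 <- current_density_amplitude(spec)$ua_per_cm2
  # t * 1e-3 (not t/1000): keeps the phase bit-identical to the compiled
  # integrator's drive evaluation
  j0 * waveform_value(spec$waveform, 2 * pi * spec$freq * (t * 1e-3))
}

#' Square-wave pulse gate
#'
#' The on/off gate of pulsed ultrasound.  Within each repetition period
#' `1/rep_freq` the gate is 1 for the first `duty_cycle` fraction and 0
#' otherwise.  The on-window is open on the left and closed on the right:
#' `(n-1)/RF < t <= (n-1+DC)/RF`; in particular the gate is 0 at `t = 0`.
#'
#' @param t Time, **seconds** (vectorised).
#' @param rep_freq Repetition frequency, Hz.
#' @param duty_cycle On-fraction, in (0, 1].
#' @return 0/1 vector, same length as `t`.
#' @examples
#' pulse_gate(c(0.02, 0.07), rep_freq = 10, duty_cycle = 0.5)  # 1, 0
#' @export
pulse_gate <- function(t, rep_freq, duty_cycle) {
  check_positive(rep_freq, "rep_freq")
  check_positive(duty_cycle, "duty_cycle")
  if (duty_cycle > 1) {
    stop(sprintf("'duty_cycle' must be in (0, 1] (got %g)", duty_cycle),
         call. = FALSE)
  }
  x <- t * rep_freq
  r <- x - floor(x)
  # right-closed convention: a point landing exactly on a period boundary
  # belongs to the end of the previous period
  r[t > 0 & r == 0] <- 1
  as.numeric(t > 0 & r <= duty_cycle)
}

#' Pulsed-wave drive current
#'
#' Current density under pulsed ultrasound: the square-wave gate applied
#' multiplicatively to the full continuous-wave carrier (including its
#' offset), `J(t) = x(t) * J0 * (sin(2*pi*f*t) + 1)`.
#'
#' @param t Time, ms (vectorised).
#' @param spec A [drive_spec()] with `mode = "pulsed"`.
#' @return Current density, uA/cm^2.
#' @export
pulsed_drive <- function(t, spec) {
  stopifnot(inherits(spec, "drive_spec"))
  if (spec$mode != "pulsed") {
    stop("'spec' must have mode = \"pulsed\"; use continuous_drive() for ",
         "continuous-wave stimuli", call. = FALSE)
  }
  gate <- pulse_gate(t * 1e-3, spec$rep_freq, spec$duty_cycle)
  gate * continuous_drive(t, spec)
}

#' Drive current at given times
#'
#' Evaluates any drive object (constant, continuous, or pulsed) on a vector
#' of times.  This is the same waveform the integrator evaluates internally
#' at Runge-Kutta substep times.
#'
#' @param drive A [drive_spec()] or [constant_drive()].
#' @param t Time, ms (vectorised).
#' @return Current density, uA/cm^2.
#' @export
drive_current <- function(drive, t) {
  if (inherits(drive, "constant_drive")) {
    return(rep(drive$i_ext, length(t)))
  }
  stopifnot(inherits(drive, "drive_spec"))
  if (drive$mode == "pulsed") pulsed_drive(t, drive) else continuous_drive(t, drive)
}

#' Mechanical index
#'
#' Safety metric for ultrasound biomechanical effects (cavitation risk):
#' `MI = p_r.3 / (sqrt(f) * C_MI)` with `C_MI = 1 MPa.MHz^(1/2)`, where
#' `p_r.3` is the attenuated peak-rarefactional pressure.  Values below 1
#' are considered free of mechanical tissue injury in diagnostic use.
#'
#' @param pr3 Attenuated peak-rarefactional pressure, MPa.
#' @param freq_mhz Acoustic working frequency, MHz.
#' @return Dimensionless MI.
#' @examples
#' mechanical_index(0.2275, 0.5)  # ~0.32
#' @export
mechanical_index <- function(pr3, freq_mhz) {
  check_positive(pr3, "pr3")
  check_positive(freq_mhz, "freq_mhz")
  c_mi <- 1  # MPa * MHz^(1/2)
  pr3 / (sqrt(freq_mhz) * c_mi)
}

#' Thermal index (unscanned modes, soft tissue)
#'
#' Safety metric for ultrasound tissue heating:
#' `TI = W * f / C_TIS` with `C_TIS = 210 mW.MHz`, where `W` is the acoustic
#' output power.  Values below 1 are considered free of thermal injury.
#'
#' @param power_mw Acoustic output power, mW.
#' @param freq_mhz Acoustic working frequency, MHz.
#' @return Dimensionless TI.
#' @examples
#' thermal_index(212, 0.5)  # ~0.505
#' @export
thermal_index <- function(power_mw, freq_mhz) {
  check_positive(power_mw, "power_mw")
  check_positive(freq_mhz, "freq_mhz")
  c_tis <- 210  # mW * MHz
  power_mw * freq_mhz / c_tis
}

#' Acoustic output power of a circular focal spot
#'
#' Converts intensity and focal-spot diameter into the acoustic output power
#' used by the thermal index: `area = pi*(d/2)^2`, `W = gamma * area`.
#'
#' @param gamma Ultrasonic power intensity, W/cm^2.
#' @param spot_diameter Focal spot diameter, mm.
#' @return A list with `spot_area_cm2` and `power_mw`.
#' @examples
#' acoustic_power(3, 3)  # ~0.0707 cm^2, ~212 mW
#' @export
acoustic_power <- function(gamma, spot_diameter) {
  check_positive(gamma, "gamma")
  check_positive(spot_diameter, "spot_diameter")
  area_cm2 <- pi * (spot_diameter / 10 / 2)^2  # mm -> cm
  list(spot_area_cm2 = area_cm2, power_mw = gamma * area_cm2 * 1000)
}

#' Acoustic safety summary
#'
#' Convenience wrapper computing the focal-spot area, acoustic output power,
#' mechanical index, and thermal index for one stimulation setting.
#'
#' @param pr3 Attenuated peak-rarefactional pressure, MPa (a measured or
#'   derated input; the package does not model attenuation).
#' @param freq_mhz Acoustic working frequency, MHz.
#' @param spot_diameter Focal spot diameter, mm.
#' @param gamma Ultrasonic power intensity, W/cm^2.
#' @return A one-row data frame with columns `pr3_mpa`, `freq_mhz`,
#'   `spot_diameter_mm`, `gamma_w_cm2`, `spot_area_cm2`, `power_mw`, `mi`,
#'   `ti`.
#' @examples
#' safety_summary(pr3 = 0.2275, freq_mhz = 0.5, spot_diameter = 3, gamma = 3)
#' @export
safety_summary <- function(pr3, freq_mhz, spot_diameter, gamma) {
  pw <- acoustic_power(gamma, spot_diameter)
  data.frame(pr3_mpa = pr3, freq_mhz = freq_mhz,
             spot_diameter_mm = spot_diameter, gamma_w_cm2 = gamma,
             spot_area_cm2 = pw$spot_area_cm2, power_mw = pw$power_mw,
             mi = mechanical_index(pr3, freq_mhz),
             ti = thermal_index(pw$power_mw, freq_mhz))
}
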