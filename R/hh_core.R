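# Hodgkin-Huxley membrane model in the shifted voltage frame (resting
# potential at 0 mV, depolarisation positive).  All rate constants and
# reversal potentials below are written in this frame; converting to the
# absolute frame would falsify every constant.

# Width of the guard band around the removable singularities of alpha_m
# (at v = 25 mV) and alpha_n (at v = 10 mV), in mV.  Inside the band the
# exact analytic limit is returned instead of the 0/0 expression.
SINGULARITY_GUARD_MV <- 1e-7

#' Hodgkin-Huxley model parameters
#'
#' The fixed squid-axon constants of the classical model, in the shifted
#' voltage frame, plus temperature.  Gating kinetics are scaled by the
#' temperature factor `phi = 3^((T - 6.3)/10)`; the default 6.3 degC gives
#' `phi = 1`.
#'
#' @param cm Membrane capacitance, uF/cm^2.
#' @param g_na,g_k,g_l Maximal sodium / potassium / leak conductances,
#'   mS/cm^2.
#' @param v_na,v_k,v_l Sodium / potassium / leak reversal potentials, mV
#'   (shifted frame).
#' @param temperature Temperature, degC.
#' @return An object of class `hh_params`.
#' @examples
#' hh_params()
#' @export
hh_params <- function(cm = 1.0, g_na = 120, g_k = 36, g_l = 0.3,
                      v_na = 115, v_k = -12, v_l = 10.59,
                      temperature = 6.3) {
  check_positive(cm, "cm")
  check_positive(g_na, "g_na", allow_zero = TRUE)
  check_positive(g_k, "g_k", allow_zero = TRUE)
  check_positive(g_l, "g_l", allow_zero = TRUE)
  for (nm in c("v_na", "v_k", "v_l", "temperature")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  structure(list(cm = cm, g_na = g_na, g_k = g_k, g_l = g_l,
                 v_na = v_na, v_k = v_k, v_l = v_l,
                 temperature = temperature),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat("Hodgkin-Huxley parameters (shifted frame):\n")
  cat(sprintf("  Cm = %g uF/cm^2; gNa = %g, gK = %g, gL = %g mS/cm^2\n",
              x$cm, x$g_na, x$g_k, x$g_l))
  cat(sprintf("  VNa = %g, VK = %g, VL = %g mV; T = %g degC (phi = %g)\n",
              x$v_na, x$v_k, x$v_l, x$temperature,
              temperature_factor(x$temperature)))
  invisible(x)
}

#' Instantaneous membrane state
#'
#' Membrane potential plus the three gating variables.  The default is the
#' resting state: `v = 0` with the gates at their resting steady-state
#' values (0.053, 0.596, 0.317).
#'
#' @param v Membrane potential, mV (shifted frame).
#' @param m,h Sodium activation / inactivation gates, in \[0, 1\].
#' @param n Potassium activation gate, in \[0, 1\].
#' @return An object of class `hh_state`.
#' @export
hh_state <- function(v = 0, m = 0.053, h = 0.596, n = 0.317) {
  if (!all(vapply(list(v, m, h, n),
                  function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1)))) {
    stop("all state components must be single finite numbers", call. = FALSE)
  }
  for (nm in c("m", "h", "n")) {
    g <- get(nm)
    if (g < 0 || g > 1) {
      stop(sprintf("gating variable '%s' must lie in [0, 1] (got %g)", nm, g),
           call. = FALSE)
    }
  }
  structure(list(v = v, m = m, h = h, n = n), class = "hh_state")
}

#' @export
print.hh_state <- function(x, ...) {
  cat(sprintf("HH state: v = %.4g mV; m = %.4g, h = %.4g, n = %.4g\n",
              x$v, x$m, x$h, x$n))
  invisible(x)
}

#' Voltage-dependent gating rate constants
#'
#' The six opening/closing rates of the gating variables, in 1/ms:
#' \deqn{\alpha_m = 0.1(25-V)/[e^{(25-V)/10}-1], \quad \beta_m = 4e^{-V/18}}
#' \deqn{\alpha_h = 0.07e^{-V/20}, \quad \beta_h = 1/[e^{(30-V)/10}+1]}
#' \deqn{\alpha_n = 0.01(10-V)/[e^{(10-V)/10}-1], \quad \beta_n = 0.125e^{-V/80}}
#'
#' `alpha_m` and `alpha_n` have removable singularities at v = 25 and
#' v = 10 mV; within `1e-7` mV of those points the exact limits (1.0 and
#' 0.1) are substituted, avoiding catastrophic cancellation.
#'
#' @param v Membrane potential, mV (vectorised, must be finite).
#' @return A list of six numeric vectors: `alpha_m`, `beta_m`, `alpha_h`,
#'   `beta_h`, `alpha_n`, `beta_n`.
#' @examples
#' rate_constants(0)
#' rate_constants(25)$alpha_m  # exactly 1 at the singular point
#' @export
rate_constants <- function(v) {
  if (!is.numeric(v) || !all(is.finite(v))) {
    stop("'v' must be finite", call. = FALSE)
  }
  xm <- 25 - v
  am <- ifelse(abs(xm) < SINGULARITY_GUARD_MV, 1.0,
               0.1 * xm / (exp(xm / 10) - 1))
  xn <- 10 - v
  an <- ifelse(abs(xn) < SINGULARITY_GUARD_MV, 0.1,
               0.01 * xn / (exp(xn / 10) - 1))
  list(alpha_m = am,
       beta_m = 4 * exp(-v / 18),
       alpha_h = 0.07 * exp(-v / 20),
       beta_h = 1 / (exp((30 - v) / 10) + 1),
       alpha_n = an,
       beta_n = 0.125 * exp(-v / 80))
}

#' Steady-state gating values
#'
#' The voltage-clamped fixed point of each gate, `x_inf = alpha/(alpha+beta)`.
#' At rest (v = 0) these are approximately 0.053, 0.596, and 0.318 for m, h,
#' n — the values used as the default initial state.
#'
#' @inheritParams rate_constants
#' @return A list of numeric vectors `m`, `h`, `n`, each in (0, 1).
#' @examples
#' steady_state_gating(0)
#' @export
steady_state_gating <- function(v) {
  r <- rate_constants(v)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Temperature factor for gating kinetics
#'
#' `phi = 3^((T - 6.3)/10)` scales all gating rate constants; it equals 1 at
#' the reference temperature 6.3 degC.
#'
#' @param temperature Temperature, degC.
#' @return Dimensionless factor, > 0.
#' @examples
#' temperature_factor(6.3)   # 1
#' temperature_factor(16.3)  # 3
#' @export
temperature_factor <- function(temperature) {
  if (!is.numeric(temperature) || !all(is.finite(temperature))) {
    stop("'temperature' must be finite", call. = FALSE)
  }
  3^((temperature - 6.3) / 10)
}

#' Ionic membrane currents
#'
#' The three conductance-based currents, in uA/cm^2 (positive = outward):
#' `i_na = g_na*m^3*h*(v - v_na)`, `i_k = g_k*n^4*(v - v_k)`,
#' `i_l = g_l*(v - v_l)`.  For 0 < v < v_na the sodium current is negative
#' (inward, depolarising).
#'
#' @param state An [hh_state()].
#' @param params An [hh_params()].
#' @return A list with `i_na`, `i_k`, `i_l`, uA/cm^2.
#' @export
ionic_currents <- function(state, params = hh_params()) {
  stopifnot(inherits(state, "hh_state"), inherits(params, "hh_params"))
  list(i_na = params$g_na * state$m^3 * state$h * (state$v - params$v_na),
       i_k = params$g_k * state$n^4 * (state$v - params$v_k),
       i_l = params$g_l * (state$v - params$v_l))
}

#' Time derivative of the membrane state
#'
#' The right-hand side of the model:
#' `cm * dV/dt = i_ext - (i_na + i_k + i_l)` and
#' `dx/dt = phi*(alpha_x*(1-x) - beta_x*x)` for each gate x.
#'
#' @param state An [hh_state()].
#' @param i_ext External current density, uA/cm^2.
#' @param params An [hh_params()].
#' @return A list with `dv` (mV/ms) and `dm`, `dh`, `dn` (1/ms).
#' @export
hh_derivatives <- function(state, i_ext, params = hh_params()) {
  stopifnot(inherits(state, "hh_state"), inherits(params, "hh_params"))
  if (!is.numeric(i_ext) || length(i_ext) != 1L || !is.finite(i_ext)) {
    stop("'i_ext' must be a single finite number", call. = FALSE)
  }
  ion <- ionic_currents(state, params)
  r <- rate_constants(state$v)
  phi <- temperature_factor(params$temperature)
  list(dv = (i_ext - (ion$i_na + ion$i_k + ion$i_l)) / params$cm,
       dm = phi * (r$alpha_m * (1 - state$m) - r$beta_m * state$m),
       dh = phi * (r$alpha_h * (1 - state$h) - r$beta_h * state$h),
       dn = phi * (r$alpha_n * (1 - state$n) - r$beta_n * state$n))
}
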