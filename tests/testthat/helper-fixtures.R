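# Shared fixtures: synthetic traces with known ground truth and small
# constructors used across test files.

# A voltage trace made of Gaussian bumps at known centers (ms), riding on a
# flat baseline; ground truth for the spike detector.
gaussian_bump_trace <- function(centers, height = 80, sd_ms = 0.5,
                                duration = max(centers) + 10, dt = 0.01) {
  t <- seq(0, duration, by = dt)
  v <- rep(0, length(t))
  for (c0 in centers) {
    v <- v + height * exp(-(t - c0)^2 / (2 * sd_ms^2))
  }
  list(t = t, v = v)
}

# A spike_train built directly from times/peaks, bypassing detection.
make_train <- function(times, peaks = rep(90, length(times))) {
  structure(list(times = times, peaks = peaks), class = "spike_train")
}

cw_drive <- function(gamma = 3, b_field = 3, freq = 5e5, ...) {
  drive_spec(gamma = gamma, b_field = b_field, freq = freq, ...)
}

pulsed_drive_spec <- function(gamma = 3, b_field = 3, freq = 5e5,
                              duty_cycle = 0.5, rep_freq = 10) {
  drive_spec(gamma = gamma, b_field = b_field, freq = freq, mode = "pulsed",
             duty_cycle = duty_cycle, rep_freq = rep_freq)
}

# Monotonicity check with the tolerance used for stepped response curves:
# at most one adjacent-pair violation, and only within 0.5% of the range.
is_monotone <- function(x, decreasing = TRUE, slack_frac = 0.005) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  viol <- if (decreasing) d > 0 else d < 0
  if (!any(viol)) return(TRUE)
  slack <- slack_frac * (max(x) - min(x))
  sum(viol) == 1 && max(abs(d[viol])) < slack
}
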