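# Firing-pattern statistics extracted from a membrane-potential trace:
# spike amplitude (AMP), interspike interval (ISI), and firing rate per
# stimulation cycle (FR).

# Spikes in this model peak near 90-100 mV (shifted frame), so 50 mV
# cleanly separates action potentials from subthreshold oscillation.
DEFAULT_SPIKE_THRESHOLD_MV <- 50
DEFAULT_MIN_SEPARATION_MS <- 2
# Onset transient excluded before computing steady-state AMP/ISI.
DEFAULT_TRANSIENT_MS <- 100

#' Detect spikes in a simulated voltage trace
#'
#' A spike is a local maximum of the voltage trace that exceeds
#' `threshold`, with successive accepted peaks at least `min_separation`
#' apart (earlier peaks win); flat-topped maxima resolve to their earliest
#' sample.
#'
#' @param result An `hh_sim` from [simulate_hh()], or any list with
#'   numeric vectors `t` (ms) and `v` (mV).
#' @param threshold Peak detection threshold, mV.
#' @param min_separation Minimum time between accepted peaks, ms.
#' @return An object of class `spike_train`: list with `times` (ms,
#'   strictly increasing) and `peaks` (mV).
#' @examples
#' sim <- simulate_hh(constant_drive(15), sim_config(duration = 100, dt = 1e-3))
#' detect_spikes(sim)
#' @export
detect_spikes <- function(result,
                          threshold = DEFAULT_SPIKE_THRESHOLD_MV,
                          min_separation = DEFAULT_MIN_SEPARATION_MS) {
  check_positive(threshold, "threshold")
  check_positive(min_separation, "min_separation")
  t <- result$t
  v <- result$v
  if (is.null(t) || is.null(v) || length(v) == 0L) {
    stop("'result' must contain a non-empty voltage trace", call. = FALSE)
  }
  nv <- length(v)
  idx <- integer(0)
  if (nv >= 3) {
    core <- v[2:(nv - 1)]
    # strictly above the previous sample, at least the next: a flat top
    # resolves to its earliest sample
    cand <- which(core > threshold & core > v[1:(nv - 2)] &
                    core >= v[3:nv]) + 1L
    if (length(cand) > 0) {
      keep <- cand[1]
      last_t <- t[cand[1]]
      for (i in cand[-1]) {
        if (t[i] - last_t >= min_separation) {
          keep <- c(keep, i)
          last_t <- t[i]
        }
      }
      idx <- keep
    }
  }
  structure(list(times = t[idx], peaks = v[idx]), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes", length(x$times)))
  if (length(x$times) > 0) {
    cat(sprintf(" over [%.3g, %.3g] ms; mean peak %.3g mV",
                min(x$times), max(x$times), mean(x$peaks)))
  }
  cat("\n")
  invisible(x)
}

#' Mean spike amplitude
#'
#' Mean peak voltage (AMP) of the spikes fired after the onset transient.
#' When no spike survives the transient cutoff the statistic is undefined
#' and `NA` is returned, never zero.
#'
#' @param train A [detect_spikes()] result.
#' @param transient Transient cutoff, ms; spikes at or before it are
#'   excluded.
#' @return Mean peak voltage, mV, or `NA_real_`.
#' @export
amplitude_stat <- function(train, transient = DEFAULT_TRANSIENT_MS) {
  stopifnot(inherits(train, "spike_train"))
  sel <- train$times > transient
  if (!any(sel)) return(NA_real_)
  mean(train$peaks[sel])
}

#' Interspike intervals within bursts
#'
#' Consecutive differences of spike times, excluding gaps longer than
#' `burst_split` so that the silent periods between pulsed-ultrasound
#' bursts do not contaminate the within-burst ISI.  For continuous
#' stimulation use the default `burst_split = Inf` (keep every gap); for
#' pulsed stimulation half the gate off-period, `(1 - DC)/(2 * RF)`, is a
#' practical split (see [burst_split_for()]).
#'
#' @param train A [detect_spikes()] result.
#' @param burst_split Gaps strictly longer than this (ms) are discarded.
#' @return A list with `isi_values` (ms) and `isi_mean` (ms, `NA` when no
#'   gap is retained).
#' @examples
#' tr <- structure(list(times = c(10, 20, 120, 130), peaks = rep(90, 4)),
#'                 class = "spike_train")
#' isi_stat(tr, burst_split = 50)  # the 100 ms inter-burst gap is dropped
#' @export
isi_stat <- function(train, burst_split = Inf) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(burst_split) || length(burst_split) != 1L ||
      is.na(burst_split) || burst_split <= 0) {
    stop("'burst_split' must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  d <- diff(train$times)
  d <- d[d <= burst_split]
  list(isi_values = d,
       isi_mean = if (length(d) > 0) mean(d) else NA_real_)
}

#' Default burst-split gap for a drive
#'
#' Half the gate off-period for a pulsed drive, `Inf` for continuous or
#' constant drives.
#'
#' @param drive A [drive_spec()] or [constant_drive()].
#' @return Burst-split gap, ms.
#' @export
burst_split_for <- function(drive) {
  if (inherits(drive, "drive_spec") && drive$mode == "pulsed") {
    off_period_ms <- (1 - drive$duty_cycle) / drive$rep_freq * 1000
    if (off_period_ms > 0) return(off_period_ms / 2)
  }
  Inf
}

#' Firing rate per stimulation cycle
#'
#' Number of spikes per complete repetition period of a pulsed drive (FR),
#' averaged over the complete cycles that remain after skipping
#' `transient_cycles` initial cycles.
#'
#' @param train A [detect_spikes()] result.
#' @param rep_freq Repetition frequency of the pulsed drive, Hz.
#' @param duration Trace duration, ms; must cover at least
#'   `transient_cycles + 1` full cycles.
#' @param transient_cycles Number of initial cycles excluded.
#' @return Mean spikes per cycle.
#' @export
firing_rate_per_cycle <- function(train, rep_freq, duration,
                                  transient_cycles = 1) {
  stopifnot(inherits(train, "spike_train"))
  check_positive(rep_freq, "rep_freq")
  check_positive(duration, "duration")
  if (transient_cycles < 0 || transient_cycles != round(transient_cycles)) {
    stop("'transient_cycles' must be a non-negative integer", call. = FALSE)
  }
  period_ms <- 1000 / rep_freq
  n_complete <- floor(duration / period_ms)
  n_counted <- n_complete - transient_cycles
  if (n_counted < 1) {
    stop(sprintf(
      "duration %g ms covers only %d complete cycle(s) at RF = %g Hz; ",
      duration, n_complete, rep_freq),
      sprintf("need at least %d to count past the transient",
              transient_cycles + 1),
      call. = FALSE)
  }
  lo <- transient_cycles * period_ms
  hi <- n_complete * period_ms
  n_spikes <- sum(train$times > lo & train$times <= hi)
  n_spikes / n_counted
}

#' Summarise a simulation as firing-pattern statistics
#'
#' Runs spike detection on a simulation and derives the steady-state AMP,
#' ISI, and (for pulsed drives) FR statistics with the standard transient
#' and burst-split conventions.
#'
#' @param sim An `hh_sim` from [simulate_hh()].
#' @param threshold,min_separation Spike detection settings, see
#'   [detect_spikes()].
#' @param transient Transient cutoff for AMP/ISI, ms.
#' @return A one-row data frame with columns `n_spikes`, `amp_mV`,
#'   `isi_ms`, `fr_per_cycle` (`NA` for non-pulsed drives).
#' @export
summarize_firing <- function(sim,
                             threshold = DEFAULT_SPIKE_THRESHOLD_MV,
                             min_separation = DEFAULT_MIN_SEPARATION_MS,
                             transient = DEFAULT_TRANSIENT_MS) {
  stopifnot(inherits(sim, "hh_sim"))
  train <- detect_spikes(sim, threshold = threshold,
                         min_separation = min_separation)
  steady <- structure(list(times = train$times[train$times > transient],
                           peaks = train$peaks[train$times > transient]),
                      class = "spike_train")
  drive <- sim$drive
  fr <- NA_real_
  if (inherits(drive, "drive_spec") && drive$mode == "pulsed") {
    fr <- firing_rate_per_cycle(train, drive$rep_freq,
                                sim$config$duration,
                                transient_cycles = 1)
  }
  data.frame(n_spikes = length(train$times),
             amp_mV = amplitude_stat(train, transient = transient),
             isi_ms = isi_stat(steady, burst_split_for(drive))$isi_mean,
             fr_per_cycle = fr)
}
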