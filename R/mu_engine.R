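#' Mu frequency band
#'
#' The sensorimotor mu rhythm is scored in a 7.5-14.5 Hz window. With 500-ms
#' segments at 1000 Hz the periodogram bins fall on a 2 Hz grid, so the bins
#' whose centers lie inside the band are 8, 10, 12 and 14 Hz.
#'
#' @param lower,upper band edges in Hz.
#' @return list with `lower` and `upper`.
#' @export
mu_band <- function(lower = 7.5, upper = 14.5) {
  stopifnot(lower > 0, lower < upper)
  list(lower = lower, upper = upper)
}

#' Band power of one 500-ms segment
#'
#' Computes the one-sided rectangular-window periodogram of each EEG channel
#' and sums the bins whose center frequency lies in `[band$lower, band$upper]`
#' (closed interval on bin centers). Powers are in microvolt-squared; a pure
#' sinusoid of amplitude A inside the band yields A^2/2.
#'
#' @param segment numeric matrix, exactly 500 samples x channels (must include
#'   the four EEG channels), or a 500-sample numeric vector.
#' @param band a [mu_band()].
#' @param sample_rate sampling rate in Hz.
#' @return For a matrix input, a named numeric vector of band powers for
#'   `C3`, `CP3`, `C4`, `CP4`; for a vector input, a single power.
#' @export
segment_band_power <- function(segment, band = mu_band(), sample_rate = 1000) {
  vec_in <- is.null(dim(segment))
  x <- if (vec_in) matrix(segment, ncol = 1L) else
    segment[, EEG_CHANNELS, drop = FALSE]
  n <- nrow(x)
  if (n != samples_per_tick(sample_rate))
    stop("segment must contain exactly ", samples_per_tick(sample_rate),
         " samples per channel, got ", n)
  freqs <- (0:(n %/% 2)) * sample_rate / n
  in_band <- freqs >= band$lower & freqs <= band$upper
  X <- stats::mvfft(x)
  # one-sided periodogram: P_k = 2|X_k|^2/n^2 for 0 < k < n/2
  half <- Mod(X[1:(n %/% 2 + 1L), , drop = FALSE])^2 / n^2
  scale <- c(1, rep(2, n %/% 2 - 1L), 1)
  p <- colSums(half[in_band, , drop = FALSE] * scale[in_band])
  if (vec_in) unname(p) else stats::setNames(p, EEG_CHANNELS)
}

#' Log2 power ratio (ERD/ERS value)
#'
#' Negative values indicate event-related desynchronization (power below
#' baseline), positive values synchronization. A zero power returns the
#' configured floor rather than -Inf so a degenerate silent tick cannot
#' propagate non-finite values into the controller.
#'
#' @param power band power, microvolt-squared (>= 0).
#' @param baseline_power baseline band power (> 0).
#' @param floor value returned when `power` is 0.
#' @return log2(power / baseline_power), vectorized.
#' @export
log2_power_ratio <- function(power, baseline_power, floor = -20) {
  if (any(baseline_power <= 0)) stop("baseline power must be positive")
  if (any(power < 0)) stop("power must be non-negative")
  out <- log2(power / baseline_power)
  out[power == 0] <- floor
  out
}

#' Running average over the most recent ticks
#'
#' The feedback metric is smoothed with a running average of the most recent
#' 6 segments (3 s). At stream start, fewer than `window` values are
#' averaged.
#'
#' @param history numeric vector of per-tick values, oldest first.
#' @param window window length in ticks.
#' @return mean of the trailing `min(window, length(history))` values.
#' @export
smoothed_metric <- function(history, window = 6L) {
  stopifnot(window >= 1L)
  n <- length(history)
  if (n == 0L) stop("empty history")
  mean(history[max(1L, n - window + 1L):n])
}

#' Baseline profile from the 15-s rest block
#'
#' Splits the rest-block recording into 500-ms ticks and computes, per EEG
#' channel, the mean mu band power across ticks (the baseline denominators of
#' the neurofeedback score), and per EMG channel the mean and SD of the
#' per-tick rectified amplitude (the reference statistics of the EMG gate).
#'
#' @param recording an `nfb_recording` covering the rest block (>= 1 tick).
#' @param band a [mu_band()].
#' @return list of class `nfb_baseline` with `mu_power` (named vector over
#'   EEG channels), `emg_mean`, `emg_sd` (named over EMG channels),
#'   `n_ticks`, `duration`.
#' @export
compute_baseline_profile <- function(recording, band = mu_band()) {
  spt <- samples_per_tick(recording$sample_rate)
  nt <- n_ticks(recording)
  if (nt < 1L) stop("need at least one full 500-ms tick of baseline data")
  pw <- matrix(0, nt, length(EEG_CHANNELS),
               dimnames = list(NULL, EEG_CHANNELS))
  em <- matrix(0, nt, length(EMG_CHANNELS),
               dimnames = list(NULL, EMG_CHANNELS))
  for (i in seq_len(nt)) {
    seg <- recording$data[tick_rows(i, spt), , drop = FALSE]
    pw[i, ] <- segment_band_power(seg, band, recording$sample_rate)
    em[i, ] <- rectified_emg_means(seg)
  }
  emg_sd <- if (nt > 1L) apply(em, 2, stats::sd) else
    stats::setNames(rep(0, length(EMG_CHANNELS)), EMG_CHANNELS)
  structure(list(mu_power = colMeans(pw),
                 emg_mean = colMeans(em),
                 emg_sd = emg_sd,
                 n_ticks = nt,
                 duration = nt * 0.5),
            class = "nfb_baseline")
}

#' @export
print.nfb_baseline <- function(x, ...) {
  cat(sprintf("<nfb_baseline> %d ticks (%.1f s)\n", x$n_ticks, x$duration))
  cat("  mu power (uV^2):",
      paste(sprintf("%s=%.3g", names(x$mu_power), x$mu_power), collapse = " "),
      "\n")
  cat("  EMG mean (uV):",
      paste(sprintf("%s=%.3g", names(x$emg_mean), x$emg_mean), collapse = " "),
      "\n")
  invisible(x)
}
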