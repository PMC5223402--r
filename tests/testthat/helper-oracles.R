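# Independent oracles and shared fixtures for the test suite.

# Direct-DFT band-power oracle: explicit correlation with complex
# exponentials at each periodogram bin, one-sided scaling. Deliberately
# avoids stats::fft so it is an independent check of segment_band_power().
dft_band_power_oracle <- function(x, lower = 7.5, upper = 14.5, sr = 1000) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  freqs <- ks * sr / n
  keep <- freqs >= lower & freqs <= upper
  total <- 0
  for (k in ks[keep]) {
    ex <- exp(-2i * pi * k * (0:(n - 1)) / n)
    Xk <- sum(x * ex)
    scale <- if (k == 0 || k == n %/% 2) 1 else 2
    total <- total + scale * Mod(Xk)^2 / n^2
  }
  total
}

# Brute-force trailing-window mean oracle for the running average.
trailing_mean_oracle <- function(values, i, window = 6L) {
  mean(values[max(1L, i - window + 1L):i])
}

# Zero recording of the full montage.
zero_recording <- function(seconds = 2, markers = NULL) {
  n <- round(seconds * 1000)
  data <- matrix(0, n, length(iinfb:::ALL_CHANNELS),
                 dimnames = list(NULL, iinfb:::ALL_CHANNELS))
  if (is.null(markers)) nfb_recording(data) else nfb_recording(data, markers)
}

# A clean mu-only subject (no noise or artifacts) for calibration tests;
# individual fields can still be overridden.
clean_profile <- function(...) {
  args <- list(noise_amp = 0, blink_rate = 0, emg_burst_rate = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(subject_profile, args)
}

# Small session schedule for fast end-to-end tests: 1 block x 2 trials,
# no motor-imagery trials.
small_config <- function(...) {
  engine_config(blocks = 1L, trials_per_block = 2L, mi_trials = 2L, ...)
}

# One default-schedule simulated session, computed once and shared across
# test files (the full schedule takes a few seconds to synthesize).
.fixture_env <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_closed_loop_session(
      subject_profile(seed = 101L))
  .fixture_env$sim
}
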