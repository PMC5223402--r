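#' Preprocessing configuration
#'
#' Two fixed profiles mirror the acquisition chain. The online (real-time)
#' chain uses a 1-100 Hz band-pass, the offline chain a 0.5 Hz high-pass and
#' zero-phase application; both notch at 60 Hz. The ocular-artifact threshold
#' is 360 uV online and 200 uV offline (the thresholds are interpreted in
#' microvolts: millivolt-scale EOG would be physically implausible). The
#' filters are a 4th-order Butterworth band-pass (high-pass offline) and a
#' 2nd-order notch with Q = 30.
#'
#' @param mode `"online"` or `"offline"`.
#' @param sample_rate sampling rate in Hz.
#' @return list of class `preproc_config` with fields `mode`, `hp_cutoff`,
#'   `lp_cutoff` (NA offline), `notch`, `notch_q`, `eog_threshold`,
#'   `artifact_window` (ms relative to the peak), `dc_window` (s),
#'   `zero_phase`, and the designed filter coefficient sets `filters`.
#' @export
preproc_config <- function(mode = c("online", "offline"), sample_rate = 1000) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    hp_cutoff = if (mode == "online") 1.0 else 0.5,
    lp_cutoff = if (mode == "online") 100 else NA_real_,
    notch = 60,
    notch_q = 30,
    eog_threshold = if (mode == "online") 360 else 200,
    artifact_window = c(-200, 500),
    dc_window = 3,
    zero_phase = (mode == "offline"),
    sample_rate = sample_rate
  )
  nyq <- sample_rate / 2
  band <- if (mode == "online") {
    signal::butter(2, c(cfg$hp_cutoff, cfg$lp_cutoff) / nyq, type = "pass")
  } else {
    signal::butter(4, cfg$hp_cutoff / nyq, type = "high")
  }
  w0 <- 2 * pi * cfg$notch / sample_rate
  alpha <- sin(w0) / (2 * cfg$notch_q)
  notch <- list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
                a = c(1 + alpha, -2 * cos(w0), 1 - alpha) / (1 + alpha))
  cfg$filters <- list(band = list(b = band$b, a = band$a), notch = notch)
  structure(cfg, class = "preproc_config")
}

#' Re-reference EEG channels to the bilateral mastoids
#'
#' Subtracts the mean of the left and right mastoid reference traces from
#' every EEG channel. EOG and EMG channels are left untouched.
#'
#' @param recording an `nfb_recording`.
#' @param left_ref,right_ref numeric vectors, same length as the recording.
#' @return the re-referenced `nfb_recording`.
#' @export
rereference_to_mastoids <- function(recording, left_ref, right_ref) {
  n <- n_samples(recording)
  if (length(left_ref) != n || length(right_ref) != n)
    stop("reference trace length does not match recording")
  ref <- (left_ref + right_ref) / 2
  recording$data[, EEG_CHANNELS] <- recording$data[, EEG_CHANNELS] - ref
  recording
}

#' Initialize streaming filter state
#'
#' @param config a [preproc_config()] (online mode).
#' @param n_channels number of channels that will be streamed.
#' @return opaque state list for [filter_stream()].
#' @export
filter_state_init <- function(config, n_channels) {
  mk <- function(f) matrix(0, max(length(f$b), length(f$a)) - 1L, n_channels)
  list(band = mk(config$filters$band), notch = mk(config$filters$notch),
       n_channels = n_channels)
}

#' Causal streaming filter over a segment
#'
#' Applies the band-pass (or high-pass) and notch cascade causally, carrying
#' internal filter state across calls: filtering a signal chunk-by-chunk is
#' sample-exactly equal to filtering the concatenation in one call.
#'
#' @param config a [preproc_config()].
#' @param segment numeric matrix, samples x channels.
#' @param state state from [filter_state_init()] or a previous call.
#' @return list with `segment` (filtered) and `state` (updated).
#' @export
filter_stream <- function(config, segment, state) {
  segment <- as.matrix(segment)
  if (is.null(state$band)) stop("filter state not initialized")
  if (ncol(segment) != state$n_channels)
    stop("channel count does not match filter state")
  f <- config$filters
  r1 <- .df2t_filter(f$band$b, f$band$a, segment, state$band)
  r2 <- .df2t_filter(f$notch$b, f$notch$a, r1$y, state$notch)
  dimnames(r2$y) <- dimnames(segment)
  list(segment = r2$y,
       state = list(band = r1$zf, notch = r2$zf,
                    n_channels = state$n_channels))
}

#' Zero-phase offline filtering of a whole recording's EEG channels
#'
#' @param recording an `nfb_recording`.
#' @param config a [preproc_config()] in offline mode.
#' @return the filtered recording (EEG channels only are modified).
#' @export
filter_offline <- function(recording, config = preproc_config("offline")) {
  if (!config$zero_phase)
    stop("filter_offline requires an offline-mode config")
  f <- config$filters
  for (ch in EEG_CHANNELS) {
    x <- recording$data[, ch]
    x <- signal::filtfilt(f$band$b, f$band$a, x)
    x <- signal::filtfilt(f$notch$b, f$notch$a, x)
    recording$data[, ch] <- x
  }
  recording
}

#' Detect ocular events on the EOG channels
#'
#' An event is an excursion where any EOG channel exceeds the threshold in
#' absolute value. Supra-threshold samples closer together than `min_gap`
#' (500 ms) belong to the same event; the event index is the sample of the
#' absolute maximum across EOG channels within the excursion (earliest sample
#' on ties).
#'
#' @param eog_traces numeric matrix, samples x EOG channels (or a vector).
#' @param threshold threshold in microvolts (> 0).
#' @param min_gap minimum separation between distinct events, in samples.
#' @return integer vector of peak sample indices (possibly empty).
#' @export
detect_eog_events <- function(eog_traces, threshold = 360, min_gap = 500L) {
  stopifnot(threshold > 0)
  if (is.null(dim(eog_traces))) eog_traces <- matrix(eog_traces, ncol = 1L)
  if (nrow(eog_traces) == 0L) return(integer(0))
  absmax <- do.call(pmax, lapply(seq_len(ncol(eog_traces)),
                                 function(j) abs(eog_traces[, j])))
  over <- which(absmax > threshold)
  if (length(over) == 0L) return(integer(0))
  grp <- cumsum(c(1L, diff(over) >= min_gap))
  vapply(split(over, grp), function(idx) idx[which.max(absmax[idx])],
         integer(1), USE.NAMES = FALSE)
}

# Merge overlapping [start, end] windows (matrix with two columns).
merge_windows <- function(win) {
  if (nrow(win) <= 1L) return(win)
  o <- order(win[, 1])
  win <- win[o, , drop = FALSE]
  out <- win[1, , drop = FALSE]
  for (i in 2:nrow(win)) {
    if (win[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], win[i, 2])
    } else {
      out <- rbind(out, win[i, , drop = FALSE])
    }
  }
  out
}

#' Attenuate ocular artifacts by local first-component removal
#'
#' Within a window of -200 to +500 ms around each detected peak, the first
#' principal component of the EEG+EOG channels (uncentered, computed from the
#' window itself) is projected out. Samples outside the windows are never
#' modified; overlapping windows are merged first. A rank-1 artifact (a
#' single spatial pattern scaled over time) is removed exactly; activity
#' spatially orthogonal to the artifact pattern is preserved.
#'
#' @param recording an `nfb_recording`.
#' @param events integer vector of artifact peak samples.
#' @param window numeric length-2, window in ms relative to each peak.
#' @return the cleaned `nfb_recording`.
#' @export
attenuate_artifact_pca <- function(recording, events, window = c(-200, 500)) {
  if (length(events) == 0L) return(recording)
  n <- n_samples(recording)
  if (any(events < 1L) || any(events > n))
    stop("artifact event outside recording bounds")
  sr <- recording$sample_rate
  win <- cbind(pmax(1L, events + round(window[1] * sr / 1000)),
               pmin(n, events + round(window[2] * sr / 1000)))
  win <- merge_windows(win)
  chans <- c(EEG_CHANNELS, EOG_CHANNELS)
  for (i in seq_len(nrow(win))) {
    rows <- win[i, 1]:win[i, 2]
    X <- recording$data[rows, chans, drop = FALSE]
    sv <- svd(X, nu = 0, nv = 1)
    if (sv$d[1] > 0) {
      v1 <- sv$v[, 1]
      X <- X - (X %*% v1) %*% t(v1)
      recording$data[rows, chans] <- X
    }
  }
  recording
}

#' DC baseline correction
#'
#' Subtracts, per channel, the mean of the first `dc_window` seconds from the
#' entire trace.
#'
#' @param recording an `nfb_recording`.
#' @param dc_window window in seconds (default 3).
#' @return the corrected recording.
#' @export
baseline_correct_dc <- function(recording, dc_window = 3) {
  n0 <- round(dc_window * recording$sample_rate)
  if (n_samples(recording) < n0)
    stop("recording shorter than the DC window")
  mu <- colMeans(recording$data[1:n0, , drop = FALSE])
  recording$data <- sweep(recording$data, 2, mu)
  recording
}
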