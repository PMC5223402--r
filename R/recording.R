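#' @useDynLib iinfb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed channel montage of the engine. EEG over left (C3, CP3) and right
# (C4, CP4) sensorimotor cortex, four ocular channels, two bipolar forearm
# EMG channels.
EEG_CHANNELS <- c("C3", "CP3", "C4", "CP4")
LEFT_CHANNELS <- c("C3", "CP3")
RIGHT_CHANNELS <- c("C4", "CP4")
EOG_CHANNELS <- c("EOG_up", "EOG_down", "EOG_left", "EOG_right")
EMG_CHANNELS <- c("EMG_flex", "EMG_ext")
ALL_CHANNELS <- c(EEG_CHANNELS, EOG_CHANNELS, EMG_CHANNELS)

MARKER_LABELS <- c("baseline_start", "trial_start", "trial_end", "rest_start",
                   "block_start", "block_end", "mi_start", "mi_end")

#' Multichannel recording container
#'
#' A `nfb_recording` holds continuous multichannel data in microvolts at a
#' fixed 1000 Hz sampling rate, plus event markers. Channels are fixed:
#' four EEG (`C3`, `CP3`, `C4`, `CP4`), four EOG and two EMG traces.
#'
#' @param data numeric matrix, samples x channels, column names exactly
#'   `ALL_CHANNELS` (in order); values in microvolts.
#' @param markers data frame with columns `label` (character, from the fixed
#'   marker vocabulary) and `sample` (1-based sample index, non-decreasing).
#' @param sample_rate sampling rate in Hz; the engine is defined at 1000.
#'
#' @return An object of class `nfb_recording` with elements `data`,
#'   `markers` and `sample_rate`.
#' @export
nfb_recording <- function(data, markers = empty_markers(), sample_rate = 1000) {
  data <- as.matrix(data)
  if (is.null(colnames(data)) || !identical(colnames(data), ALL_CHANNELS)) {
    missing <- setdiff(ALL_CHANNELS, colnames(data))
    if (length(missing) > 0L)
      stop("recording is missing channel(s): ", paste(missing, collapse = ", "))
    data <- data[, ALL_CHANNELS, drop = FALSE]
  }
  markers <- as.data.frame(markers)
  stopifnot(all(c("label", "sample") %in% names(markers)))
  if (nrow(markers) > 0L) {
    bad <- setdiff(unique(markers$label), MARKER_LABELS)
    if (length(bad) > 0L)
      stop("unknown marker label(s): ", paste(bad, collapse = ", "))
    if (any(markers$sample < 1L) || any(markers$sample > nrow(data)))
      stop("marker sample index out of range")
    if (is.unsorted(markers$sample))
      stop("marker samples must be sorted")
  }
  structure(list(data = data, markers = markers, sample_rate = sample_rate),
            class = "nfb_recording")
}

empty_markers <- function() {
  data.frame(label = character(0), sample = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.nfb_recording <- function(x, ...) {
  cat(sprintf("<nfb_recording> %d samples (%.1f s) x %d channels, %d markers\n",
              nrow(x$data), nrow(x$data) / x$sample_rate, ncol(x$data),
              nrow(x$markers)))
  invisible(x)
}

n_samples <- function(recording) nrow(recording$data)

#' Number of complete 500-ms ticks in a recording
#' @param recording an `nfb_recording`.
#' @return integer tick count.
#' @export
n_ticks <- function(recording) {
  floor(n_samples(recording) / samples_per_tick(recording$sample_rate))
}

samples_per_tick <- function(sample_rate = 1000) as.integer(round(sample_rate * 0.5))

# Extract tick `i` (1-based) from a samples x channels matrix.
tick_rows <- function(i, spt = 500L) ((i - 1L) * spt + 1L):(i * spt)

# Per-tick rectified (full-wave) mean of the EMG channels of a segment.
# Returns a named vector, one entry per EMG channel.
rectified_emg_means <- function(segment) {
  colMeans(abs(segment[, EMG_CHANNELS, drop = FALSE]))
}
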