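#' Offline preprocessing of a continuous recording
#'
#' The post-hoc chain: DC baseline correction from the first 3 s, zero-phase
#' 0.5 Hz high-pass plus 60 Hz notch on the EEG channels, ocular event
#' detection at the offline 200 uV threshold, and first-component artifact
#' attenuation in -200..+500 ms windows.
#'
#' @param recording an `nfb_recording`.
#' @param pconfig an offline [preproc_config()].
#' @return the preprocessed recording.
#' @export
offline_preprocess <- function(recording, pconfig = preproc_config("offline")) {
  recording <- baseline_correct_dc(recording, pconfig$dc_window)
  recording <- filter_offline(recording, pconfig)
  ev <- detect_eog_events(recording$data[, EOG_CHANNELS, drop = FALSE],
                          pconfig$eog_threshold)
  attenuate_artifact_pca(recording, ev, pconfig$artifact_window)
}

#' Epoch a recording by its event markers
#'
#' Cuts marker-to-marker epochs: `trial_start`/`trial_end` pairs become
#' feedback (`nfb`) epochs, `mi_start`/`mi_end` pairs motor-imagery (`mi`)
#' epochs, `rest_start` opens a rest epoch that runs to the next marker (or
#' the end of the recording), and `baseline_start` opens the baseline epoch.
#' Rest epochs inside the motor-imagery block are labeled `mi_rest`. If a
#' config is supplied, epoch durations that deviate from the configured
#' schedule are surfaced as a warning rather than silently adjusted.
#'
#' @param recording an `nfb_recording`.
#' @param config optional [engine_config()] for schedule validation.
#' @return tibble with columns `kind`, `epoch`, `start`, `end` (inclusive
#'   sample bounds), `duration_s`.
#' @export
epoch_by_markers <- function(recording, config = NULL) {
  mk <- recording$markers
  empty <- tibble::tibble(kind = character(), epoch = integer(),
                          start = integer(), end = integer(),
                          duration_s = numeric())
  if (nrow(mk) == 0L) {
    warning("recording has no markers; returning zero epochs")
    return(empty)
  }
  n <- n_samples(recording)
  pair_epochs <- function(open, close, kind) {
    s <- mk$sample[mk$label == open]
    e <- mk$sample[mk$label == close]
    if (length(s) != length(e))
      stop("unmatched ", open, "/", close, " markers (",
           length(s), " vs ", length(e), ")")
    if (length(s) == 0L) return(empty)
    if (any(e <= s)) stop("marker pair ", open, "/", close, " out of order")
    tibble::tibble(kind = kind, epoch = seq_along(s), start = as.integer(s),
                   end = as.integer(e - 1L), duration_s = (e - s) / 1000)
  }
  open_epochs <- function(label, kind) {
    s <- mk$sample[mk$label == label]
    if (length(s) == 0L) return(empty)
    ends <- vapply(s, function(x) {
      nxt <- mk$sample[mk$sample > x]
      if (length(nxt) == 0L) n + 1L else min(nxt)
    }, numeric(1))
    tibble::tibble(kind = kind, epoch = seq_along(s), start = as.integer(s),
                   end = as.integer(ends - 1L), duration_s = (ends - s) / 1000)
  }
  nfb <- pair_epochs("trial_start", "trial_end", "nfb")
  mi <- pair_epochs("mi_start", "mi_end", "mi")
  rest <- open_epochs("rest_start", "rest")
  bl <- open_epochs("baseline_start", "baseline")
  # rests inside the motor-imagery block
  block_starts <- mk$sample[mk$label == "block_start"]
  n_ii_blocks <- if (!is.null(config)) config$blocks else 3L
  if (length(block_starts) > n_ii_blocks && nrow(rest) > 0L) {
    mi_block_at <- sort(block_starts)[n_ii_blocks + 1L]
    rest$kind[rest$start >= mi_block_at] <- "mi_rest"
  }
  out <- dplyr::bind_rows(bl, nfb, rest, mi)
  out <- out[order(out$start), ]
  out$epoch <- stats::ave(seq_len(nrow(out)), out$kind, FUN = seq_along)
  if (!is.null(config)) {
    expect <- c(baseline = config$baseline, nfb = config$trial,
                rest = config$rest, mi = config$mi_duration)
    for (k in names(expect)) {
      d <- out$duration_s[out$kind == k]
      off <- abs(d - expect[[k]]) > 1e-9
      if (any(off))
        warning(sprintf("%d %s epoch(s) deviate from the configured %g s",
                        sum(off), k, expect[[k]]), call. = FALSE)
    }
  }
  out
}

# Tick grid of a set of epochs: one row per complete 500-ms tick.
epoch_ticks <- function(epochs, spt = 500L) {
  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    nt <- (epochs$end[i] - epochs$start[i] + 1L) %/% spt
    if (nt == 0L) return(NULL)
    tibble::tibble(kind = epochs$kind[i], epoch = epochs$epoch[i],
                   tick = seq_len(nt),
                   start = epochs$start[i] + (seq_len(nt) - 1L) * spt)
  })
  dplyr::bind_rows(rows)
}

#' Reject EMG-contaminated 500-ms segments
#'
#' Applies the same gate as the online system to every tick of the given
#' epochs: a tick whose rectified EMG mean exceeds the baseline mean plus
#' `multiplier` SD on either channel is dropped.
#'
#' @param recording an `nfb_recording`.
#' @param epochs epochs from [epoch_by_markers()] (already filtered to the
#'   task of interest).
#' @param baseline an `nfb_baseline`.
#' @param multiplier SD multiplier (default 2).
#' @return list with `ticks` (tibble: `kind`, `epoch`, `tick`, `start`,
#'   `emg_flag`), `kept` (the unflagged subset) and `rejected_fraction`.
#' @export
reject_emg_segments <- function(recording, epochs, baseline, multiplier = 2) {
  if (is.null(baseline$emg_mean)) stop("baseline lacks EMG statistics")
  spt <- samples_per_tick(recording$sample_rate)
  tk <- epoch_ticks(epochs, spt)
  if (nrow(tk) == 0L)
    return(list(ticks = tk, kept = tk, rejected_fraction = NaN))
  tk$emg_flag <- vapply(tk$start, function(s) {
    seg <- recording$data[s:(s + spt - 1L), , drop = FALSE]
    emg_gate(rectified_emg_means(seg), baseline, multiplier)
  }, logical(1))
  list(ticks = tk, kept = tk[!tk$emg_flag, ],
       rejected_fraction = mean(tk$emg_flag))
}

# Mean band power per channel over the final `seconds` of an epoch.
epoch_tail_baseline <- function(recording, epoch, seconds, band) {
  spt <- samples_per_tick(recording$sample_rate)
  nt_tail <- as.integer(round(seconds / 0.5))
  nt <- (epoch$end - epoch$start + 1L) %/% spt
  if (nt < nt_tail)
    stop("epoch too short for a ", seconds, " s baseline window")
  pw <- vapply(seq_len(nt_tail), function(j) {
    i <- nt - nt_tail + j
    s <- epoch$start + (i - 1L) * spt
    segment_band_power(recording$data[s:(s + spt - 1L), , drop = FALSE],
                       band, recording$sample_rate)
  }, numeric(4))
  stats::setNames(rowMeans(pw), EEG_CHANNELS)
}

#' Per-tick log2 ERD/S table
#'
#' For every kept tick, mu band power per channel is divided by a
#' task-specific mean baseline power and log2-transformed: for the feedback
#' (`nfb`) task the baseline is the last 4 s of the baseline-calculation
#' period; for the motor-imagery (`mi`) task it is the last 4 s of the
#' initial rest period of the MI block. The hemisphere value of a tick is
#' the mean of its two channels' log2 ratios (left: C3/CP3; right: C4/CP4).
#'
#' @param recording a preprocessed `nfb_recording`.
#' @param kept_ticks kept-tick tibble from [reject_emg_segments()].
#' @param epochs the full epoch table (to locate the baseline windows).
#' @param task `"nfb"` or `"mi"`.
#' @param group,session labels attached to every record.
#' @param band a [mu_band()].
#' @param baseline_seconds baseline window length (4 s).
#' @return tibble: `group`, `session`, `task`, `hemisphere`, `tick`,
#'   `log2_erds`.
#' @export
compute_erds_table <- function(recording, kept_ticks, epochs,
                               task = c("nfb", "mi"), group = "nfb",
                               session = 1L, band = mu_band(),
                               baseline_seconds = 4) {
  task <- match.arg(task)
  src_kind <- if (task == "nfb") "baseline" else "mi_rest"
  src <- epochs[epochs$kind == src_kind, ]
  if (nrow(src) == 0L)
    stop("no ", src_kind, " epoch available for the ", task, " baseline")
  base <- epoch_tail_baseline(recording, src[1, ], baseline_seconds, band)
  if (any(base <= 0)) stop("baseline powers must be positive")
  tk <- kept_ticks[kept_ticks$kind == task, ]
  spt <- samples_per_tick(recording$sample_rate)
  rows <- lapply(seq_len(nrow(tk)), function(i) {
    s <- tk$start[i]
    pw <- segment_band_power(recording$data[s:(s + spt - 1L), , drop = FALSE],
                             band, recording$sample_rate)
    lr <- log2_power_ratio(pw, base)
    tibble::tibble(group = group, session = as.integer(session), task = task,
                   hemisphere = c("left", "right"),
                   tick = (tk$epoch[i] - 1L) * 10000L + tk$tick[i],
                   log2_erds = c(mean(lr[LEFT_CHANNELS]),
                                 mean(lr[RIGHT_CHANNELS])))
  })
  dplyr::bind_rows(rows)
}

#' Descriptive summary per group x session x task x hemisphere
#'
#' @param table an ERD/S table from [compute_erds_table()] (tables from
#'   several sessions/groups can be row-bound first).
#' @return tibble with one row per populated cell: `group`, `session`,
#'   `task`, `hemisphere`, `mean_log2_erds`, `sd_log2_erds`, `n`.
#' @export
summarize_group_session <- function(table) {
  if (nrow(table) == 0L) stop("empty ERD/S table")
  bad <- !is.finite(table$log2_erds)
  if (any(bad)) {
    warning(sum(bad), " non-finite ERD/S value(s) dropped")
    table <- table[!bad, ]
  }
  grouped <- dplyr::group_by(
    table, dplyr::across(dplyr::all_of(c("group", "session", "task",
                                         "hemisphere"))))
  dplyr::summarise(
    grouped,
    mean_log2_erds = mean(.data[["log2_erds"]]),
    sd_log2_erds = stats::sd(.data[["log2_erds"]]),
    n = dplyr::n(),
    .groups = "drop")
}

#' Full offline analysis of one session recording
#'
#' Offline preprocessing, marker epoching, EMG rejection (feedback task) and
#' per-tick ERD/S computation for both the feedback and motor-imagery tasks.
#'
#' @param recording the raw session `nfb_recording`.
#' @param config an [engine_config()].
#' @param group,session labels for the output table.
#' @return list with `erds` (combined tidy table), `epochs`, `rejection`
#'   (the [reject_emg_segments()] result for the feedback epochs) and
#'   `baseline` (the `nfb_baseline` used for the EMG gate).
#' @export
analyze_session <- function(recording, config = engine_config(),
                            group = "nfb", session = 1L) {
  rec <- offline_preprocess(recording)
  epochs <- suppressWarnings(epoch_by_markers(rec, config))
  bl_epoch <- epochs[epochs$kind == "baseline", ]
  if (nrow(bl_epoch) == 0L) stop("recording lacks a baseline epoch")
  baseline <- compute_baseline_profile(
    nfb_recording(rec$data[bl_epoch$start[1]:bl_epoch$end[1], ,
                           drop = FALSE]), config$band)
  rej <- reject_emg_segments(rec, epochs[epochs$kind == "nfb", ], baseline,
                             config$emg_sd_multiplier)
  mi_ticks <- epoch_ticks(epochs[epochs$kind == "mi", ])
  erds <- dplyr::bind_rows(
    compute_erds_table(rec, rej$kept, epochs, "nfb", group, session,
                       config$band),
    if (nrow(mi_ticks) > 0L)
      compute_erds_table(rec, mi_ticks, epochs, "mi", group, session,
                         config$band))
  list(erds = erds, epochs = epochs, rejection = rej, baseline = baseline)
}
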