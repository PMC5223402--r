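#' Simulate a full closed-loop neurofeedback session
#'
#' Runs a virtual subject through the complete session schedule: the 15-s
#' baseline block, 3 blocks of 10 feedback trials (50 s of imagined
#' imitation followed by 10 s of rest), and a closing motor-imagery block of
#' 10 trials (20 s each, rests randomized on 8-12 s). Every tick passes
#' through the same online pipeline as [run_session()] (causal filtering,
#' ocular-artifact attenuation, band power, smoothing, score, EMG gate,
#' video-score state machine, end-of-trial titration), and the subject's
#' contralateral power ratio drifts downward after successful trials
#' according to `profile$responsiveness`. The returned raw recording carries
#' markers such that `run_session(recording)` reproduces the returned log
#' exactly for a non-adapting subject.
#'
#' @param profile a [subject_profile()].
#' @param config an [engine_config()].
#' @return list with `recording` (raw `nfb_recording` with markers) and
#'   `log` (a `session_log`).
#' @export
simulate_closed_loop_session <- function(profile, config = engine_config()) {
  pconfig <- preproc_config("online")
  gstate <- gen_state_init(profile)
  fstate <- filter_state_init(pconfig, length(EEG_CHANNELS))
  prof <- profile

  raw_pieces <- list()
  marker_labels <- character(0)
  marker_samples <- integer(0)
  sample0 <- 0L

  add_markers <- function(labels) {
    marker_labels <<- c(marker_labels, labels)
    marker_samples <<- c(marker_samples, rep(sample0 + 1L, length(labels)))
  }
  # generate one chunk, stream it through the online preprocessing, and
  # return the processed copy (the raw copy is appended to the recording)
  emit_chunk <- function(task_state, ticks) {
    ch <- generate_chunk(prof, task_state, ticks, gstate)
    gstate <<- ch$state
    raw_pieces[[length(raw_pieces) + 1L]] <<- ch$data
    proc <- ch$data
    fs <- filter_stream(pconfig, proc[, EEG_CHANNELS, drop = FALSE], fstate)
    fstate <<- fs$state
    proc[, EEG_CHANNELS] <- fs$segment
    ev <- detect_eog_events(proc[, EOG_CHANNELS, drop = FALSE],
                            pconfig$eog_threshold)
    if (length(ev) > 0L) {
      sub <- attenuate_artifact_pca(nfb_recording(proc), ev,
                                    pconfig$artifact_window)
      proc <- sub$data
    }
    sample0 <<- sample0 + nrow(proc)
    proc
  }
  metrics_of <- function(proc) {
    spt <- samples_per_tick(1000)
    nt <- nrow(proc) %/% spt
    pw <- matrix(0, nt, 4, dimnames = list(NULL, EEG_CHANNELS))
    em <- matrix(0, nt, 2, dimnames = list(NULL, EMG_CHANNELS))
    for (i in seq_len(nt)) {
      seg <- proc[tick_rows(i, spt), , drop = FALSE]
      pw[i, ] <- segment_band_power(seg, config$band)
      em[i, ] <- rectified_emg_means(seg)
    }
    list(power = pw, emg = em)
  }

  # baseline block
  add_markers("baseline_start")
  baseline <- compute_baseline_profile(
    nfb_recording(emit_chunk("rest", config$ticks_baseline)), config$band)

  # feedback blocks
  state <- feedback_state(level = 1L)
  tick_logs <- list(); trial_logs <- list()
  tick0 <- 0L; trial_i <- 0L
  for (b in seq_len(config$blocks)) {
    for (tr in seq_len(config$trials_per_block)) {
      trial_i <- trial_i + 1L
      labs <- "trial_start"
      if (tr == 1L) labs <- c(if (b > 1L) "block_end", "block_start", labs)
      add_markers(labs)
      trial_start_sample <- sample0 + 1L
      proc <- emit_chunk("ii", config$ticks_per_trial)
      metrics <- metrics_of(proc)
      state$video_score <- 1L
      state$lockout_remaining <- 0L
      level_before <- state$level
      res <- run_trial_ticks(metrics, baseline, state, config, "real")
      state <- res$state
      nt <- length(res$video_score)
      tick_logs[[trial_i]] <- data.frame(
        tick = tick0 + seq_len(nt),
        time_s = (trial_start_sample - 1L) / 1000 + seq_len(nt) * config$tick,
        block = b, trial = trial_i,
        nfb_score = res$nfb_score, video_score = res$video_score,
        level = res$level, emg_flag = res$emg_flag)
      tick0 <- tick0 + nt
      state <- end_of_trial_update(res$video_score, state, config)
      trial_logs[[trial_i]] <- data.frame(
        trial = trial_i, block = b, level_before = level_before,
        level_after = state$level,
        titration_mean = state$last_titration_mean)
      # subject adaptation: success deepens contralateral ERD
      if (prof$responsiveness > 0 && state$last_titration_mean > 4) {
        prof$contra_ratio_task <-
          max(0.05, prof$contra_ratio_task * (1 - prof$responsiveness))
      }
      add_markers(c("trial_end", "rest_start"))
      emit_chunk("rest", config$ticks_per_rest)
    }
  }

  # motor-imagery block: one initial rest, then mi trials with jittered rests
  mi_rest_ticks <- function() {
    as.integer(round(stats::runif(1, config$mi_rest[1], config$mi_rest[2]) /
                       config$tick))
  }
  add_markers(c("block_end", "block_start", "rest_start"))
  emit_chunk("rest", mi_rest_ticks())
  for (tr in seq_len(config$mi_trials)) {
    add_markers("mi_start")
    emit_chunk("mi", config$ticks_mi)
    add_markers(c("mi_end", "rest_start"))
    emit_chunk("rest", mi_rest_ticks())
  }

  data <- do.call(rbind, raw_pieces)
  markers <- data.frame(label = marker_labels, sample = marker_samples)
  markers <- rbind(markers,
                   data.frame(label = "block_end", sample = nrow(data)))
  recording <- nfb_recording(data, markers)
  log <- structure(list(ticks = do.call(rbind, tick_logs),
                        trials = do.call(rbind, trial_logs),
                        baseline = baseline, mode = "real"),
                   class = "session_log")
  list(recording = recording, log = log)
}
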