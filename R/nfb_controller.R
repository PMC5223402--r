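#' Difficulty table
#'
#' One row per difficulty level from -1 to 15. The left-hemisphere weight
#' `lw` is 1 throughout. The right-hemisphere weight `rw` is 0 for levels
#' <= 4, rises by 0.1 per level over 5-13, and is 1 at levels 14-15. The
#' score thresholds `[lower, upper]` climb over levels -1..4 and are [2, 6]
#' for 4-14, collapsing to [2, 2] at level 15.
#'
#' @return data frame with columns `level`, `lw`, `rw`, `lower`, `upper`.
#' @export
difficulty_table <- function() {
  level <- -1:15
  rw <- ifelse(level <= 4, 0, ifelse(level >= 14, 1, (level - 4) / 10))
  lower <- c(-8, -6, -4, -2, 0, rep(2, 11), 2)
  upper <- c(-4, -2, 0, 2, 4, rep(6, 10), 2, 2)
  data.frame(level = level, lw = 1, rw = rw, lower = lower, upper = upper)
}

#' Parameters of one difficulty level
#'
#' @param level integer in \[-1, 15\].
#' @return one-row data frame (`level`, `lw`, `rw`, `lower`, `upper`).
#' @export
difficulty_params <- function(level) {
  tab <- difficulty_table()
  if (length(level) != 1L || !level %in% tab$level)
    stop("level must be a single integer in [-1, 15]")
  tab[tab$level == level, , drop = FALSE]
}

#' Engine configuration
#'
#' The trial and session schedule and the controller constants of the
#' neurofeedback engine, all at their published defaults: 500-ms processing
#' ticks, 50-s trials followed by 10 s of rest, 10 trials per block, 3
#' blocks, difficulty titration over the final 20 s of each trial, a 2-s
#' video-score lockout, a 15-s baseline block, a closing block of 10 x 20-s
#' motor-imagery trials with rest randomized on \[8, 12\] s, and an EMG gate
#' at baseline mean + 2 SD.
#'
#' @param tick,trial,rest,baseline,titration_window,lockout,mi_duration
#'   durations in seconds.
#' @param trials_per_block,blocks,mi_trials counts.
#' @param mi_rest numeric length-2, rest jitter range in seconds.
#' @param emg_sd_multiplier EMG gate multiplier.
#' @param band a [mu_band()].
#' @param smoothing_window running-average length in ticks.
#' @param difficulty the difficulty table.
#' @return list of class `engine_config`.
#' @export
engine_config <- function(tick = 0.5, trial = 50, rest = 10,
                          trials_per_block = 10L, blocks = 3L,
                          titration_window = 20, lockout = 2, baseline = 15,
                          mi_trials = 10L, mi_duration = 20,
                          mi_rest = c(8, 12), emg_sd_multiplier = 2,
                          band = mu_band(), smoothing_window = 6L,
                          difficulty = difficulty_table()) {
  stopifnot(tick > 0, trial > 0, rest > 0, baseline > 0, lockout > 0,
            trials_per_block >= 1, blocks >= 1, mi_trials >= 0,
            mi_duration > 0, length(mi_rest) == 2, mi_rest[1] <= mi_rest[2],
            emg_sd_multiplier > 0, smoothing_window >= 1)
  if (titration_window > trial)
    stop("titration window cannot exceed the trial duration")
  cfg <- list(tick = tick, trial = trial, rest = rest,
              trials_per_block = as.integer(trials_per_block),
              blocks = as.integer(blocks),
              titration_window = titration_window, lockout = lockout,
              baseline = baseline, mi_trials = as.integer(mi_trials),
              mi_duration = mi_duration, mi_rest = mi_rest,
              emg_sd_multiplier = emg_sd_multiplier, band = band,
              smoothing_window = as.integer(smoothing_window),
              difficulty = difficulty)
  cfg$ticks_per_trial <- as.integer(round(trial / tick))
  cfg$ticks_per_rest <- as.integer(round(rest / tick))
  cfg$ticks_baseline <- as.integer(round(baseline / tick))
  cfg$ticks_titration <- as.integer(round(titration_window / tick))
  cfg$ticks_lockout <- as.integer(round(lockout / tick))
  cfg$ticks_mi <- as.integer(round(mi_duration / tick))
  structure(cfg, class = "engine_config")
}

#' Neurofeedback score (hemisphere-weighted lateralization metric)
#'
#' `score = rw * log2(C4/C4b + CP4/CP4b) - lw * log2(C3/C3b + CP3/CP3b)`,
#' where each term is the log2 of the *sum* of the two channels'
#' power-to-baseline ratios for that hemisphere. At rest (all ratios 1) each
#' hemisphere term is log2(2) = 1, so the resting score is `rw - lw`
#' (e.g. -1 at the low difficulty levels where rw = 0). Contralateral
#' (left) ERD raises the score; ipsilateral (right) ERS raises it when
#' rw > 0.
#'
#' @param powers named numeric vector of (smoothed) band powers at `C3`,
#'   `CP3`, `C4`, `CP4`, microvolt-squared.
#' @param baseline an `nfb_baseline` (or a named vector of baseline powers).
#' @param row a difficulty row from [difficulty_params()].
#' @param normalize if `TRUE`, each hemisphere term uses the mean rather
#'   than the sum of the two channel ratios (removing the resting log2(2)
#'   offset); default `FALSE`, the form as published.
#' @return the score (numeric scalar).
#' @export
compute_nfb_score <- function(powers, baseline, row, normalize = FALSE) {
  base <- if (inherits(baseline, "nfb_baseline")) baseline$mu_power else baseline
  if (any(base[EEG_CHANNELS] <= 0)) stop("baseline powers must be positive")
  ratio <- powers[EEG_CHANNELS] / base[EEG_CHANNELS]
  denom <- if (normalize) 2 else 1
  left <- log2(sum(ratio[LEFT_CHANNELS]) / denom)
  right <- log2(sum(ratio[RIGHT_CHANNELS]) / denom)
  unname(row$rw * right - row$lw * left)
}

#' EMG gate
#'
#' Flags a 500-ms segment as contaminated by overt muscle activity when the
#' rectified mean of either EMG channel strictly exceeds its baseline mean
#' plus `multiplier` baseline SDs.
#'
#' @param segment 500 x channels matrix (must include the EMG channels), or
#'   a named vector of precomputed rectified EMG means.
#' @param baseline an `nfb_baseline`.
#' @param multiplier SD multiplier (default 2).
#' @return logical flag.
#' @export
emg_gate <- function(segment, baseline, multiplier = 2) {
  m <- if (is.null(dim(segment))) segment[EMG_CHANNELS] else
    rectified_emg_means(segment)
  any(m > baseline$emg_mean + multiplier * baseline$emg_sd)
}

#' Initial feedback state
#'
#' @param level starting difficulty level (sessions start at 1).
#' @return list of class `feedback_state`: `video_score`,
#'   `lockout_remaining` (ticks), `level`, `level1_streak`, `tick_index`.
#' @export
feedback_state <- function(level = 1L) {
  structure(list(video_score = 1L, lockout_remaining = 0L,
                 level = as.integer(level), level1_streak = 0L,
                 tick_index = 0L),
            class = "feedback_state")
}

#' Advance the video score by one tick
#'
#' Excess EMG resets the video score to 1 and restarts the lockout. During a
#' lockout the score is frozen and the lockout counts down. Otherwise a
#' score strictly above the upper threshold raises the video score by 1
#' (capped at 6) and a score strictly below the lower threshold lowers it by
#' 1 (floored at 1); any actual change starts a `lockout_ticks` lockout.
#'
#' @param state a `feedback_state`.
#' @param score current neurofeedback score.
#' @param row difficulty row (thresholds `lower`, `upper`).
#' @param emg_flag logical from [emg_gate()].
#' @param lockout_ticks lockout length in ticks (2 s = 4 ticks).
#' @return the updated `feedback_state`.
#' @export
step_video_score <- function(state, score, row, emg_flag = FALSE,
                             lockout_ticks = 4L) {
  state$tick_index <- state$tick_index + 1L
  if (isTRUE(emg_flag)) {
    state$video_score <- 1L
    state$lockout_remaining <- as.integer(lockout_ticks)
    return(state)
  }
  if (state$lockout_remaining > 0L) {
    state$lockout_remaining <- state$lockout_remaining - 1L
    return(state)
  }
  vs <- state$video_score
  if (score > row$upper) {
    new <- min(6L, vs + 1L)
  } else if (score < row$lower) {
    new <- max(1L, vs - 1L)
  } else {
    new <- vs
  }
  if (new != vs) state$lockout_remaining <- as.integer(lockout_ticks)
  state$video_score <- new
  state
}

#' End-of-trial difficulty titration
#'
#' The video scores from the final titration window (20 s = 40 ticks) are
#' averaged: a mean strictly above 4 raises the difficulty level (capped at
#' 15), a mean strictly below 2 lowers it. Demotion below level 1 is only
#' possible once the subject has completed three consecutive trials at
#' level 1 (the just-completed trial counts toward the streak); the floor is
#' level -1.
#'
#' @param video_scores integer vector of the completed trial's per-tick
#'   video scores (>= the titration window).
#' @param state a `feedback_state` (fields `level`, `level1_streak`).
#' @param config an [engine_config()].
#' @return the state with updated `level` and `level1_streak`, plus a
#'   `titration_mean` attribute-free field `last_titration_mean`.
#' @export
end_of_trial_update <- function(video_scores, state, config = engine_config()) {
  nt <- config$ticks_titration
  if (length(video_scores) < nt)
    stop("trial shorter than the titration window")
  m <- mean(utils::tail(video_scores, nt))
  level <- state$level
  streak <- if (level == 1L) state$level1_streak + 1L else 0L
  new_level <- level
  if (m > 4) {
    new_level <- min(15L, level + 1L)
  } else if (m < 2) {
    if (level > 1L) {
      new_level <- level - 1L
    } else if (level == 1L) {
      if (streak >= 3L) new_level <- 0L
    } else {
      new_level <- max(-1L, level - 1L)
    }
  }
  if (new_level != 1L) streak <- 0L
  state$level <- as.integer(new_level)
  state$level1_streak <- streak
  state$last_titration_mean <- m
  state
}

# ---- session orchestration over a recorded stream --------------------------

# Split a recording into contiguous chunks delimited by its markers; each
# chunk carries its role (baseline/trial/rest/mi/mi_rest), block and trial
# bookkeeping. Chunks are the unit of streaming preprocessing.
session_chunks <- function(recording, config) {
  mk <- recording$markers
  if (nrow(mk) == 0L) stop("recording has no markers")
  bounds <- sort(unique(c(mk$sample, n_samples(recording) + 1L)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1] - 1L
  labels_at <- function(s) mk$label[mk$sample == s]
  role <- character(length(starts)); block <- integer(length(starts))
  trial <- integer(length(starts))
  cur_block <- 0L; cur_trial <- 0L; in_mi <- FALSE
  for (i in seq_along(starts)) {
    labs <- labels_at(starts[i])
    if ("block_start" %in% labs) {
      cur_block <- cur_block + 1L
      in_mi <- cur_block > config$blocks
    }
    role[i] <-
      if ("baseline_start" %in% labs) "baseline"
      else if ("trial_start" %in% labs) { cur_trial <- cur_trial + 1L; "trial" }
      else if ("mi_start" %in% labs) { cur_trial <- cur_trial + 1L; "mi" }
      else if ("rest_start" %in% labs) { if (in_mi) "mi_rest" else "rest" }
      else "other"
    block[i] <- cur_block; trial[i] <- cur_trial
  }
  data.frame(start = starts, end = ends, role = role, block = block,
             trial = trial)
}

# Streaming preprocessing of a recording, chunk by chunk: causal band-pass +
# notch on the EEG channels (state carried across chunks), then per-chunk
# ocular event detection and first-component attenuation. Returns the
# preprocessed recording. Mirrors exactly what the closed-loop simulator
# applies tick by tick.
preprocess_online <- function(recording, chunks,
                              pconfig = preproc_config("online")) {
  st <- filter_state_init(pconfig, length(EEG_CHANNELS))
  for (i in seq_len(nrow(chunks))) {
    rows <- chunks$start[i]:chunks$end[i]
    fs <- filter_stream(pconfig, recording$data[rows, EEG_CHANNELS,
                                                drop = FALSE], st)
    recording$data[rows, EEG_CHANNELS] <- fs$segment
    st <- fs$state
    ev <- detect_eog_events(recording$data[rows, EOG_CHANNELS, drop = FALSE],
                            pconfig$eog_threshold)
    if (length(ev) > 0L) {
      sub <- nfb_recording(recording$data[rows, , drop = FALSE])
      sub <- attenuate_artifact_pca(sub, ev, pconfig$artifact_window)
      recording$data[rows, ] <- sub$data
    }
  }
  recording
}

# Per-tick channel powers and rectified EMG means for a chunk of a
# preprocessed recording.
chunk_tick_metrics <- function(recording, start, end, band) {
  spt <- samples_per_tick(recording$sample_rate)
  nt <- (end - start + 1L) %/% spt
  pw <- matrix(0, nt, 4, dimnames = list(NULL, EEG_CHANNELS))
  em <- matrix(0, nt, 2, dimnames = list(NULL, EMG_CHANNELS))
  for (i in seq_len(nt)) {
    rows <- (start + (i - 1L) * spt):(start + i * spt - 1L)
    seg <- recording$data[rows, , drop = FALSE]
    pw[i, ] <- segment_band_power(seg, band, recording$sample_rate)
    em[i, ] <- rectified_emg_means(seg)
  }
  list(power = pw, emg = em)
}

# Run the controller over one trial's tick metrics. Returns per-tick log
# rows and the updated feedback state. In sham mode the presented video
# score and level come from the yoke rows; EMG never alters them.
run_trial_ticks <- function(metrics, baseline, state, config, mode = "real",
                            yoke_rows = NULL) {
  nt <- nrow(metrics$power)
  row <- difficulty_params(state$level)
  vs <- integer(nt); sc <- numeric(nt); emg <- logical(nt); lev <- integer(nt)
  hist <- matrix(NA_real_, 0, 4)
  for (i in seq_len(nt)) {
    hist <- rbind(hist, metrics$power[i, ])
    w <- max(1L, i - config$smoothing_window + 1L):i
    smoothed <- colMeans(hist[w, , drop = FALSE])
    sc[i] <- compute_nfb_score(smoothed, baseline, row)
    emg[i] <- emg_gate(metrics$emg[i, ], baseline, config$emg_sd_multiplier)
    if (mode == "real") {
      # the frame shown during tick i carries the score as of tick i-1;
      # the update computed from tick i takes effect on the next frame
      vs[i] <- state$video_score
      lev[i] <- state$level
      state <- step_video_score(state, sc[i], row, emg[i],
                                config$ticks_lockout)
    } else {
      vs[i] <- yoke_rows$video_score[i]
      lev[i] <- yoke_rows$level[i]
    }
  }
  list(video_score = vs, nfb_score = sc, emg_flag = emg, level = lev,
       state = state)
}

#' Run a neurofeedback session over a recorded stream
#'
#' Processes a recording tick by tick through the full online pipeline
#' (causal filtering, ocular-artifact attenuation, mu band power, 6-tick
#' smoothing, the hemisphere-weighted score, EMG gating, the video-score
#' state machine and end-of-trial difficulty titration). In `real` mode the
#' controller runs live: the session starts at difficulty level 1 and the
#' video score resets to 1 at each trial start. In `sham` mode the presented
#' video score and difficulty level are replayed verbatim from the yoke log
#' (EMG flags are still computed and logged but never alter the presented
#' stimulus).
#'
#' @param recording an `nfb_recording` with session markers (as produced by
#'   [simulate_closed_loop_session()] or read from file).
#' @param config an [engine_config()].
#' @param mode `"real"` or `"sham"`.
#' @param yoke a `session_log` to replay (required in sham mode).
#' @return a `session_log`: list with `ticks` (per-tick data frame: `tick`,
#'   `time_s`, `block`, `trial`, `nfb_score`, `video_score`, `level`,
#'   `emg_flag`) and `trials` (per-trial data frame: `trial`, `block`,
#'   `level_before`, `level_after`, `titration_mean`).
#' @export
run_session <- function(recording, config = engine_config(),
                        mode = c("real", "sham"), yoke = NULL) {
  mode <- match.arg(mode)
  if (mode == "sham" && is.null(yoke))
    stop("sham mode requires a yoke log")
  chunks <- session_chunks(recording, config)
  if (!"baseline" %in% chunks$role)
    stop("recording lacks a baseline block")
  rec <- preprocess_online(recording, chunks)
  bl_chunk <- chunks[chunks$role == "baseline", ][1, ]
  baseline <- compute_baseline_profile(
    nfb_recording(rec$data[bl_chunk$start:bl_chunk$end, , drop = FALSE]),
    config$band)

  trial_chunks <- chunks[chunks$role == "trial", ]
  n_trials <- nrow(trial_chunks)
  if (mode == "sham") {
    expect <- n_trials * config$ticks_per_trial
    if (nrow(yoke$ticks) != expect)
      stop("yoke log does not match the session schedule (",
           nrow(yoke$ticks), " ticks, expected ", expect, ")")
  }
  state <- feedback_state(level = 1L)
  tick_logs <- vector("list", n_trials)
  trial_logs <- vector("list", n_trials)
  tick0 <- 0L
  for (ti in seq_len(n_trials)) {
    ch <- trial_chunks[ti, ]
    metrics <- chunk_tick_metrics(rec, ch$start, ch$end, config$band)
    state$video_score <- 1L           # video restarts black-and-white
    state$lockout_remaining <- 0L
    level_before <- state$level
    yoke_rows <- if (mode == "sham")
      yoke$ticks[tick0 + seq_len(nrow(metrics$power)), ] else NULL
    res <- run_trial_ticks(metrics, baseline, state, config, mode, yoke_rows)
    state <- res$state
    nt <- length(res$video_score)
    tick_logs[[ti]] <- data.frame(
      tick = tick0 + seq_len(nt),
      time_s = (ch$start - 1L) / rec$sample_rate + seq_len(nt) * config$tick,
      block = ch$block, trial = ti,
      nfb_score = res$nfb_score, video_score = res$video_score,
      level = res$level, emg_flag = res$emg_flag)
    tick0 <- tick0 + nt
    if (mode == "real") {
      state <- end_of_trial_update(res$video_score, state, config)
      tm <- state$last_titration_mean
    } else {
      nxt <- if (ti < n_trials) yoke$trials$level_after[ti] else
        yoke$trials$level_after[ti]
      state$level <- nxt
      tm <- yoke$trials$titration_mean[ti]
    }
    trial_logs[[ti]] <- data.frame(
      trial = ti, block = ch$block, level_before = level_before,
      level_after = state$level, titration_mean = tm)
  }
  structure(list(ticks = do.call(rbind, tick_logs),
                 trials = do.call(rbind, trial_logs),
                 baseline = baseline, mode = mode),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s mode: %d trials, %d ticks, final level %d\n",
              x$mode, nrow(x$trials), nrow(x$ticks),
              utils::tail(x$trials$level_after, 1)))
  invisible(x)
}
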