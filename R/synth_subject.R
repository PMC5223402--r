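#' Virtual subject profile
#'
#' Generative parameters of a simulated participant. The mu rhythm is an
#' amplitude-modulated sinusoid at `mu_freq`; during imagined imitation (ii)
#' or motor imagery (mi) its amplitude at each hemisphere's channels is
#' scaled by the square root of the corresponding power ratio, so band power
#' scales by the ratio itself (negative log2 ratios are ERD). A 1/f
#' background, blink artifacts on the ocular channels (with bleed-through
#' into EEG) and EMG bursts complete the signal model.
#'
#' The burst-free EMG envelope is amplitude-stabilized: each 500-ms tick's
#' rectified mean follows a slow, bounded sinusoidal modulation (+/-5% around
#' `emg_amp`), so the baseline-mean + 2 SD gate never fires unless a burst is
#' scheduled.
#'
#' @param contra_ratio_task target mu-power ratio (task/baseline) at the
#'   left-hemisphere (contralateral) channels during ii/mi; > 0, < 1 is ERD.
#' @param ipsi_ratio_task same for the right-hemisphere channels.
#' @param responsiveness per-trial multiplicative drift: after each trial
#'   whose mean video score exceeds 4, `contra_ratio_task` is multiplied by
#'   `1 - responsiveness` (floored at 0.05); 0 disables learning.
#' @param mu_freq mu center frequency, Hz.
#' @param mu_amp baseline mu amplitude, microvolts.
#' @param noise_amp RMS of the 1/f background (and ocular channel noise),
#'   microvolts.
#' @param blink_rate blinks per minute.
#' @param emg_burst_rate EMG bursts per minute.
#' @param emg_amp baseline EMG RMS, microvolts.
#' @param seed RNG seed used by the generator entry points.
#' @return list of class `subject_profile`.
#' @export
subject_profile <- function(contra_ratio_task = 0.5, ipsi_ratio_task = 1,
                            responsiveness = 0, mu_freq = 10, mu_amp = 10,
                            noise_amp = 2, blink_rate = 8,
                            emg_burst_rate = 2, emg_amp = 5, seed = 1L) {
  stopifnot(contra_ratio_task > 0, ipsi_ratio_task > 0, responsiveness >= 0,
            mu_freq > 0, mu_amp >= 0, noise_amp >= 0, blink_rate >= 0,
            emg_burst_rate >= 0, emg_amp >= 0)
  structure(list(contra_ratio_task = contra_ratio_task,
                 ipsi_ratio_task = ipsi_ratio_task,
                 responsiveness = responsiveness,
                 mu_freq = mu_freq, mu_amp = mu_amp, noise_amp = noise_amp,
                 blink_rate = blink_rate, emg_burst_rate = emg_burst_rate,
                 emg_amp = emg_amp, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Initialize generator state
#'
#' Seeds the RNG from the profile and zeroes the phase/time accumulators, so
#' every generator entry point is reproducible given the profile seed.
#'
#' @param profile a [subject_profile()].
#' @param seed optional seed overriding `profile$seed`.
#' @return opaque generator state.
#' @export
gen_state_init <- function(profile, seed = profile$seed) {
  set.seed(seed)
  list(t0 = 0, sr = 1000)
}

TASK_STATES <- c("rest", "ii", "mi")

# cached 20-450 Hz shaping filter for the EMG noise floor
emg_band_coefs <- local({
  cache <- list()
  function(sr) {
    key <- as.character(sr)
    if (is.null(cache[[key]])) {
      bf <- signal::butter(2, c(20, 450) / (sr / 2), type = "pass")
      cache[[key]] <<- list(b = bf$b, a = bf$a)
    }
    cache[[key]]
  }
})

# 1/f-shaped noise vector with target RMS, length n at sample rate sr.
pink_noise <- function(n, rms, sr) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sr / n
  f <- pmin(f, sr - f)              # mirrored frequency axis
  shape <- 1 / sqrt(pmax(f, 1))     # flatten below 1 Hz to keep DC bounded
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# Generate a contiguous chunk of n_ticks ticks in one task state.
# Returns list(data = samples x ALL_CHANNELS matrix, state = advanced state).
generate_chunk <- function(profile, task_state, ticks, state) {
  task_state <- match.arg(task_state, TASK_STATES)
  sr <- state$sr
  spt <- samples_per_tick(sr)
  n <- ticks * spt
  tt <- state$t0 + (seq_len(n) - 1) / sr
  data <- matrix(0, n, length(ALL_CHANNELS),
                 dimnames = list(NULL, ALL_CHANNELS))

  ratio <- c(rep(if (task_state == "rest") 1 else profile$contra_ratio_task, 2),
             rep(if (task_state == "rest") 1 else profile$ipsi_ratio_task, 2))
  mu_wave <- sin(2 * pi * profile$mu_freq * tt)
  for (k in seq_along(EEG_CHANNELS)) {
    ch <- EEG_CHANNELS[k]
    data[, ch] <- profile$mu_amp * sqrt(ratio[k]) * mu_wave +
      pink_noise(n, profile$noise_amp, sr)
  }

  # ocular channels: white noise plus scheduled blinks
  if (profile$noise_amp > 0) {
    for (ch in EOG_CHANNELS)
      data[, ch] <- stats::rnorm(n, sd = profile$noise_amp)
  }
  dur <- n / sr
  n_blinks <- stats::rpois(1, profile$blink_rate * dur / 60)
  blink_len <- round(0.4 * sr)
  if (n_blinks > 0 && n > blink_len) {
    starts <- sort(sample.int(n - blink_len, n_blinks, replace = TRUE))
    shape <- 300 * 0.5 * (1 - cos(2 * pi * seq_len(blink_len) / blink_len))
    for (s in starts) {
      idx <- s:(s + blink_len - 1L)
      data[idx, "EOG_up"] <- data[idx, "EOG_up"] + shape
      data[idx, "EOG_down"] <- data[idx, "EOG_down"] - shape
      data[idx, EEG_CHANNELS] <- data[idx, EEG_CHANNELS] + 0.2 * shape
    }
  }

  # EMG: band-limited noise, rectified mean pinned per tick to a bounded
  # slow modulation; scheduled bursts scale a whole tick by 5.
  if (profile$emg_amp > 0) {
    bf <- emg_band_coefs(sr)
    for (ch in EMG_CHANNELS) {
      raw <- stats::rnorm(n)
      raw <- .df2t_filter(bf$b, bf$a, matrix(raw, ncol = 1L),
                          matrix(0, max(length(bf$b), length(bf$a)) - 1L,
                                 1L))$y[, 1]
      burst <- stats::runif(ticks) < profile$emg_burst_rate * (spt / sr) / 60
      for (i in seq_len(ticks)) {
        rows <- tick_rows(i, spt)
        t_mid <- state$t0 + (i - 0.5) * spt / sr
        target <- profile$emg_amp * sqrt(2 / pi) *
          (1 + 0.05 * sin(2 * pi * t_mid / 5))
        if (burst[i]) target <- 5 * target
        m <- mean(abs(raw[rows]))
        data[rows, ch] <- if (m > 0) raw[rows] * target / m else 0
      }
    }
  }

  state$t0 <- state$t0 + dur
  list(data = data, state = state)
}

#' Generate a rest-state baseline recording
#'
#' Mu at baseline amplitude with no task modulation, plus background noise
#' and artifacts per the profile; deterministic given the profile seed.
#'
#' @param profile a [subject_profile()].
#' @param duration duration in seconds (> 0; realized on the 500-ms tick
#'   grid).
#' @return an `nfb_recording` with a `baseline_start` marker at sample 1.
#' @export
generate_baseline_recording <- function(profile, duration = 15) {
  if (duration <= 0) stop("duration must be positive")
  ticks <- max(1L, round(duration / 0.5))
  st <- gen_state_init(profile)
  chunk <- generate_chunk(profile, "rest", ticks, st)
  nfb_recording(chunk$data,
                data.frame(label = "baseline_start", sample = 1L))
}

#' Generate a single 500-ms segment
#'
#' During `ii`/`mi`, left-channel mu power is `contra_ratio_task` times and
#' right-channel mu power `ipsi_ratio_task` times the baseline power, in
#' expectation.
#'
#' @param profile a [subject_profile()].
#' @param task_state one of `"rest"`, `"ii"`, `"mi"`.
#' @param gen_state state from [gen_state_init()] or a previous call.
#' @return list with `segment` (500 x 10 matrix) and `gen_state`.
#' @export
generate_tick <- function(profile, task_state, gen_state) {
  chunk <- generate_chunk(profile, task_state, 1L, gen_state)
  list(segment = chunk$data, gen_state = chunk$state)
}
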