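make_stream_state <- function(cfg) filter_state_init(cfg, 1L)

test_that("mastoid re-referencing subtracts the reference mean from EEG only", {
  rec <- zero_recording(1)
  rec$data[] <- 3
  n <- nrow(rec$data)
  # zero references leave everything unchanged
  expect_identical(rereference_to_mastoids(rec, numeric(n), numeric(n))$data,
                   rec$data)
  # channels equal to the reference mean cancel exactly
  out <- rereference_to_mastoids(rec, rep(2, n), rep(4, n))
  expect_true(all(out$data[, c("C3", "CP3", "C4", "CP4")] == 0))
  expect_true(all(out$data[, "EOG_up"] == 3))
  # constant 5 uV refs shift every EEG sample by 5
  rec$data[] <- 10
  out <- rereference_to_mastoids(rec, rep(5, n), rep(5, n))
  expect_true(all(out$data[, "C4"] == 5))
  expect_error(rereference_to_mastoids(rec, numeric(2), numeric(2)), "length")
})

test_that("the online filter passes mu and rejects line noise", {
  cfg <- preproc_config("online")
  t <- seq(0, 4, by = 1e-3)[-1]
  gain_of <- function(f) {
    x <- matrix(sin(2 * pi * f * t), ncol = 1)
    y <- filter_stream(cfg, x, make_stream_state(cfg))$segment
    tail_idx <- (length(t) - 999):length(t)   # after settling
    sqrt(mean(y[tail_idx, 1]^2)) / sqrt(mean(x[tail_idx, 1]^2))
  }
  expect_lt(20 * log10(gain_of(60)), -20)
  expect_lt(abs(20 * log10(gain_of(10))), 1)
})

test_that("streaming chunk-wise filtering equals one-shot filtering", {
  cfg <- preproc_config("online")
  set.seed(1)
  x <- matrix(rnorm(1000, sd = 20), ncol = 1)
  whole <- filter_stream(cfg, x, make_stream_state(cfg))$segment
  st <- make_stream_state(cfg)
  a <- filter_stream(cfg, x[1:500, , drop = FALSE], st)
  b <- filter_stream(cfg, x[501:1000, , drop = FALSE], a$state)
  expect_lt(max(abs(rbind(a$segment, b$segment) - whole)), 1e-9)
})

test_that("filtering is linear", {
  cfg <- preproc_config("online")
  set.seed(2)
  x <- matrix(rnorm(2000), ncol = 1)
  y <- matrix(rnorm(2000), ncol = 1)
  f <- function(z) filter_stream(cfg, z, make_stream_state(cfg))$segment
  expect_lt(max(abs(f(2 * x - 3 * y) - (2 * f(x) - 3 * f(y)))), 1e-9)
})

test_that("online and offline configs differ exactly where specified", {
  on <- preproc_config("online")
  off <- preproc_config("offline")
  expect_equal(on$hp_cutoff, 1.0)
  expect_equal(off$hp_cutoff, 0.5)
  expect_equal(on$lp_cutoff, 100)
  expect_true(is.na(off$lp_cutoff))
  expect_equal(on$eog_threshold, 360)
  expect_equal(off$eog_threshold, 200)
  expect_false(on$zero_phase)
  expect_true(off$zero_phase)
  expect_equal(on$notch, off$notch)
  expect_equal(on$artifact_window, off$artifact_window)
  expect_equal(on$dc_window, off$dc_window)
})

blink_shape <- function(amp = 300, len = 400) {
  amp * 0.5 * (1 - cos(2 * pi * seq_len(len) / len))
}

test_that("ocular events are detected at excursion peaks", {
  expect_identical(detect_eog_events(matrix(0, 1000, 4), 200), integer(0))
  x <- matrix(0, 3000, 1)
  x[301:700, 1] <- blink_shape(300)
  ev <- detect_eog_events(x, 200)
  expect_equal(ev, 300L + 200L)   # raised-cosine peak at window center
  x[2301:2700, 1] <- blink_shape(-300)
  expect_length(detect_eog_events(x, 200), 2L)
})

test_that("first-component attenuation removes rank-1 artifacts exactly", {
  chans <- c("C3", "CP3", "C4", "CP4", "EOG_up", "EOG_down",
             "EOG_left", "EOG_right")
  pattern <- c(0.2, 0.2, 0.2, 0.2, 1, -1, 0.1, 0.1)
  rec <- zero_recording(3)
  tc <- c(rep(0, 1000), blink_shape(300), rep(0, 1600))
  rec$data[, chans] <- outer(tc, pattern)
  ev <- detect_eog_events(rec$data[, c("EOG_up", "EOG_down",
                                       "EOG_left", "EOG_right")], 200)
  out <- attenuate_artifact_pca(rec, ev)
  expect_lt(sqrt(mean(out$data[, chans]^2)), 1e-6)
  # untouched without events
  expect_identical(attenuate_artifact_pca(rec, integer(0))$data, rec$data)
})

test_that("attenuation preserves orthogonal activity and out-of-window data", {
  chans <- c("C3", "CP3", "C4", "CP4", "EOG_up", "EOG_down",
             "EOG_left", "EOG_right")
  p <- rep(1, 8) / sqrt(8)            # artifact pattern
  q <- rep(c(1, -1), 4) / sqrt(8)     # orthogonal signal pattern
  rec <- zero_recording(3)
  tc <- c(rep(0, 1000), blink_shape(300), rep(0, 1600))
  sig <- 5 * sin(2 * pi * 10 * seq_len(3000) / 1000)
  rec$data[, chans] <- outer(tc, p) + outer(sig, q)
  before <- rec$data
  out <- attenuate_artifact_pca(rec, 1200L)
  win <- 1000:1700
  resid <- out$data[win, chans] - outer(sig[win], q)
  expect_lt(sqrt(mean(resid^2)) / sqrt(mean(outer(sig[win], q)^2)), 0.01)
  outside <- setdiff(seq_len(3000), win)
  expect_identical(out$data[outside, ], before[outside, ])
  expect_error(attenuate_artifact_pca(rec, 99999L), "bounds")
})

test_that("DC correction subtracts the early-window mean from whole traces", {
  rec <- zero_recording(5)
  rec$data[, "C3"] <- 7
  out <- baseline_correct_dc(rec)
  expect_true(all(out$data[, "C3"] == 0))
  t <- seq_len(5000) / 1000
  rec$data[, "C4"] <- sin(2 * pi * 10 * t)          # whole cycles in 3 s
  rec$data[, "CP3"] <- sin(2 * pi * 10 * t) + 3
  out <- baseline_correct_dc(rec)
  expect_lt(max(abs(out$data[, "C4"] - sin(2 * pi * 10 * t))), 1e-9)
  expect_lt(max(abs(out$data[, "CP3"] - sin(2 * pi * 10 * t))), 1e-9)
  expect_error(baseline_correct_dc(zero_recording(1)), "shorter")
})
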