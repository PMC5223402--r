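test_that("epoching a default session reconstructs the schedule", {
  sim <- default_sim()
  ep <- epoch_by_markers(sim$recording, engine_config())
  expect_equal(sum(ep$kind == "nfb"), 30L)
  expect_true(all(ep$duration_s[ep$kind == "nfb"] == 50))
  expect_equal(sum(ep$kind == "rest"), 30L)
  expect_true(all(ep$duration_s[ep$kind == "rest"] == 10))
  expect_equal(sum(ep$kind == "mi"), 10L)
  expect_true(all(ep$duration_s[ep$kind == "mi"] == 20))
  expect_equal(sum(ep$kind == "baseline"), 1L)
  expect_equal(ep$duration_s[ep$kind == "baseline"], 15)
  # motor-imagery rests carry their own label and the published jitter range
  mi_rest <- ep$duration_s[ep$kind == "mi_rest"]
  expect_equal(length(mi_rest), 11L)  # initial rest + one per MI trial
  expect_true(all(mi_rest >= 8 & mi_rest <= 12))
  expect_warning(epoch_by_markers(zero_recording(1)), "no markers")
})

test_that("unmatched trial markers are rejected", {
  mk <- data.frame(label = c("trial_start", "trial_end", "trial_start"),
                   sample = c(1L, 1000L, 1500L))
  rec <- zero_recording(2, markers = mk)
  expect_error(epoch_by_markers(rec), "unmatched")
})

test_that("EMG rejection drops exactly the scheduled burst ticks", {
  p <- clean_profile(seed = 37L)
  rec <- generate_baseline_recording(p, 25)
  rec$markers <- data.frame(label = c("baseline_start", "trial_start",
                                      "trial_end"),
                            sample = c(1L, 15001L, 25001L))
  # trial_end at sample 25001 is out of range; clamp to the last sample
  rec$markers$sample[3] <- 25000L
  base <- compute_baseline_profile(
    nfb_recording(rec$data[1:15000, , drop = FALSE]))
  burst_ticks <- c(3L, 7L, 12L)    # within the 20-tick trial epoch
  for (b in burst_ticks) {
    rows <- (15000L + (b - 1L) * 500L):(15000L + b * 500L - 1L)
    rec$data[rows, c("EMG_flex", "EMG_ext")] <-
      5 * rec$data[rows, c("EMG_flex", "EMG_ext")]
  }
  ep <- epoch_by_markers(rec)
  rej <- reject_emg_segments(rec, ep[ep$kind == "nfb", ], base)
  expect_equal(sum(rej$ticks$emg_flag), length(burst_ticks))
  expect_equal(sort(rej$ticks$tick[rej$ticks$emg_flag]), burst_ticks)
  expect_equal(rej$rejected_fraction, 3 / 19)
  # saturated EMG rejects everything
  rec$data[, c("EMG_flex", "EMG_ext")] <- 1e4
  rej2 <- reject_emg_segments(rec, ep[ep$kind == "nfb", ], base)
  expect_equal(rej2$rejected_fraction, 1)
})

erds_fixture <- function(scale = 1) {
  # noise-free mu recording: 15-s baseline then one 10-s feedback trial
  p <- clean_profile(mu_amp = 10, emg_amp = 0, seed = 41L)
  rec <- generate_baseline_recording(p, 25)
  rec$data <- rec$data * scale
  rec$markers <- data.frame(
    label = c("baseline_start", "trial_start", "trial_end"),
    sample = c(1L, 15001L, 25000L))
  rec
}

test_that("ERD/S values are zero at baseline power and shift with amplitude", {
  rec <- erds_fixture()
  ep <- epoch_by_markers(rec)
  base <- compute_baseline_profile(nfb_recording(rec$data[1:15000, , drop = FALSE]))
  kept <- reject_emg_segments(rec, ep[ep$kind == "nfb", ], base)$kept
  tab <- compute_erds_table(rec, kept, ep, "nfb")
  expect_true(all(c("group", "session", "task", "hemisphere", "tick",
                    "log2_erds") %in% names(tab)))
  expect_lt(max(abs(tab$log2_erds)), 1e-6)
  # doubling every amplitude adds exactly +2 to every record relative to
  # the *original* baseline window
  rec2 <- erds_fixture()
  trial_rows <- 15001:25000
  rec2$data[trial_rows, ] <- 2 * rec2$data[trial_rows, ]
  tab2 <- compute_erds_table(rec2, kept, ep, "nfb")
  expect_equal(tab2$log2_erds, tab$log2_erds + 2, tolerance = 1e-9)
})

test_that("offline analysis recovers the programmed left-only ERD", {
  p <- clean_profile(contra_ratio_task = 0.5, ipsi_ratio_task = 1, seed = 43L)
  sim <- simulate_closed_loop_session(p, small_config())
  res <- analyze_session(sim$recording, small_config())
  s <- summarize_group_session(res$erds)
  left <- s$mean_log2_erds[s$task == "nfb" & s$hemisphere == "left"]
  right <- s$mean_log2_erds[s$task == "nfb" & s$hemisphere == "right"]
  expect_lt(abs(left - (-1)), 0.2)
  expect_lt(abs(right - 0), 0.2)
  # the MI task shows the same left-lateralized pattern
  mi_left <- s$mean_log2_erds[s$task == "mi" & s$hemisphere == "left"]
  expect_lt(abs(mi_left - (-1)), 0.25)
})

test_that("group summaries equal brute-force grouped means", {
  set.seed(47)
  tab <- tibble::tibble(
    group = sample(c("nfb", "sham"), 200, TRUE),
    session = sample(1:4, 200, TRUE),
    task = sample(c("nfb", "mi"), 200, TRUE),
    hemisphere = sample(c("left", "right"), 200, TRUE),
    tick = 1:200,
    log2_erds = rnorm(200))
  s <- summarize_group_session(tab)
  key <- paste(tab$group, tab$session, tab$task, tab$hemisphere)
  oracle <- tapply(tab$log2_erds, key, mean)
  got <- setNames(s$mean_log2_erds,
                  paste(s$group, s$session, s$task, s$hemisphere))
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-12)
  one <- summarize_group_session(tab[1, ])
  expect_equal(one$mean_log2_erds, tab$log2_erds[1])
  expect_equal(nrow(one), 1L)
  two <- tab[1:2, ]
  two$group <- "nfb"; two$session <- 1L; two$task <- "nfb"
  two$hemisphere <- "left"
  two$log2_erds <- c(1.5, -1.5)
  expect_equal(summarize_group_session(two)$mean_log2_erds, 0)
  expect_error(summarize_group_session(tab[0, ]), "empty")
})

test_that("rejection is order-independent", {
  p <- clean_profile(emg_burst_rate = 30, seed = 53L)
  rec <- generate_baseline_recording(p, 30)
  rec$markers <- data.frame(
    label = c("baseline_start", "trial_start", "trial_end", "trial_start",
              "trial_end"),
    sample = c(1L, 15001L, 20001L, 20001L, 30000L))
  base <- compute_baseline_profile(nfb_recording(rec$data[1:15000, , drop = FALSE]))
  ep <- epoch_by_markers(rec)
  fwd <- reject_emg_segments(rec, ep[ep$kind == "nfb", ], base)
  rev <- reject_emg_segments(rec, ep[ep$kind == "nfb", ][2:1, ], base)
  expect_setequal(paste(fwd$kept$epoch, fwd$kept$tick),
                  paste(rev$kept$epoch, rev$kept$tick))
})
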