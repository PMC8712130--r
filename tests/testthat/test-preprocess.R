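fs <- 256

tone_recording <- function(freq, amp = 10, dur_s = 8, channels = c("Cz", "Pz")) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  signal_recording(amp * sin(2 * pi * freq * t), fs = fs, channels = channels)
}

interior <- function(x, fs, trim_s = 1) {
  x[(trim_s * fs):(length(x) - trim_s * fs)]
}

test_that("notch removes 50 Hz and the band-pass preserves 10 Hz", {
  rec50 <- tone_recording(50)
  out50 <- filter_recording(rec50)
  expect_lt(stats::sd(out50$data[, 1]) / stats::sd(rec50$data[, 1]), 0.05)

  rec10 <- tone_recording(10)
  out10 <- filter_recording(rec10)
  expect_gt(stats::sd(out10$data[, 1]) / stats::sd(rec10$data[, 1]), 0.90)
})

test_that("a constant signal is eliminated by the 1 Hz high-pass", {
  rec <- signal_recording(rep(25, 8 * fs), fs = fs)
  out <- filter_recording(rec)
  expect_lt(max(abs(out$data[, 1])), 0.5)
})

test_that("band edges outside (0, fs/2) are rejected", {
  rec <- tone_recording(10)
  expect_error(filter_recording(rec, band = c(1, 130)), "Band edges")
  expect_error(filter_recording(rec, band = c(0, 45)), "Band edges")
})

test_that("filtering is idempotent for passband content", {
  rec <- tone_recording(10, dur_s = 10)
  once <- filter_recording(rec)
  twice <- filter_recording(once)
  a <- interior(once$data[, 1], fs)
  b <- interior(twice$data[, 1], fs)
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.02)
})

blinky_sim <- function(blink_amp = 150, seed = 31) {
  cfg <- cohort_config(blink_rate_per_min = 10, artifact_prob = 0,
                       blink_amp_uV = blink_amp, blocks_per_level = 1L)
  profile <- subject_profile("S01", cfg, seed)
  profile$blink_amp_uV <- blink_amp
  plan <- generate_session("S01", "audio", seed, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, seed, cfg)
  sim
}

# Mean signed correlation with the blink template over all blink windows;
# averaging over blinks cancels the background's incidental correlation with
# the smooth template, leaving the systematic blink residual.
blink_window_cor <- function(rec, starts) {
  tpl <- vwmeeg:::blink_template(rec$fs)
  vapply(c("Fz", "F3", "Cz", "Pz"), function(ch) {
    vals <- vapply(starts, function(s0) {
      seg <- rec$data[s0 + seq_along(tpl) - 1L, ch]
      stats::cor(seg, tpl)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}

test_that("regression removes the blink component inside blink windows", {
  sim <- blinky_sim()
  starts <- sim$truth$blink_starts
  expect_gt(length(starts), 10)
  before <- blink_window_cor(sim$recording, starts)
  expect_gt(mean(before), 0.5)      # blinks clearly visible pre-removal
  cleaned <- remove_blinks(sim$recording)
  after <- blink_window_cor(cleaned, starts)
  expect_true(all(abs(after) < 0.1))
})

test_that("blink removal quality is invariant to blink amplitude", {
  sim2 <- blinky_sim(blink_amp = 300)
  cleaned2 <- remove_blinks(sim2$recording)
  after2 <- blink_window_cor(cleaned2, sim2$truth$blink_starts)
  expect_true(all(abs(after2) < 0.1))
})

test_that("recordings without blinks pass through almost unchanged", {
  cfg <- cohort_config(blink_rate_per_min = 0, artifact_prob = 0)
  profile <- subject_profile("S01", cfg, 7)
  plan <- generate_session("S01", "audio", 7, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 7, cfg)
  out <- remove_blinks(sim$recording)
  rel <- vapply(seq_len(ncol(out$data)), function(j) {
    d <- out$data[, j] - sim$recording$data[, j]
    sqrt(mean(d^2)) / sqrt(mean(sim$recording$data[, j]^2))
  }, numeric(1))
  expect_true(all(rel < 0.01))
  expect_error(remove_blinks(sim$recording, blink_channel = "XX"), "XX")
})

test_that("epoching yields 896-sample stimulus-locked windows, values exact", {
  cfg <- scaled_config()
  profile <- subject_profile("S01", cfg, 9)
  plan <- generate_session("S01", "audio", 9, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 9, cfg)
  one_block <- plan[plan$block_id == "task1", ]
  ep <- epoch_recording(sim$recording, one_block)
  expect_equal(dim(ep$data)[c(1, 3)], c(896L, 21L))
  expect_equal(ep$t0_ms, -500)
  # exact sample preservation
  onset <- one_block$onset_ms[1]
  i0 <- round((onset - 500) / 1000 * fs) + 1L
  expect_identical(ep$data[, "Fz", 1],
                   sim$recording$data[i0:(i0 + 895), "Fz"])
  expect_equal(round(3.5 * 256), 896)
})

test_that("events too close to the recording edge are dropped with a warning", {
  rec <- signal_recording(rnorm(10 * fs), fs = fs)
  ev <- tibble::tibble(block_id = "b", kind = "task", level = 0L,
                       modality = "audio", item_index = 0:1,
                       onset_ms = c(100, 2000), duration_ms = 500,
                       is_target = FALSE)
  expect_warning(ep <- epoch_recording(rec, ev), "Dropping 1")
  expect_equal(dim(ep$data)[3], 1L)
})

test_that("artifact criteria flag threshold, trend, flat and jump epochs", {
  n_s <- 896
  t <- (seq_len(n_s) - 1) / fs
  quiet <- sin(2 * pi * 10 * t) * 5
  spike <- quiet; spike[400] <- 100
  ramp <- seq(-75, 75, length.out = n_s)
  flat <- rep(0, n_s)
  smooth40 <- 40 * sin(2 * pi * 10 * t)
  ep <- epochs_from_signals(list(quiet, spike, ramp, flat, smooth40))
  out <- detect_artifacts(ep)
  flags <- out$info

  expect_false(flags$artifact[1])
  # one sample at 100 uV: amplitude threshold fires
  expect_true(flags$flag_threshold[2])
  # -75..+75 uV ramp over 3.5 s: slope ~42.9 uV/s -> trend only
  expect_true(flags$flag_trend[3])
  expect_false(flags$flag_threshold[3])
  expect_false(flags$flag_jump[3])
  # all-zero epoch: flat-channel guard (slope 0 < 0.3 uV/s, range < 1 uV)
  expect_true(flags$flag_trend[4])
  # smooth 40 uV 10 Hz oscillation: max successive step ~9.8 uV < 30
  expect_false(flags$artifact[5])
})

test_that("all criteria constants must be positive", {
  expect_error(artifact_criteria(amp_uV = -1), "positive")
  expect_s3_class(artifact_criteria(), "artifact_criteria")
})

test_that("loosening any criterion never flags more epochs", {
  es <- simulate_epoch_set(n_epochs = 120, n_inject = 30, seed = 5,
                           channels = c("Fpz", "Fz", "Cz", "Pz", "O1"))
  strict <- detect_artifacts(es$epochs)$info$artifact
  loose <- detect_artifacts(
    es$epochs,
    artifact_criteria(amp_uV = 120, slope_max_uV_s = 60, slope_min_uV_s = 0.1,
                      flat_range_uV = 0.5, jump_uV = 60)
  )$info$artifact
  expect_true(all(which(loose) %in% which(strict)))
})

test_that("QC counts summarise the flags", {
  es <- simulate_epoch_set(n_epochs = 50, n_inject = 10, seed = 2,
                           channels = c("Cz", "Pz"))
  out <- detect_artifacts(es$epochs, exclude_channels = character(0))
  qc <- qc_counts(out)
  expect_equal(qc$n_epochs, 50L)
  expect_equal(qc$n_artifact, sum(out$info$artifact))
  expect_equal(qc$prop_rejected, qc$n_artifact / 50)
})
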