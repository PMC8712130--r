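quiet_cfg <- function(...) {
  cohort_config(blink_rate_per_min = 0, artifact_prob = 0, ...)
}

test_that("closed-eyes posterior spectrum peaks at the profile's alpha frequency", {
  cfg <- quiet_cfg(iaf_mean = 10, iaf_sd = 0)
  profile <- subject_profile("S01", cfg, 4)
  profile$iaf_hz <- 10
  plan <- generate_session("S01", "audio", 4, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 4, cfg)
  ce <- crop_recording(sim$recording, "closed_eyes")
  # periodogram argmax oracle on O1
  sp <- welch_psd(ce$data[, "O1"], ce$fs, window_s = 2, overlap_s = 1)
  f_peak <- sp$freq[which.max(sp$psd)]
  expect_lt(abs(f_peak - 10), 0.5)
})

test_that("theta load gain of 2 quadruples 2-back frontal theta power", {
  cfg <- quiet_cfg(theta_load_gain = 2, theta_gain_sdlog = 0)
  profile <- subject_profile("S01", cfg, 8)
  profile$theta_load_gain <- 2
  # near-noiseless, no block-state jitter: the band power then reflects the
  # load-gain scaling contract alone
  profile$noise_1f_rms <- 1
  profile$noise_white_sd <- 0
  profile$osc_jitter_sdlog <- 0
  plan <- generate_session("S01", "audio", 8, blocks_per_level = 2)
  sim <- simulate_recording(profile, plan, 8, cfg)
  epochs <- epoch_recording(sim$recording, plan)
  scheme <- band_scheme(profile$iaf_hz)
  bp <- compute_band_power(epochs, scheme)
  bp <- dplyr::left_join(bp, epochs$info[, c("epoch", "kind", "level")],
                         by = "epoch")
  theta_f <- bp |>
    dplyr::filter(.data$band == "theta", .data$kind == "task",
                  .data$channel %in% c("F3", "F4", "Fz")) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(power = mean(.data$power))
  ratio <- theta_f$power[theta_f$level == 2] / theta_f$power[theta_f$level == 0]
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("no blink transients are injected at rate zero", {
  cfg <- quiet_cfg()
  profile <- subject_profile("S01", cfg, 2)
  plan <- generate_session("S01", "video", 2, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 2, cfg)
  expect_lt(max(abs(sim$recording$data[, c("Fpz", "Fz")])), 80)
  expect_length(sim$truth$blink_starts, 0)
})

test_that("blink transients appear on the forehead channel when enabled", {
  cfg <- cohort_config(blink_rate_per_min = 12, artifact_prob = 0)
  profile <- subject_profile("S01", cfg, 2)
  plan <- generate_session("S01", "video", 2, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 2, cfg)
  expect_gt(length(sim$truth$blink_starts), 0)
  expect_gt(max(sim$recording$data[, "Fpz"]), 80)
})

test_that("simulated oscillation power matches its analytic value (Parseval)", {
  cfg <- quiet_cfg(noise_1f_rms = 0, noise_white_sd = 0, alpha_closed_amp = 12)
  profile <- subject_profile("S01", cfg, 5)
  profile$noise_1f_rms <- 0
  profile$noise_white_sd <- 0
  profile$alpha_closed_amp <- 12
  plan <- generate_session("S01", "audio", 5, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 5, cfg)
  ce <- crop_recording(sim$recording, "closed_eyes")
  analytic <- 12^2 / 2 * (1 + vwmeeg:::osc_am_depth^2 / 2)  # O1 weight = 1
  expect_lt(abs(stats::var(ce$data[, "O1"]) / analytic - 1), 0.05)
})

test_that("behavioural generator recovers configured condition means", {
  cfg <- quiet_cfg(rt_load_slope_ms = 100, ei_rt_coupling = 0, rt_sdlog = 0.25)
  profile <- subject_profile("S01", cfg, 6)
  profile$rt_load_slope_ms <- 100
  profile$ei_rt_coupling <- 0
  profile$acc_by_condition[] <- 1
  plan <- generate_session("S01", "video", 6, blocks_per_level = 48L)
  resp <- simulate_behavior(profile, plan, 6)
  expect_true(all(resp$correct))
  joined <- dplyr::left_join(resp, plan[, c("block_id", "item_index", "level")],
                             by = c("block_id", "item_index"))
  mrt <- tapply(joined$rt_ms, joined$level, mean)
  expect_gte(length(joined$rt_ms) / 3, 1000)
  expect_lt(abs((mrt[["2"]] - mrt[["0"]]) - 200), 20)
})

test_that("perfect accuracy yields all-correct responses and determinism holds", {
  cfg <- quiet_cfg()
  profile <- subject_profile("S01", cfg, 3)
  profile$acc_by_condition[] <- 1
  plan <- generate_session("S01", "audio", 3, blocks_per_level = 1)
  r1 <- simulate_behavior(profile, plan, 3)
  r2 <- simulate_behavior(profile, plan, 3)
  expect_true(all(r1$correct))
  expect_identical(r1, r2)
  expect_identical(r1$response[r1$correct],
                   ifelse(dplyr::left_join(r1, plan,
                                           by = c("block_id", "item_index"))$is_target,
                          "target", "nontarget")[r1$correct])
})

test_that("recording simulation is deterministic in the seed", {
  cfg <- scaled_config()
  profile <- subject_profile("S01", cfg, 10)
  plan <- generate_session("S01", "audio", 10, blocks_per_level = 1)
  s1 <- simulate_recording(profile, plan, 10, cfg)
  s2 <- simulate_recording(profile, plan, 10, cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("injected artifacts are logged against existing epochs", {
  cfg <- cohort_config(artifact_prob = 0.2, blink_rate_per_min = 0,
                       blocks_per_level = 1L)
  profile <- subject_profile("S01", cfg, 12)
  plan <- generate_session("S01", "audio", 12, blocks_per_level = 1)
  sim <- simulate_recording(profile, plan, 12, cfg)
  log <- sim$truth$injected_artifacts
  expect_gt(nrow(log), 0)
  expect_true(all(log$type %in% c("spike", "ramp", "flat", "step")))
  key_log <- paste(log$block_id, log$item_index)
  key_plan <- paste(plan$block_id, plan$item_index)
  expect_true(all(key_log %in% key_plan))
  expect_false(any(log$channel == "Fpz"))
})

test_that("labelled epoch sets carry the requested injections", {
  es <- simulate_epoch_set(n_epochs = 60, n_inject = 12, seed = 1,
                           channels = c("Fpz", "Cz", "Pz", "O1"))
  expect_s3_class(es$epochs, "eeg_epochs")
  expect_equal(dim(es$epochs$data), c(896, 4, 60))
  expect_equal(nrow(es$injected), 12)
  expect_true(all(es$injected$epoch <= 60))
})

test_that("cohorts are written to disk with a byte-stable manifest", {
  cfg <- scaled_config(n_subjects = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_cohort(cfg, seed = 21, out_dir = d1)
  make_cohort(cfg, seed = 21, out_dir = d2)
  files <- list.files(d1)
  expect_true("manifest.yaml" %in% files)
  expect_equal(sum(grepl("_recording.rds$", files)), 4)  # 2 subjects x 2 modalities
  expect_equal(sum(grepl("_events.tsv$", files)), 4)
  expect_identical(readLines(file.path(d1, "manifest.yaml")),
                   readLines(file.path(d2, "manifest.yaml")))
  rec <- readRDS(file.path(d1, "S01_audio_recording.rds"))
  expect_s3_class(rec, "eeg_recording")
  expect_error(make_cohort(scaled_config(n_subjects = 1), 1, d1), "at least 2")
})
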