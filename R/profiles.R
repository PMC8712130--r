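#' Cohort-level simulation configuration
#'
#' Population parameters of the synthetic child cohort plus pipeline toggles.
#' Defaults emulate the study conditions: 11 subjects, two modalities, six
#' 21-stimulus task blocks (two per n-back level) plus a 21-item baseline block
#' and a 60 s closed-eyes segment per modality, 20 channels at 256 Hz, blink
#' artifacts on the forehead channel, theta power that grows multiplicatively
#' with memory load, parietal gamma that separates the modalities, and
#' reaction times / accuracies that worsen with load (accuracy means follow the
#' reported condition percentages).
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param modalities Modalities simulated per subject.
#' @param blocks_per_level Task blocks per n-back level (2 in the full design).
#' @param channels Montage subset to simulate.
#' @param fs Sampling rate in Hz.
#' @param closed_eyes_s Closed-eyes rest length (s), used for IAF estimation.
#' @param iaf_mean,iaf_sd Population alpha-peak frequency (Hz).
#' @param theta_base_power Baseline theta oscillation power, uV^2.
#' @param theta_load_gain Multiplicative theta power gain per load step; 1 = no
#'   load effect.
#' @param theta_gain_sdlog Between-subject log-SD of the theta load gain.
#' @param gamma_modality_gain Named amplitude factor per load step for parietal
#'   gamma, one entry per modality; values below 1 make gamma fall with load.
#' @param alpha_closed_amp,alpha_task_amp Posterior alpha amplitudes (uV)
#'   during closed eyes and during the session.
#' @param beta_amp,gamma_amp Base beta / parietal gamma amplitudes (uV).
#' @param ei_beta_gain Log-power gain linking the per-block engagement latent
#'   to beta power.
#' @param osc_jitter_sdlog Log-SD of the per-block lognormal power jitter on
#'   each task oscillation (block-to-block state variability; keeps every
#'   condition cell noisy, as in real band power).
#' @param noise_1f_rms RMS (uV) of the 1/f^beta background noise.
#' @param noise_1f_exponent Spectral exponent beta of the background noise.
#' @param noise_white_sd SD (uV) of additive white sensor noise.
#' @param blink_rate_per_min Mean blink rate (Poisson).
#' @param blink_amp_uV Blink peak amplitude at Fpz.
#' @param artifact_prob Per-epoch probability of an injected supra-threshold
#'   artifact (spike / ramp / flat / step), logged as ground truth.
#' @param rt_base_ms,rt_load_slope_ms,rt_modality_shift_ms Reaction-time model:
#'   mean correct RT (ms, from stimulus offset) is
#'   `rt_base + slope * level + shift * [modality == audio]`.
#' @param rt_sdlog Log-SD of the lognormal RT distribution.
#' @param ei_rt_coupling Strength of the negative engagement-RT coupling: block
#'   RT means are multiplied by `exp(-ei_rt_coupling * engagement)`.
#' @param acc_means Named accuracy means per modality_level cell.
#' @param acc_sd Between-subject SD of cell accuracies.
#' @param filter Run the notch + band-pass stage in the pipeline.
#' @param blink_removal Run regression-based blink removal in the pipeline.
#' @return A list of class `vwm_config`.
#' @export
cohort_config <- function(n_subjects = 11L,
                          modalities = c("audio", "video"),
                          blocks_per_level = 2L,
                          channels = eeg_montage(),
                          fs = 256,
                          closed_eyes_s = 60,
                          iaf_mean = 10, iaf_sd = 0.8,
                          theta_base_power = 8,
                          theta_load_gain = 1.25,
                          theta_gain_sdlog = 0.08,
                          gamma_modality_gain = c(audio = 0.9, video = 1.0),
                          alpha_closed_amp = 12,
                          alpha_task_amp = 4,
                          beta_amp = 3,
                          gamma_amp = 2.5,
                          ei_beta_gain = 0.3,
                          osc_jitter_sdlog = 0.15,
                          noise_1f_rms = 8,
                          noise_1f_exponent = 1,
                          noise_white_sd = 2,
                          blink_rate_per_min = 8,
                          blink_amp_uV = 150,
                          artifact_prob = 0.03,
                          rt_base_ms = 515,
                          rt_load_slope_ms = 140,
                          rt_modality_shift_ms = 130,
                          rt_sdlog = 0.25,
                          ei_rt_coupling = 0.12,
                          acc_means = c(audio_0 = 0.970, audio_1 = 0.876,
                                        audio_2 = 0.870, video_0 = 0.909,
                                        video_1 = 0.833, video_2 = 0.740),
                          acc_sd = 0.03,
                          filter = TRUE,
                          blink_removal = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "vwm_config")
}

#' Draw one subject's simulation profile
#'
#' Subject-level parameters are drawn around the population values in the
#' configuration (lognormal for powers and gains, truncated normal for IAF and
#' accuracies).
#'
#' @param subject_id Subject identifier.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `vwm_profile`.
#' @export
subject_profile <- function(subject_id, config = cohort_config(), seed = 1L) {
  cfg <- config
  with_seed(mix_seed(seed, subject_id, "profile"), {
    acc <- pmin(pmax(cfg$acc_means + stats::rnorm(6, 0, cfg$acc_sd), 0.5), 1)
    names(acc) <- names(cfg$acc_means)
    p <- list(
      subject_id = subject_id,
      profile_seed = mix_seed(seed, subject_id, "latents"),
      iaf_hz = min(12, max(8, stats::rnorm(1, cfg$iaf_mean, cfg$iaf_sd))),
      theta_base_power = cfg$theta_base_power * stats::rlnorm(1, 0, 0.2),
      theta_load_gain = cfg$theta_load_gain * stats::rlnorm(1, 0, cfg$theta_gain_sdlog),
      gamma_modality_gain = cfg$gamma_modality_gain,
      alpha_closed_amp = cfg$alpha_closed_amp * stats::rlnorm(1, 0, 0.15),
      alpha_task_amp = cfg$alpha_task_amp,
      beta_amp = cfg$beta_amp * stats::rlnorm(1, 0, 0.1),
      gamma_amp = cfg$gamma_amp * stats::rlnorm(1, 0, 0.1),
      ei_beta_gain = cfg$ei_beta_gain,
      osc_jitter_sdlog = cfg$osc_jitter_sdlog,
      noise_1f_rms = cfg$noise_1f_rms,
      noise_1f_exponent = cfg$noise_1f_exponent,
      noise_white_sd = cfg$noise_white_sd,
      blink_rate_per_min = cfg$blink_rate_per_min,
      blink_amp_uV = cfg$blink_amp_uV,
      artifact_prob = cfg$artifact_prob,
      rt_base_ms = cfg$rt_base_ms + stats::rnorm(1, 0, 30),
      rt_load_slope_ms = cfg$rt_load_slope_ms + stats::rnorm(1, 0, 20),
      rt_modality_shift_ms = cfg$rt_modality_shift_ms,
      rt_sdlog = cfg$rt_sdlog,
      ei_rt_coupling = cfg$ei_rt_coupling,
      acc_by_condition = acc
    )
    structure(p, class = "vwm_profile")
  })
}

# Per-block standard-normal engagement latent, shared between the EEG and the
# behaviour generators so that low-engagement blocks have both lower beta
# power and longer RTs.
block_engagement <- function(profile, plan) {
  ids <- unique(plan$block_id[plan$kind == "task"])
  modality <- attr(plan, "modality")
  e <- vapply(ids, function(b) {
    with_seed(mix_seed(profile$profile_seed, modality, b, "engagement"),
              stats::rnorm(1))
  }, numeric(1))
  tibble(block_id = ids, engagement = unname(e))
}
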