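# Synthetic EEG generation. Signals are built additively in microvolts:
# 1/f^beta background + white sensor noise + amplitude-modulated sinusoidal
# oscillations with fixed scalp topographies + blink transients + logged
# supra-threshold artifact injections.

# Channel topography weights (full montage); subset to simulated channels.
topo_weights <- function() {
  list(
    theta = c(Fpz = 0.5, Fz = 1, F3 = 1, F4 = 0.85, F7 = 0.9, F8 = 0.75,
              Cz = 1, C3 = 0.9, C4 = 0.75, T7 = 0.85, T8 = 0.6, Pz = 0.95,
              P3 = 0.8, P4 = 0.6, P7 = 0.65, P8 = 0.5, Cp5 = 0.7, Cp6 = 0.55,
              O1 = 0.55, O2 = 0.45),
    alpha = c(Fpz = 0.15, Fz = 0.2, F3 = 0.2, F4 = 0.2, F7 = 0.2, F8 = 0.2,
              Cz = 0.35, C3 = 0.3, C4 = 0.3, T7 = 0.3, T8 = 0.3, Pz = 0.9,
              P3 = 0.8, P4 = 0.8, P7 = 0.75, P8 = 0.75, Cp5 = 0.55,
              Cp6 = 0.55, O1 = 1, O2 = 1),
    beta = c(Fpz = 0.5, Fz = 0.8, F3 = 0.8, F4 = 0.8, F7 = 0.75, F8 = 0.75,
             Cz = 0.8, C3 = 0.8, C4 = 0.8, T7 = 0.7, T8 = 0.7, Pz = 0.75,
             P3 = 0.75, P4 = 0.75, P7 = 0.7, P8 = 0.7, Cp5 = 0.7, Cp6 = 0.7,
             O1 = 0.65, O2 = 0.65),
    gamma = c(Fpz = 0.1, Fz = 0.2, F3 = 0.2, F4 = 0.2, F7 = 0.2, F8 = 0.2,
              Cz = 0.3, C3 = 0.25, C4 = 0.25, T7 = 0.25, T8 = 0.25, Pz = 0.9,
              P3 = 1, P4 = 1, P7 = 0.9, P8 = 0.9, Cp5 = 0.5, Cp6 = 0.5,
              O1 = 0.3, O2 = 0.3),
    blink = c(Fpz = 1, Fz = 0.35, F3 = 0.3, F4 = 0.3, F7 = 0.28, F8 = 0.28,
              Cz = 0.15, C3 = 0.12, C4 = 0.12, T7 = 0.08, T8 = 0.08,
              Pz = 0.07, P3 = 0.06, P4 = 0.06, P7 = 0.05, P8 = 0.05,
              Cp5 = 0.07, Cp6 = 0.07, O1 = 0.03, O2 = 0.03)
  )
}

# Gaussian 1/f^beta noise, one unit-variance column per channel. Spectral
# synthesis: each inverse FFT of a positive-frequency complex Gaussian
# spectrum yields two real series (real/imaginary part), so channels are
# generated in quadrature pairs. `fmax` (with `fs`) truncates the spectrum,
# emulating band-limited (already low-passed) background activity.
pink_noise <- function(n, m, beta = 1, fs = NULL, fmax = NULL) {
  nc <- as.integer(ceiling(m / 2))
  nf <- n %/% 2L
  amp <- (seq_len(nf) / n)^(-beta / 2)
  if (!is.null(fmax) && !is.null(fs)) {
    amp[(seq_len(nf) * fs / n) > fmax] <- 0
  }
  S <- (matrix(stats::rnorm(nf * nc), nf, nc) +
          1i * matrix(stats::rnorm(nf * nc), nf, nc)) * amp
  full <- rbind(matrix(0 + 0i, 1L, nc), S,
                matrix(0 + 0i, n - nf - 1L, nc))
  z <- stats::mvfft(full, inverse = TRUE)
  # Var(Re z) = Var(Im z) = sum(amp^2): normalize analytically so the
  # expected variance is exactly 1 and the spectral shape is untouched
  cbind(Re(z), Im(z))[, seq_len(m), drop = FALSE] / sqrt(sum(amp^2))
}

# Amplitude-modulated sinusoid added over sample range `idx` with channel
# weights `w`. AM depth 0.2 raises power by the fixed factor 1 + 0.2^2/2.
osc_am_depth <- 0.2

add_oscillation <- function(X, idx, t, freq, amp, w, phase, am_phase = 0,
                            am_freq = 0.11) {
  s <- amp * sin(2 * pi * freq * t[idx] + phase) *
    (1 + osc_am_depth * sin(2 * pi * am_freq * t[idx] + am_phase))
  X[idx, ] <- X[idx, ] + outer(s, w)
  X
}

blink_template <- function(fs, width_s = 0.4) {
  n <- round(width_s * fs)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

# Epoch window relative to stimulus onset: -500 ms .. offset + 2500 ms.
epoch_window_s <- c(-0.5, 3.0)

#' Simulate one continuous EEG recording for a session
#'
#' Concatenates a closed-eyes rest segment (strong posterior alpha at the
#' subject's alpha-peak frequency), the baseline block, and the task blocks.
#' Within task blocks, theta power over fronto-central channels scales as
#' `theta_load_gain^level`, parietal gamma amplitude as
#' `gamma_modality_gain[modality]^level`, and beta power follows a per-block
#' engagement latent shared with the behaviour generator. Blink transients
#' (largest at Fpz, decaying posteriorly) and a configurable fraction of
#' supra-threshold artifact epochs (spikes, trend ramps, flat channels,
#' step jumps) are injected and logged as ground truth.
#'
#' @param profile A [subject_profile()].
#' @param plan A session plan from [generate_session()].
#' @param seed Integer seed.
#' @param config A [cohort_config()]; supplies channels and sampling rate.
#' @return A list: `recording` (an `eeg_recording`) and `truth` (ground-truth
#'   log with injected artifacts, per-block engagement and oscillation
#'   amplitudes, and the true IAF).
#' @export
simulate_recording <- function(profile, plan, seed, config = cohort_config()) {
  fs <- config$fs
  channels <- config$channels
  m <- length(channels)
  modality <- attr(plan, "modality")
  closed_eyes_s <- attr(plan, "closed_eyes_s") %||% config$closed_eyes_s

  dur_s <- max(plan$onset_ms + plan$duration_ms) / 1000 + 4
  n <- ceiling(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  w <- lapply(topo_weights(), function(v) unname(v[channels]))

  sim_seed <- mix_seed(seed, profile$subject_id, modality, "eeg")
  eng <- block_engagement(profile, plan)

  X <- with_seed(sim_seed, {
    X <- if (profile$noise_1f_rms > 0) {
      pink_noise(n, m, profile$noise_1f_exponent) * profile$noise_1f_rms
    } else {
      matrix(0, n, m)
    }
    if (profile$noise_white_sd > 0) {
      X <- X + matrix(stats::rnorm(n * m, 0, profile$noise_white_sd), n, m)
    }

    # closed-eyes posterior alpha
    idx_ce <- seq_len(min(n, round(closed_eyes_s * fs)))
    X <- add_oscillation(X, idx_ce, t, profile$iaf_hz,
                         profile$alpha_closed_amp, w$alpha,
                         phase = stats::runif(1, 0, 2 * pi),
                         am_phase = stats::runif(1, 0, 2 * pi))

    theta_f <- profile$iaf_hz - 4
    beta_f <- profile$iaf_hz + 8
    gamma_f <- profile$iaf_hz + 20
    g_mod <- profile$gamma_modality_gain[[modality]]

    for (b in unique(plan$block_id)) {
      items <- plan[plan$block_id == b, ]
      lev <- if (items$kind[1] == "baseline") 0L else items$level[1]
      i0 <- max(1L, floor((min(items$onset_ms) / 1000 + epoch_window_s[1] - 0.1) * fs))
      i1 <- min(n, ceiling((max(items$onset_ms) / 1000 + epoch_window_s[2] + 0.1) * fs))
      idx <- seq.int(i0, i1)
      e_b <- if (items$kind[1] == "baseline") 0 else
        eng$engagement[eng$block_id == b]

      # block-to-block state variability: independent lognormal power jitter
      # per oscillation, so no condition cell is noise-free
      jit <- exp(stats::rnorm(3, 0, profile$osc_jitter_sdlog) / 2)
      theta_amp <- sqrt(2 * profile$theta_base_power *
                          profile$theta_load_gain^lev) * jit[1]
      beta_amp <- profile$beta_amp * exp(profile$ei_beta_gain * e_b / 2) * jit[2]
      gamma_amp <- profile$gamma_amp * g_mod^lev * jit[3]
      ph <- stats::runif(8, 0, 2 * pi)
      tb <- t[idx]
      am <- function(phase) 1 + osc_am_depth * sin(2 * pi * 0.11 * tb + phase)
      S <- cbind(
        theta_amp * sin(2 * pi * theta_f * tb + ph[1]) * am(ph[2]),
        beta_amp * sin(2 * pi * beta_f * tb + ph[3]) * am(ph[4]),
        gamma_amp * sin(2 * pi * gamma_f * tb + ph[5]) * am(ph[6]),
        profile$alpha_task_amp * sin(2 * pi * profile$iaf_hz * tb + ph[7]) *
          am(ph[8])                              # mild session alpha
      )
      X[idx, ] <- X[idx, ] + S %*% rbind(w$theta, w$beta, w$gamma, w$alpha)
    }

    # blinks over the whole recording
    blink_starts <- integer(0)
    if (profile$blink_rate_per_min > 0) {
      n_blinks <- stats::rpois(1, profile$blink_rate_per_min * dur_s / 60)
      if (n_blinks > 0) {
        tpl <- blink_template(fs)
        blink_starts <- sort(sample.int(n - length(tpl), n_blinks))
        for (s0 in blink_starts) {
          a <- profile$blink_amp_uV * stats::runif(1, 0.8, 1.2)
          ii <- s0 + seq_along(tpl) - 1L
          X[ii, ] <- X[ii, ] + outer(a * tpl, w$blink)
        }
      }
    }
    list(X = X, blink_starts = blink_starts)
  })
  blink_starts <- X$blink_starts
  X <- X$X

  # artifact injection, logged
  truth_art <- tibble(block_id = character(), item_index = integer(),
                      channel = character(), type = character())
  stim <- plan
  if (profile$artifact_prob > 0) {
    inj <- with_seed(mix_seed(sim_seed, "artifacts"), {
      pick <- which(stats::runif(nrow(stim)) < profile$artifact_prob)
      if (length(pick) == 0L) NULL else {
        types <- rep(c("spike", "ramp", "flat", "step"), length.out = length(pick))
        chans <- sample(setdiff(channels, "Fpz"), length(pick), replace = TRUE)
        list(pick = pick, types = types, chans = chans,
             u = stats::runif(length(pick)), u2 = stats::runif(length(pick)),
             sgn = sample(c(-1, 1), length(pick), replace = TRUE))
      }
    })
    if (!is.null(inj)) {
      for (k in seq_along(inj$pick)) {
        row <- stim[inj$pick[k], ]
        i0 <- round((row$onset_ms / 1000 + epoch_window_s[1]) * fs) + 1L
        win_n <- round(diff(epoch_window_s) * fs)
        ci <- match(inj$chans[k], channels)
        type <- inj$types[k]
        if (type == "spike") {
          # 100-130 uV half-sine, ~20 ms, placed away from epoch overlap
          c0 <- i0 + round((0.55 + 2.3 * inj$u[k]) * fs)
          pulse <- inj$sgn[k] * (100 + 30 * inj$u2[k]) *
            sin(pi * seq_len(5) / 6)
          X[c0 + seq_along(pulse) - 1L, ci] <- X[c0 + seq_along(pulse) - 1L, ci] + pulse
        } else if (type == "ramp") {
          slope <- inj$sgn[k] * (42 + 3 * inj$u[k])       # uV/s, centred
          tt <- (seq_len(win_n) - win_n / 2) / fs
          X[i0 + seq_len(win_n) - 1L, ci] <- X[i0 + seq_len(win_n) - 1L, ci] + slope * tt
        } else if (type == "flat") {
          X[i0 + seq_len(win_n) - 1L, ci] <- stats::rnorm(win_n, 0, 0.08)
        } else {
          c0 <- i0 + round((0.55 + 2.0 * inj$u[k]) * fs)
          box <- round(0.4 * fs)
          X[c0 + seq_len(box) - 1L, ci] <- X[c0 + seq_len(box) - 1L, ci] +
            inj$sgn[k] * (50 + 20 * inj$u2[k])
        }
        truth_art <- bind_rows(truth_art,
                               tibble(block_id = row$block_id,
                                      item_index = row$item_index,
                                      channel = inj$chans[k], type = type))
      }
    }
  }

  colnames(X) <- channels
  block_ann <- stim |>
    group_by(.data$block_id) |>
    summarise(onset_s = min(.data$onset_ms) / 1000 + epoch_window_s[1],
              duration_s = (max(.data$onset_ms) - min(.data$onset_ms)) / 1000 +
                diff(epoch_window_s), .groups = "drop") |>
    dplyr::rename(label = "block_id")
  ann <- bind_rows(
    tibble(label = "closed_eyes", onset_s = 0, duration_s = closed_eyes_s),
    block_ann
  ) |> arrange(.data$onset_s)

  rec <- new_recording(X, fs, ann, profile$subject_id, modality)
  truth <- list(
    injected_artifacts = truth_art,
    engagement = eng,
    iaf_hz = profile$iaf_hz,
    blink_starts = blink_starts,
    theta_power_by_level = profile$theta_base_power *
      profile$theta_load_gain^(0:2)
  )
  list(recording = rec, truth = truth)
}

#' Simulate trial-by-trial behaviour for a session
#'
#' Correctness is Bernoulli with the profile's per-condition accuracy; correct
#' and incorrect responses both carry a lognormal reaction time (measured from
#' stimulus offset) whose mean grows with memory load, is longer in the
#' auditory modality, and is multiplied by `exp(-ei_rt_coupling * engagement)`
#' using the same per-block engagement latent as the EEG generator.
#'
#' @inheritParams simulate_recording
#' @return Tibble of trial responses: `block_id`, `item_index`, `response`,
#'   `correct`, `rt_ms`.
#' @export
simulate_behavior <- function(profile, plan, seed) {
  modality <- attr(plan, "modality")
  items <- plan[plan$kind == "task", ]
  eng <- block_engagement(profile, plan)
  items <- left_join(items, eng, by = "block_id")
  cell <- paste(modality, items$level, sep = "_")
  p_correct <- unname(profile$acc_by_condition[cell])
  mu <- (profile$rt_base_ms + profile$rt_load_slope_ms * items$level +
           profile$rt_modality_shift_ms * (modality == "audio")) *
    exp(-profile$ei_rt_coupling * items$engagement)

  with_seed(mix_seed(seed, profile$subject_id, modality, "behavior"), {
    correct <- stats::runif(nrow(items)) < p_correct
    rt <- stats::rlnorm(nrow(items),
                        meanlog = log(mu) - profile$rt_sdlog^2 / 2,
                        sdlog = profile$rt_sdlog)
    rt <- pmax(150, pmin(rt, stimulus_timing(modality, "task")$isi_ms))
    tibble(
      block_id = items$block_id,
      item_index = items$item_index,
      response = ifelse(correct == items$is_target, "target", "nontarget"),
      correct = correct,
      rt_ms = rt
    )
  })
}

#' Simulate a labelled epoch set for artifact-detector validation
#'
#' Generates independent 3.5 s epochs of band-limited background EEG
#' (1/f noise truncated at the 45 Hz band-pass edge, as preprocessing leaves
#' it, plus white sensor noise and a mild alpha oscillation) and injects
#' supra-threshold artifacts — amplitude
#' spikes, linear trend ramps, flat channels, and step jumps — into a known
#' subset, returning the ground-truth labels.
#'
#' @param n_epochs Total number of epochs.
#' @param n_inject Number of epochs receiving one artifact each.
#' @param seed Integer seed.
#' @param fs Sampling rate.
#' @param channels Channel labels.
#' @param noise_1f_rms,noise_white_sd Background noise levels (uV).
#' @return A list: `epochs` (an `eeg_epochs`), `injected` (tibble of epoch
#'   index, channel, type).
#' @export
simulate_epoch_set <- function(n_epochs = 500L, n_inject = 100L, seed = 1L,
                               fs = 256, channels = eeg_montage(),
                               noise_1f_rms = 8, noise_white_sd = 2) {
  n_s <- round(diff(epoch_window_s) * fs)
  m <- length(channels)
  with_seed(mix_seed(seed, "epoch_set"), {
    # background emulates preprocessed (1-45 Hz band-passed) epochs
    M <- pink_noise(n_s, m * n_epochs, 1, fs = fs, fmax = 45) * noise_1f_rms +
      matrix(stats::rnorm(n_s * m * n_epochs, 0, noise_white_sd), n_s)
    tt <- (seq_len(n_s) - 1) / fs
    alpha <- 4 * sin(2 * pi * 10 * tt)
    M <- M + alpha                      # same mild oscillation on every column

    pick <- sort(sample.int(n_epochs, n_inject))
    types <- rep(c("spike", "ramp", "flat", "step"), length.out = n_inject)
    chan_pool <- setdiff(channels, "Fpz")
    chans <- sample(chan_pool, n_inject, replace = TRUE)
    for (k in seq_len(n_inject)) {
      col <- (pick[k] - 1L) * m + match(chans[k], channels)
      if (types[k] == "spike") {
        c0 <- sample.int(n_s - 10L, 1)
        M[c0 + 0:4, col] <- M[c0 + 0:4, col] + sample(c(-1, 1), 1) *
          stats::runif(1, 100, 130) * sin(pi * (1:5) / 6)
      } else if (types[k] == "ramp") {
        slope <- sample(c(-1, 1), 1) * stats::runif(1, 42, 45)
        M[, col] <- M[, col] + slope * (tt - mean(tt))
      } else if (types[k] == "flat") {
        M[, col] <- stats::rnorm(n_s, 0, 0.08)
      } else {
        c0 <- sample.int(n_s - round(0.4 * fs) - 1L, 1)
        ii <- c0 + seq_len(round(0.4 * fs))
        M[ii, col] <- M[ii, col] + sample(c(-1, 1), 1) * stats::runif(1, 50, 70)
      }
    }
    A <- array(M, dim = c(n_s, m, n_epochs),
               dimnames = list(NULL, channels, NULL))
    info <- tibble(epoch = seq_len(n_epochs))
    list(
      epochs = new_epochs(A, fs, t0_ms = epoch_window_s[1] * 1000, info = info),
      injected = tibble(epoch = pick, channel = chans, type = types)
    )
  })
}

#' Write a synthetic cohort to disk
#'
#' Simulates `config$n_subjects` subjects (both modalities each) and writes,
#' per subject-modality, the recording (`.rds`), the event table (`.tsv`,
#' plan joined with simulated responses), and one cohort-level YAML manifest
#' holding seeds, subject profiles, and the ground-truth artifact log.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
make_cohort <- function(config = cohort_config(), seed = 1L, out_dir) {
  if (config$n_subjects < 2L) abort("A cohort needs at least 2 subjects.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) abort(sprintf("Cannot write to '%s'.", out_dir))

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  manifest <- list(seed = as.integer(seed), n_subjects = config$n_subjects,
                   subjects = list())
  for (sid in subjects) {
    profile <- subject_profile(sid, config, seed)
    entry <- list(profile = lapply(unclass(profile), function(x)
      if (is.numeric(x)) unname(round(x, 6)) else x))
    for (modality in config$modalities) {
      plan <- generate_session(sid, modality, seed,
                               blocks_per_level = config$blocks_per_level,
                               closed_eyes_s = config$closed_eyes_s)
      sim <- simulate_recording(profile, plan, seed, config)
      resp <- simulate_behavior(profile, plan, seed)
      base <- file.path(out_dir, paste0(sid, "_", modality))
      saveRDS(sim$recording, paste0(base, "_recording.rds"))
      write_events_tsv(plan, paste0(base, "_events.tsv"), responses = resp)
      entry[[paste0("artifacts_", modality)]] <-
        lapply(as.list(sim$truth$injected_artifacts), as.vector)
    }
    manifest$subjects[[sid]] <- entry
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
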