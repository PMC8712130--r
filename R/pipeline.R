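# End-to-end orchestration: simulate -> preprocess -> spectral -> behavioural
# scoring -> statistics, reproducible from (config, seed). Per-session work
# (simulation, filtering, blink removal, epoching, IAF) is done recording by
# recording to bound memory; band powers and all table statistics are
# assembled cohort-wide.

#' Reduced configuration for replicate simulation studies
#'
#' The full configuration with the problem size reduced for Monte Carlo
#' replication: one task block per level, an 8-channel montage subset covering
#' the frontal and midline clusters plus posterior IAF channels, a 40 s
#' closed-eyes segment, no blink or artifact injection, no white sensor
#' noise, and the filter stage off
#' (the simulated signals are band-limited by construction). Study conditions
#' — 256 Hz, 21-stimulus blocks, the ISIs, 11 subjects, the 2x3 design and
#' the default effect sizes — are unchanged.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @return A `vwm_config`.
#' @export
scaled_config <- function(...) {
  cohort_config(
    blocks_per_level = 1L,
    channels = c("Fz", "F3", "F4", "F7", "F8", "Cz", "Pz", "O1"),
    closed_eyes_s = 40,
    blink_rate_per_min = 0,
    artifact_prob = 0,
    noise_white_sd = 0,
    filter = FALSE,
    blink_removal = FALSE,
    ...
  )
}

# Simulate and preprocess one subject-modality session. Returns the epoched
# data with artifact flags, the subject's band scheme, raw per-epoch band
# powers (matrix bands x (channel*epoch)), behaviour scores, and QC counts.
prepare_session <- function(profile, modality, config, seed) {
  sid <- profile$subject_id
  plan <- generate_session(sid, modality, seed,
                           blocks_per_level = config$blocks_per_level,
                           closed_eyes_s = config$closed_eyes_s)
  sim <- simulate_recording(profile, plan, seed, config)
  rec <- sim$recording
  resp <- simulate_behavior(profile, plan, seed)

  if (config$filter) rec <- filter_recording(rec)
  if (config$blink_removal) rec <- remove_blinks(rec)

  iaf_ch <- intersect(c("O1", "O2", "Pz"), rec$channels)
  iaf <- min(13, max(7, estimate_iaf(crop_recording(rec, "closed_eyes"),
                                     channels = iaf_ch)))
  scheme <- band_scheme(iaf)

  epochs <- epoch_recording(rec, plan)
  epochs <- detect_artifacts(epochs)

  # Welch PSD for every epoch/channel at once, integrated over the subject's
  # IAF-relative bands
  d <- dim(epochs$data)
  sp <- welch_psd(matrix(epochs$data, nrow = d[1]), epochs$fs)
  bp <- integrate_bands(sp$freq, sp$psd, scheme$bands)

  info <- epochs$info
  behavior <- score_session(resp, plan)
  list(
    subject = sid, modality = modality, iaf = iaf,
    channels = epochs$channels, band_power = bp, info = info,
    behavior = behavior,
    qc = mutate(qc_counts(epochs), subject = sid, modality = modality,
                iaf_hz = iaf)
  )
}

# Long band-power table for one prepared session, with epoch metadata.
session_power_table <- function(s) {
  n_band <- nrow(s$band_power)
  m <- length(s$channels)
  n_e <- nrow(s$info)
  tibble(
    subject = s$subject,
    modality = s$modality,
    epoch = rep(s$info$epoch, each = n_band * m),
    kind = rep(s$info$kind, each = n_band * m),
    level = rep(s$info$level, each = n_band * m),
    artifact = rep(s$info$artifact, each = n_band * m),
    channel = rep(rep(s$channels, each = n_band), times = n_e),
    band = rep(rownames(s$band_power), times = m * n_e),
    power = as.vector(s$band_power)
  )
}

# The cluster/band combinations entered into the reported ANOVAs.
canonical_anova_rows <- function() {
  tibble(
    cluster = c("frontal", "midline", "left_hemisphere", "parietal"),
    band = c("theta", "theta", "theta", "gamma")
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates a cohort (EEG and behaviour), preprocesses every recording,
#' computes IAF-relative baseline-normalized cluster band powers and the
#' engagement index, scores behaviour (ACC, mean correct RT, IES), and runs
#' the 2x3 load-by-modality repeated-measures ANOVAs (with Shapiro-Wilk
#' gating), Duncan post hoc tests on the load factor, and the cell-level
#' EI-RT Pearson correlation. Identical (config, seed) give identical reports.
#'
#' @param config A [cohort_config()] or [scaled_config()].
#' @param seed Integer master seed; every stage derives its randomness from it.
#' @param posthoc Run Duncan post hoc tests (skipped in replicate studies).
#' @return An object of class `vwm_report`: a list of tibbles — `behavior`,
#'   `anova_behavior`, `anova_eeg`, `posthoc`, `correlation`, `cluster_power`,
#'   `ei`, `qc` — plus `provenance`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, posthoc = TRUE) {
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  sessions <- list()
  for (sid in subjects) {
    profile <- subject_profile(sid, config, seed)
    for (modality in config$modalities) {
      sessions[[paste(sid, modality)]] <- tryCatch(
        prepare_session(profile, modality, config, seed),
        error = function(e) {
          abort(sprintf("Pipeline failed for %s/%s: %s", sid, modality,
                        conditionMessage(e)))
        }
      )
    }
  }

  power <- purrr::map_dfr(sessions, session_power_table)
  clean <- filter(power, !.data$artifact)
  task <- filter(clean, .data$kind == "task")
  baseline <- filter(clean, .data$kind == "baseline")
  chk <- baseline |>
    dplyr::count(.data$subject, .data$modality)
  if (nrow(chk) < length(sessions)) {
    abort("Some session lost all clean baseline epochs during rejection.")
  }

  # per-channel, per-band ratio normalization against the session's baseline
  base_mean <- baseline |>
    group_by(.data$subject, .data$modality, .data$channel, .data$band) |>
    summarise(base_power = mean(.data$power), .groups = "drop")
  norm <- task |>
    left_join(base_mean, by = c("subject", "modality", "channel", "band")) |>
    mutate(power = .data$power / .data$base_power)

  defs <- cluster_defs()
  avail <- sessions[[1]]$channels
  clusters <- defs[names(defs) != "ei_set"]
  clusters <- Filter(function(ch) all(resolve_channels(ch) %in% avail), clusters)
  cluster_power <- purrr::map_dfr(names(clusters), function(cl) {
    norm |>
      filter(.data$channel %in% resolve_channels(clusters[[cl]])) |>
      group_by(.data$subject, .data$modality, .data$level, .data$band) |>
      summarise(power = mean(.data$power), .groups = "drop") |>
      mutate(cluster = cl)
  }) |>
    select("subject", "modality", "level", "cluster", "band", "power")

  # EI per epoch from raw band powers over the available ei_set channels
  ei_set <- intersect(defs$ei_set, avail)
  ei <- task |>
    filter(.data$channel %in% ei_set,
           .data$band %in% c("beta", "alpha", "theta")) |>
    group_by(.data$subject, .data$modality, .data$level, .data$epoch,
             .data$band) |>
    summarise(power = mean(.data$power), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "band", values_from = "power") |>
    mutate(ei = engagement_index(.data$beta, .data$alpha, .data$theta)) |>
    group_by(.data$subject, .data$modality, .data$level) |>
    summarise(ei = mean(.data$ei), .groups = "drop")

  behavior <- purrr::map_dfr(sessions, "behavior") |>
    dplyr::rename(subject = "subject_id")
  qc <- purrr::map_dfr(sessions, "qc")

  # behavioural ANOVAs
  beh_measures <- c(rt = "mean_rt_correct_ms", acc = "acc", ies = "ies_ms")
  fits <- list()
  anova_behavior <- purrr::map_dfr(names(beh_measures), function(m) {
    tab <- behavior |>
      select("subject", "modality", "level", value = all_of(beh_measures[[m]]))
    fit <- factorial_anova(tab)
    fits[[m]] <<- fit
    mutate(tidy(fit), measure = m, anova_method = fit$method)
  })

  # neurophysiological ANOVAs on the canonical cluster/band rows + EI
  rows <- canonical_anova_rows() |>
    dplyr::semi_join(dplyr::distinct(cluster_power, .data$cluster, .data$band),
                     by = c("cluster", "band"))
  anova_eeg <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    tab <- cluster_power |>
      filter(.data$cluster == rows$cluster[i], .data$band == rows$band[i]) |>
      select("subject", "modality", "level", value = "power")
    fit <- factorial_anova(tab)
    fits[[paste(rows$cluster[i], rows$band[i])]] <<- fit
    mutate(tidy(fit), cluster = rows$cluster[i], band = rows$band[i],
           anova_method = fit$method)
  })
  ei_fit <- factorial_anova(select(ei, "subject", "modality", "level",
                                   value = "ei"))
  fits[["ei"]] <- ei_fit
  anova_eeg <- bind_rows(
    anova_eeg,
    mutate(tidy(ei_fit), cluster = "ei_set", band = "beta/(alpha+theta)",
           anova_method = ei_fit$method)
  )

  posthoc_tbl <- if (posthoc) {
    purrr::map_dfr(names(fits), function(nm) {
      mutate(tidy(duncan_posthoc(fits[[nm]], "level")), measure = nm)
    })
  } else {
    tibble()
  }

  # cell-level EI-RT correlation (11 subjects x 6 cells -> n = 66, df = 64)
  cells <- left_join(ei,
                     behavior[, c("subject", "modality", "level",
                                  "mean_rt_correct_ms")],
                     by = c("subject", "modality", "level"))
  correlation <- correlate(cells$ei, cells$mean_rt_correct_ms)

  provenance <- tibble(
    seed = as.integer(seed),
    config_hash = rlang::hash(unclass(config)),
    n_subjects = config$n_subjects,
    blocks_per_level = config$blocks_per_level,
    n_channels = length(config$channels),
    package_version = as.character(utils::packageVersion("vwmeeg"))
  )

  structure(
    list(behavior = behavior, anova_behavior = anova_behavior,
         anova_eeg = anova_eeg, posthoc = posthoc_tbl,
         correlation = correlation, cluster_power = cluster_power, ei = ei,
         qc = qc, provenance = provenance),
    class = "vwm_report"
  )
}

#' @export
print.vwm_report <- function(x, ...) {
  cat("<vwm_report> dual-modality n-back pipeline run\n")
  cat(sprintf("  subjects: %d, seed: %d\n", x$provenance$n_subjects,
              x$provenance$seed))
  cat("\nBehavioural ANOVA (effect rows):\n")
  print(as.data.frame(x$anova_behavior[, c("measure", "effect", "F", "p",
                                           "partial_eta_sq")]), row.names = FALSE)
  cat("\nNeurophysiological ANOVA:\n")
  print(as.data.frame(x$anova_eeg[, c("cluster", "band", "effect", "F", "p",
                                      "partial_eta_sq")]), row.names = FALSE)
  cat("\nEI-RT correlation:\n")
  print(as.data.frame(x$correlation), row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `behavior.tsv`, `anova_behavior.tsv`, `anova_eeg.tsv`, `posthoc.tsv`,
#' `correlation.tsv`, `cluster_power.tsv`, `ei.tsv`, `qc.tsv` and
#' `provenance.yaml`.
#'
#' @param report A `vwm_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- c("behavior", "anova_behavior", "anova_eeg", "posthoc",
           "correlation", "cluster_power", "ei", "qc")
  for (nm in tsv) {
    readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  yaml::write_yaml(as.list(report$provenance), file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Replicate-cohort simulation study
#'
#' Runs the pipeline on `n_reps` independently seeded cohorts and collects,
#' per replicate, the load-effect p values for frontal and midline theta and
#' the engagement index, and the cell-level EI-RT Pearson r. Used for power
#' and type-I calibration of the scaled design.
#'
#' @param n_reps Number of replicate cohorts.
#' @param config A `vwm_config` (typically [scaled_config()]).
#' @param seed Master seed; replicate r uses a seed derived from (seed, r).
#' @return Tibble with one row per replicate.
#' @export
replicate_cohorts <- function(n_reps, config = scaled_config(), seed = 1L) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    rep_seed <- mix_seed(seed, "replicate", r)
    report <- run_pipeline(config, rep_seed, posthoc = FALSE)
    load_p <- function(cl) {
      v <- report$anova_eeg |>
        filter(.data$cluster == cl, .data$effect == "level")
      if (nrow(v) == 0) NA_real_ else v$p[1]
    }
    tibble(
      rep = r,
      seed = rep_seed,
      theta_frontal_load_p = load_p("frontal"),
      theta_midline_load_p = load_p("midline"),
      ei_load_p = load_p("ei_set"),
      ei_rt_r = report$correlation$r
    )
  })
}
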