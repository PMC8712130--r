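# Independent oracles used across the suite.

# Naive per-definition n-back labeller: one explicit comparison per position.
oracle_label_targets <- function(letters, level, probe = "X") {
  n <- length(letters)
  flags <- logical(n)
  for (i in seq_len(n)) {
    flags[i] <- if (level == 0) {
      letters[i] == probe
    } else if (i > level) {
      letters[i] == letters[i - level]
    } else {
      FALSE
    }
  }
  flags
}

# Brute-force balanced within-subject 2x3 decomposition from marginal means.
# Independent of aov(): sums of squares written out term by term.
oracle_rm_anova <- function(table) {
  s <- sort(unique(table$subject))
  mods <- sort(unique(table$modality))
  levs <- sort(unique(table$level))
  y <- array(NA_real_, c(length(s), length(mods), length(levs)))
  for (r in seq_len(nrow(table))) {
    y[match(table$subject[r], s), match(table$modality[r], mods),
      match(table$level[r], levs)] <- table$value[r]
  }
  gm <- mean(y)
  m_i <- apply(y, 1, mean); m_j <- apply(y, 2, mean); m_k <- apply(y, 3, mean)
  m_ij <- apply(y, c(1, 2), mean); m_ik <- apply(y, c(1, 3), mean)
  m_jk <- apply(y, c(2, 3), mean)
  ns <- length(s); nj <- length(mods); nk <- length(levs)

  ss_mod <- nk * ns * sum((m_j - gm)^2)
  ss_lev <- nj * ns * sum((m_k - gm)^2)
  ss_int <- ns * sum((m_jk - outer(m_j, rep(1, nk)) -
                        outer(rep(1, nj), m_k) + gm)^2)
  ss_err_mod <- nk * sum((m_ij - outer(m_i, rep(1, nj)) -
                            outer(rep(1, ns), m_j) + gm)^2)
  ss_err_lev <- nj * sum((m_ik - outer(m_i, rep(1, nk)) -
                            outer(rep(1, ns), m_k) + gm)^2)
  ss_total <- sum((y - gm)^2)
  ss_subj <- nj * nk * sum((m_i - gm)^2)
  ss_err_int <- ss_total - ss_subj - ss_mod - ss_lev - ss_int -
    ss_err_mod - ss_err_lev

  mk <- function(effect, ss_eff, df_eff, ss_err, df_err) {
    F <- if (ss_eff == 0) 0 else (ss_eff / df_eff) / (ss_err / df_err)
    tibble::tibble(
      effect = effect, df_effect = df_eff, df_error = df_err,
      ss_effect = ss_eff, ss_error = ss_err, ms_error = ss_err / df_err,
      F = F,
      p = if (ss_eff == 0) 1 else stats::pf(F, df_eff, df_err, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
    )
  }
  dplyr::bind_rows(
    mk("modality", ss_mod, nj - 1, ss_err_mod, (ns - 1) * (nj - 1)),
    mk("level", ss_lev, nk - 1, ss_err_lev, (ns - 1) * (nk - 1)),
    mk("modality:level", ss_int, (nj - 1) * (nk - 1), ss_err_int,
       (ns - 1) * (nj - 1) * (nk - 1))
  )
}

# Random balanced 2x3 cell table.
random_cell_table <- function(n_subjects, seed, effect_level = 0,
                              effect_mod = 0) {
  withr::with_seed(seed, {
    g <- tidyr::expand_grid(
      subject = sprintf("s%d", seq_len(n_subjects)),
      modality = c("audio", "video"),
      level = 0:2
    )
    g$value <- stats::rnorm(nrow(g)) + effect_level * g$level +
      effect_mod * (g$modality == "audio")
    g
  })
}

# Single-channel recording wrapper around a bare signal vector.
signal_recording <- function(x, fs = 256, channels = "O1") {
  m <- matrix(rep(x, length(channels)), ncol = length(channels))
  colnames(m) <- channels
  vwmeeg:::new_recording(
    m, fs,
    tibble::tibble(label = "closed_eyes", onset_s = 0,
                   duration_s = length(x) / fs)
  )
}

# Single-channel epochs object from a list of signal vectors.
epochs_from_signals <- function(signals, fs = 256, channel = "Cz") {
  n_s <- length(signals[[1]])
  A <- array(unlist(signals), dim = c(n_s, 1, length(signals)),
             dimnames = list(NULL, channel, NULL))
  vwmeeg:::new_epochs(A, fs, t0_ms = -500,
                      info = tibble::tibble(epoch = seq_along(signals)))
}
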