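# Preprocessing: zero-phase notch + Butterworth band-pass, regression-based
# blink removal driven by the forehead channel, stimulus-locked epoching, and
# the three-criterion artifact rejection (amplitude / trend / jump).

#' Artifact rejection criteria
#'
#' The three epoch-rejection criteria and their default constants: the
#' amplitude threshold (+-80 uV on any sample), the trend criterion (ordinary
#' least-squares slope over the epoch above 40 uV/s, or — as a flat /
#' disconnected-channel guard — below 0.3 uV/s with a peak-to-peak range under
#' `flat_range_uV`), and the sample-to-sample jump criterion (successive-sample
#' difference above 30 uV).
#'
#' @param amp_uV Amplitude threshold, applied symmetrically.
#' @param slope_max_uV_s Maximum admissible trend slope.
#' @param slope_min_uV_s Minimum slope of the flat-channel guard.
#' @param flat_range_uV Peak-to-peak range below which a low-slope channel is
#'   considered flat/disconnected.
#' @param jump_uV Maximum successive-sample difference.
#' @return A list of class `artifact_criteria`.
#' @export
artifact_criteria <- function(amp_uV = 80, slope_max_uV_s = 40,
                              slope_min_uV_s = 0.3, flat_range_uV = 1,
                              jump_uV = 30) {
  vals <- c(amp_uV, slope_max_uV_s, slope_min_uV_s, flat_range_uV, jump_uV)
  if (any(vals <= 0)) abort("All artifact criteria must be positive.")
  structure(list(amp_uV = amp_uV, slope_max_uV_s = slope_max_uV_s,
                 slope_min_uV_s = slope_min_uV_s, flat_range_uV = flat_range_uV,
                 jump_uV = jump_uV),
            class = "artifact_criteria")
}

#' Notch and band-pass filter a recording
#'
#' Applies a 50 Hz notch (2nd-order Butterworth band-stop, +-2 Hz) followed by
#' a 5th-order Butterworth band-pass, both zero-phase (forward-backward) so
#' that epoch-relative timing is preserved. Channels are demeaned first.
#'
#' @param rec An `eeg_recording`.
#' @param notch_hz Power-line frequency to notch out; `NULL` skips the notch.
#' @param band Band-pass edges in Hz.
#' @param order Butterworth band-pass order.
#' @return The filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, notch_hz = 50, band = c(1, 45), order = 5) {
  fs <- rec$fs
  if (any(band <= 0) || any(band >= fs / 2)) {
    abort(sprintf("Band edges must lie in (0, %g) Hz.", fs / 2))
  }
  if (fs <= 2 * band[2]) abort("Sampling rate must exceed twice the upper band edge.")
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  nt <- if (!is.null(notch_hz)) {
    signal::butter(2, c(notch_hz - 2, notch_hz + 2) / (fs / 2), type = "stop")
  }
  X <- rec$data
  for (j in seq_len(ncol(X))) {
    x <- X[, j] - mean(X[, j])
    if (!is.null(nt)) x <- signal::filtfilt(nt, x)
    X[, j] <- signal::filtfilt(bp, x)
  }
  out <- rec
  out$data <- X
  out
}

# Blink events on the forehead channel: matched filter against the blink
# template thresholded at `k` SDs and gated by a minimum raw amplitude
# (blinks are large transients; the gate keeps background noise from
# triggering spurious events). Contiguous supra-threshold runs collapse to
# one event at the best-scoring alignment. Returns event start indices.
detect_blink_events <- function(x, fs, k = 3, width_s = 0.4,
                                min_peak_uV = 40) {
  tpl <- blink_template(fs, width_s)
  tpl <- (tpl - mean(tpl)) / sqrt(sum((tpl - mean(tpl))^2))
  L <- length(tpl)
  score <- stats::filter(x, rev(tpl), method = "convolution", sides = 1)
  score[is.na(score)] <- 0
  thr <- k * stats::sd(score)
  hits <- which(score > thr)
  if (length(hits) == 0L) return(integer(0))
  runs <- split(hits, cumsum(c(1L, diff(hits) > L / 2)))
  peaks <- vapply(runs, function(r) r[which.max(score[r])], numeric(1))
  starts <- pmax(1L, as.integer(peaks) - L + 1L)
  starts <- starts[starts + L - 1L <= length(x)]
  starts[vapply(starts, function(s0) {
    max(x[s0:(s0 + L - 1L)]) > min_peak_uV
  }, logical(1))]
}

# Union of event windows expanded by a margin (used for sample replacement).
detect_blink_windows <- function(x, fs, k = 3, width_s = 0.4, margin_s = 0.1,
                                 min_peak_uV = 40) {
  starts <- detect_blink_events(x, fs, k, width_s, min_peak_uV)
  if (length(starts) == 0L) return(integer(0))
  L <- round(width_s * fs)
  m <- round(margin_s * fs)
  idx <- unique(unlist(lapply(starts, function(s0) seq(s0 - m, s0 + L - 1L + m))))
  sort(idx[idx >= 1 & idx <= length(x)])
}

#' Remove eye-blink contributions by forehead-channel regression
#'
#' Detects blink events on the blink channel (matched filter at 3 SD with an
#' amplitude gate), estimates each channel's blink coupling by regressing the
#' channels' per-event matched-filter amplitudes on the blink channel's
#' (which suppresses the slow background noise that a raw sample-wise
#' regression would inherit), then subtracts the scaled blink-channel signal
#' within the detected windows only — non-blink segments pass through
#' unchanged. The blink channel itself is retained for quality control but
#' should be excluded from analysis clusters.
#'
#' @param rec An `eeg_recording`.
#' @param blink_channel Channel driving the removal.
#' @return The cleaned `eeg_recording`.
#' @export
remove_blinks <- function(rec, blink_channel = "Fpz") {
  if (!blink_channel %in% rec$channels) {
    abort(sprintf("Blink channel '%s' not present in the recording.", blink_channel))
  }
  fs <- rec$fs
  fp <- rec$data[, blink_channel]
  starts <- detect_blink_events(fp, fs)
  if (length(starts) == 0L) return(rec)

  tpl <- blink_template(fs)
  tplc <- tpl - mean(tpl)
  tpl_ss <- sum(tplc^2)
  L <- length(tpl)
  ev_idx <- lapply(starts, function(s0) s0 + seq_len(L) - 1L)

  # per-event matched-filter amplitudes, blink channel and all others
  amp_of <- function(x) {
    vapply(ev_idx, function(ii) sum(x[ii] * tplc) / tpl_ss, numeric(1))
  }
  a_fp <- amp_of(fp)
  denom <- sum(a_fp^2)
  if (denom <= 0) return(rec)

  m <- round(0.1 * fs)
  win_idx <- lapply(ev_idx, function(ii) {
    jj <- seq(min(ii) - m, max(ii) + m)
    jj[jj >= 1 & jj <= length(fp)]
  })
  X <- rec$data
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == blink_channel) next
    beta <- sum(amp_of(X[, j]) * a_fp) / denom
    for (jj in win_idx) {
      X[jj, j] <- X[jj, j] - beta * (fp[jj] - mean(fp[jj]))
    }
  }
  out <- rec
  out$data <- X
  out
}

#' Segment a recording into stimulus-locked epochs
#'
#' One epoch per event, from 500 ms before stimulus onset to 2500 ms after its
#' offset (3.5 s, 896 samples at 256 Hz). Sample values are copied exactly; no
#' resampling or scaling. Events whose window does not fit inside the
#' recording are dropped with a warning.
#'
#' @param rec An `eeg_recording`.
#' @param events Tibble with `onset_ms`, `duration_ms` and metadata columns
#'   (`block_id`, `kind`, `level`, `modality`, `item_index`, `is_target`).
#' @param pre_ms Window start relative to stimulus onset (negative = before).
#' @param post_offset_ms Window end relative to stimulus offset.
#' @return An `eeg_epochs` object; `info` carries the event metadata.
#' @export
epoch_recording <- function(rec, events, pre_ms = -500, post_offset_ms = 2500) {
  fs <- rec$fs
  n <- nrow(rec$data)
  win_ms <- (events$duration_ms + post_offset_ms) - pre_ms
  n_s <- round(win_ms[1] / 1000 * fs)
  start <- round((events$onset_ms + pre_ms) / 1000 * fs) + 1L
  ok <- start >= 1L & (start + n_s - 1L) <= n
  if (any(!ok)) {
    warn(sprintf("Dropping %d epoch(s) too close to the recording edge.", sum(!ok)))
  }
  events <- events[ok, , drop = FALSE]
  start <- start[ok]
  m <- ncol(rec$data)
  A <- array(NA_real_, dim = c(n_s, m, length(start)),
             dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_along(start)) {
    A[, , e] <- rec$data[start[e] + seq_len(n_s) - 1L, ]
  }
  info <- as_tibble(events)
  info$epoch <- seq_len(nrow(info))
  new_epochs(A, fs, t0_ms = pre_ms, info = info)
}

#' Flag artifactual epochs by the amplitude / trend / jump criteria
#'
#' Each criterion is evaluated per channel over the whole epoch; an epoch is
#' marked artifactual when any analysis channel triggers any criterion
#' (whole-epoch rejection). The blink channel is excluded by default.
#'
#' @param epochs An `eeg_epochs`.
#' @param criteria An [artifact_criteria()].
#' @param exclude_channels Channels ignored by the detector.
#' @return The `eeg_epochs` with logical columns `flag_threshold`,
#'   `flag_trend`, `flag_jump` and `artifact` added to `info`.
#' @export
detect_artifacts <- function(epochs, criteria = artifact_criteria(),
                             exclude_channels = "Fpz") {
  if (dim(epochs$data)[3] == 0L) abort("No epochs to screen.")
  keep <- !(epochs$channels %in% exclude_channels)
  A <- epochs$data[, keep, , drop = FALSE]
  d <- dim(A)
  n_s <- d[1]; m <- d[2]; n_e <- d[3]
  M <- matrix(A, nrow = n_s)                       # samples x (channel*epoch)

  over_amp <- .colSums(M > criteria$amp_uV | M < -criteria$amp_uV,
                       n_s, ncol(M)) > 0L

  tt <- (seq_len(n_s) - 1) / epochs$fs
  tc <- tt - mean(tt)
  slope <- as.vector(crossprod(tc, M)) / sum(tc^2)  # OLS slope, uV/s
  low_slope <- which(abs(slope) < criteria$slope_min_uV_s)
  flat <- logical(ncol(M))
  if (length(low_slope) > 0) {
    flat[low_slope] <- vapply(low_slope, function(j) {
      diff(range(M[, j])) < criteria$flat_range_uV
    }, logical(1))
  }
  over_trend <- abs(slope) > criteria$slope_max_uV_s | flat

  D <- M[-1, , drop = FALSE] - M[-n_s, , drop = FALSE]
  over_jump <- .colSums(D > criteria$jump_uV | D < -criteria$jump_uV,
                        n_s - 1L, ncol(M)) > 0L

  per_epoch <- function(v) apply(matrix(v, nrow = m), 2, any)
  info <- epochs$info
  info$flag_threshold <- per_epoch(over_amp)
  info$flag_trend <- per_epoch(over_trend)
  info$flag_jump <- per_epoch(over_jump)
  info$artifact <- info$flag_threshold | info$flag_trend | info$flag_jump
  out <- epochs
  out$info <- info
  out
}

#' Per-subject artifact QC counts
#'
#' @param epochs An `eeg_epochs` after [detect_artifacts()].
#' @return One-row tibble of epoch counts per flag.
#' @export
qc_counts <- function(epochs) {
  info <- epochs$info
  tibble(
    n_epochs = nrow(info),
    n_threshold = sum(info$flag_threshold),
    n_trend = sum(info$flag_trend),
    n_jump = sum(info$flag_jump),
    n_artifact = sum(info$artifact),
    prop_rejected = mean(info$artifact)
  )
}
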