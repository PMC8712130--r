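# Welch spectra, IAF-anchored band definitions, band power, baseline
# normalization, electrode-cluster averaging, and the engagement index.

#' Welch power spectral density
#'
#' Averaged periodogram with a Hanning window (default 1 s segments, 50%
#' overlap) and per-segment mean detrending. One-sided density in uV^2/Hz.
#'
#' @param x Numeric vector or samples-by-series matrix.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds.
#' @param overlap_s Segment overlap in seconds.
#' @return A list: `freq` (Hz) and `psd` (frequency-by-series matrix).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap_s = 0.5) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  nwin <- round(window_s * fs)
  if (n < nwin) abort("Signal shorter than one Welch window.")
  step <- nwin - round(overlap_s * fs)
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- signal::hanning(nwin)
  scale <- 2 / (fs * sum(w^2))
  nf <- nwin %/% 2 + 1L

  acc <- matrix(0, nf, ncol(x))
  for (s0 in starts) {
    seg <- x[s0 + seq_len(nwin) - 1L, , drop = FALSE]
    seg <- w * seg - outer(w, colMeans(seg))   # windowed, mean-detrended
    F <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + (Re(F)^2 + Im(F)^2)
  }
  psd <- acc * (scale / length(starts))
  psd[c(1L, nf), ] <- psd[c(1L, nf), ] / 2     # DC and Nyquist are not doubled
  list(freq = (seq_len(nf) - 1L) * fs / nwin, psd = psd)
}

#' Estimate the individual alpha frequency (IAF)
#'
#' Peak frequency of the channel-averaged Welch spectrum of a closed-eyes
#' segment within the search range, refined by parabolic interpolation between
#' neighbouring bins. The peak must be a local maximum and must exceed the
#' 1/f background (log-log linear fit over 4-20 Hz excluding the search range)
#' by the prominence factor; otherwise the canonical 10 Hz is returned with a
#' warning.
#'
#' @param rec An `eeg_recording` of the closed-eyes segment (>= 30 s).
#' @param channels Channels averaged for the estimate (posterior by default).
#' @param search_range Frequency range searched for the alpha peak.
#' @param window_s Welch window (2 s gives 0.5 Hz bins for peak picking).
#' @param prominence Minimum peak / background power ratio.
#' @return IAF in Hz.
#' @export
estimate_iaf <- function(rec, channels = c("O1", "O2", "Pz"),
                         search_range = c(7, 13), window_s = 2,
                         prominence = 1.5) {
  if (nrow(rec$data) / rec$fs < 30) abort("Closed-eyes segment must be at least 30 s.")
  channels <- resolve_channels(channels, rec$channels)
  sp <- welch_psd(rec$data[, channels, drop = FALSE], rec$fs,
                  window_s = window_s, overlap_s = window_s / 2)
  p <- rowMeans(sp$psd)
  f <- sp$freq

  in_rng <- which(f >= search_range[1] & f <= search_range[2])
  i <- in_rng[which.max(p[in_rng])]
  fallback <- function(msg) {
    warn(paste0(msg, "; falling back to 10 Hz."))
    10
  }
  if (i <= 1L || i >= length(p)) return(fallback("No alpha peak in range"))
  if (p[i] < p[i - 1L] || p[i] < p[i + 1L]) {
    return(fallback("No local maximum inside the search range"))
  }

  # 1/f background from a log-log fit outside the search range
  bg_idx <- which(f >= 4 & f <= 20 & (f < search_range[1] | f > search_range[2]))
  fit <- stats::lm.fit(cbind(1, log(f[bg_idx])), log(p[bg_idx]))
  bg_at_peak <- exp(sum(fit$coefficients * c(1, log(f[i]))))
  if (p[i] < prominence * bg_at_peak) {
    return(fallback("Alpha peak not prominent above the 1/f background"))
  }

  y1 <- p[i - 1L]; y2 <- p[i]; y3 <- p[i + 1L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  f[i] + delta * (f[2] - f[1])
}

#' IAF-relative frequency band scheme
#'
#' Bands are anchored to the individual alpha frequency: theta `[IAF-6,
#' IAF-2]`, low alpha `[IAF-2, IAF]`, upper alpha `[IAF, IAF+2]`, alpha
#' `[IAF-2, IAF+2]`, beta `[IAF+2, IAF+16]`, gamma `[IAF+16, IAF+30]`, with
#' the gamma top edge clipped to the 45 Hz band-pass limit.
#'
#' @param iaf_hz IAF in `[7, 13]` Hz.
#' @param clip_hz Upper analysis limit.
#' @return A list of class `band_scheme`: `iaf_hz` and `bands`, a named list
#'   of `c(lo, hi)` intervals in Hz.
#' @examples
#' band_scheme(10)$bands$theta # 4 8
#' @export
band_scheme <- function(iaf_hz, clip_hz = 45) {
  if (!(length(iaf_hz) == 1L && iaf_hz >= 7 && iaf_hz <= 13)) {
    abort("`iaf_hz` must lie in [7, 13] Hz.")
  }
  bands <- list(
    theta = c(iaf_hz - 6, iaf_hz - 2),
    low_alpha = c(iaf_hz - 2, iaf_hz),
    upper_alpha = c(iaf_hz, iaf_hz + 2),
    alpha = c(iaf_hz - 2, iaf_hz + 2),
    beta = c(iaf_hz + 2, iaf_hz + 16),
    gamma = c(iaf_hz + 16, min(iaf_hz + 30, clip_hz))
  )
  structure(list(iaf_hz = iaf_hz, bands = bands), class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme> IAF = %.2f Hz\n", x$iaf_hz))
  for (b in names(x$bands)) {
    cat(sprintf("  %-11s [%5.2f, %5.2f) Hz\n", b, x$bands[[b]][1], x$bands[[b]][2]))
  }
  invisible(x)
}

# Integrate a PSD matrix over [lo, hi) for each band. Bins are assigned
# half-open so adjacent bands tile without double counting.
integrate_bands <- function(freq, psd, bands) {
  df <- freq[2] - freq[1]
  out <- lapply(bands, function(b) {
    sel <- freq >= b[1] & freq < b[2]
    colSums(psd[sel, , drop = FALSE]) * df
  })
  do.call(rbind, out)                   # bands x series
}

#' Band power per epoch and channel
#'
#' Welch PSD per epoch and channel (Hanning window, default 1 s segments with
#' 50% overlap, per-segment mean detrending), integrated over each
#' IAF-relative band. Band edges above the Nyquist frequency are clipped with
#' a warning.
#'
#' @param epochs An `eeg_epochs`.
#' @param scheme A [band_scheme()].
#' @param window_s,overlap_s Welch segmenting (seconds).
#' @return Tibble: `epoch`, `channel`, `band`, `power` (uV^2).
#' @export
compute_band_power <- function(epochs, scheme, window_s = 1, overlap_s = 0.5) {
  d <- dim(epochs$data)
  nyq <- epochs$fs / 2
  bands <- scheme$bands
  for (b in names(bands)) {
    if (bands[[b]][2] > nyq) {
      warn(sprintf("Band '%s' upper edge clipped to the Nyquist frequency.", b))
      bands[[b]][2] <- nyq
    }
  }
  M <- matrix(epochs$data, nrow = d[1])           # samples x (channel*epoch)
  sp <- welch_psd(M, epochs$fs, window_s, overlap_s)
  bp <- integrate_bands(sp$freq, sp$psd, bands)   # bands x (channel*epoch)

  grid <- expand.grid(channel = epochs$channels,
                      epoch = epochs$info$epoch %||% seq_len(d[3]),
                      stringsAsFactors = FALSE)
  out <- tibble(
    epoch = rep(grid$epoch, each = length(bands)),
    channel = rep(grid$channel, each = length(bands)),
    band = rep(names(bands), times = nrow(grid)),
    power = as.vector(bp)
  )
  out
}

#' Baseline-normalize band power
#'
#' Divides task-epoch band power by the per-channel, per-band mean power over
#' the baseline epochs (ratio mode, dimensionless) or expresses it in dB
#' (`10 * log10(ratio)`).
#'
#' @param task_power Band-power tibble for task epochs ([compute_band_power()]).
#' @param baseline_power Band-power tibble for (clean) baseline epochs.
#' @param mode `"ratio"` or `"db"`.
#' @return `task_power` with `power` replaced by the normalized value.
#' @export
baseline_normalize <- function(task_power, baseline_power,
                               mode = c("ratio", "db")) {
  mode <- match.arg(mode)
  base <- baseline_power |>
    group_by(.data$channel, .data$band) |>
    summarise(base_power = mean(.data$power), .groups = "drop")
  bad <- base[base$base_power <= 0, ]
  if (nrow(bad) > 0) {
    abort(sprintf("Non-positive baseline power for %s.",
                  paste(paste(bad$channel, bad$band, sep = "/"), collapse = ", ")))
  }
  out <- left_join(task_power, base, by = c("channel", "band"))
  if (anyNA(out$base_power)) abort("Baseline power missing for some channel/band.")
  out$power <- out$power / out$base_power
  if (mode == "db") out$power <- 10 * log10(out$power)
  out$base_power <- NULL
  out
}

#' Average band power over an electrode cluster
#'
#' Arithmetic mean across the cluster's channels, per epoch and band.
#'
#' @param power Band-power tibble with `epoch`, `channel`, `band`, `power`.
#' @param channels Cluster channel labels (old temporal labels such as T4 are
#'   mapped to the recorded montage when `alias = TRUE`).
#' @param alias Apply the montage alias map.
#' @return Tibble: `epoch`, `band`, `power`.
#' @export
cluster_average <- function(power, channels, alias = TRUE) {
  present <- unique(power$channel)
  ch <- if (alias) resolve_channels(channels, montage = present) else {
    missing <- setdiff(channels, present)
    if (length(missing) > 0) {
      abort(sprintf("Channel(s) not in power table: %s",
                    paste(missing, collapse = ", ")))
    }
    channels
  }
  power |>
    filter(.data$channel %in% ch) |>
    group_by(.data$epoch, .data$band) |>
    summarise(power = mean(.data$power), .groups = "drop")
}

#' Engagement index
#'
#' The brainwave engagement index EI = Beta / (Alpha + Theta), a dimensionless
#' band-power ratio indexing attentive engagement; alpha is the full
#' `[IAF-2, IAF+2]` band.
#'
#' @param beta_power,alpha_power,theta_power Band powers (same units).
#' @return EI.
#' @examples
#' engagement_index(1, 1, 1) # 0.5
#' @export
engagement_index <- function(beta_power, alpha_power, theta_power) {
  denom <- alpha_power + theta_power
  if (any(denom <= 0)) abort("Alpha + theta power must be positive for EI.")
  beta_power / denom
}
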