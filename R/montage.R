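#' The 20-channel recording montage
#'
#' Channel labels of the ambulatory recording setup (10-20 positions,
#' earlobe-referenced, 256 Hz). `Fpz` is the forehead channel used for blink
#' detection/removal and is excluded from analysis clusters.
#'
#' @return Character vector of 20 channel labels.
#' @export
eeg_montage <- function() {
  c("Fpz", "Fz", "F3", "F4", "F7", "F8", "Cz", "C3", "C4", "T7", "T8",
    "Pz", "P3", "P4", "P7", "P8", "Cp5", "Cp6", "O1", "O2")
}

# Old 10-20 temporal labels occasionally used in cluster listings mapped to
# the recorded equivalents.
montage_aliases <- function() {
  c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
}

resolve_channels <- function(channels, montage = eeg_montage(), alias = TRUE) {
  ch <- as.character(channels)
  if (alias) {
    al <- montage_aliases()
    hit <- ch %in% names(al)
    ch[hit] <- al[ch[hit]]
  }
  missing <- setdiff(ch, montage)
  if (length(missing) > 0) {
    abort(sprintf("Channel(s) not in montage: %s", paste(missing, collapse = ", ")))
  }
  ch
}

#' Electrode cluster definitions
#'
#' Named channel sets whose band powers are averaged before statistics:
#' frontal, parietal, occipital, midline, left/right hemisphere, and the
#' 19-channel set (all channels except the forehead `Fpz`) over which the
#' engagement index is computed. The right-hemisphere listing uses the old
#' temporal label T4, mapped to the recorded T8. Two parietal variants are in
#' circulation; `parietal = "lateral"` is \{P3, P4, P7, P8\},
#' `"with_pz"` is \{Pz, P3, P7, P8\}.
#'
#' @param parietal Which parietal cluster variant to use.
#' @return Named list of character vectors of channel labels.
#' @export
cluster_defs <- function(parietal = c("lateral", "with_pz")) {
  parietal <- match.arg(parietal)
  par_ch <- if (parietal == "lateral") c("P3", "P4", "P7", "P8") else
    c("Pz", "P3", "P7", "P8")
  list(
    frontal = c("F3", "F4", "F7", "F8", "Fz"),
    parietal = par_ch,
    occipital = c("O1", "O2"),
    midline = c("Fz", "Cz", "Pz"),
    left_hemisphere = c("F3", "C3", "T7", "P3", "O1"),
    right_hemisphere = resolve_channels(c("F4", "C4", "T4", "P4", "O2")),
    ei_set = setdiff(eeg_montage(), "Fpz")
  )
}
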