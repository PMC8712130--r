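# Continuous multichannel EEG container: a samples x channels matrix in
# microvolts plus sampling rate and segment annotations.

new_recording <- function(data, fs, annotations, subject_id = NA_character_,
                          modality = NA_character_) {
  stopifnot(is.matrix(data), !is.null(colnames(data)))
  structure(
    list(data = data, fs = fs, channels = colnames(data),
         annotations = annotations, subject_id = subject_id,
         modality = modality, unit = "uV"),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples (%.1f s at %g Hz, %s)\n",
              x$subject_id, x$modality, ncol(x$data), nrow(x$data),
              nrow(x$data) / x$fs, x$fs, x$unit))
  print(x$annotations)
  invisible(x)
}

#' Extract an annotated segment of a recording
#'
#' @param rec An `eeg_recording`.
#' @param label Annotation label, e.g. `"closed_eyes"` or a block id.
#' @return An `eeg_recording` holding only that segment.
#' @export
crop_recording <- function(rec, label) {
  ann <- rec$annotations[rec$annotations$label == label, ]
  if (nrow(ann) == 0L) abort(sprintf("No annotation labelled '%s'.", label))
  i0 <- floor(ann$onset_s[1] * rec$fs) + 1L
  i1 <- min(nrow(rec$data), i0 + round(ann$duration_s[1] * rec$fs) - 1L)
  new_recording(rec$data[i0:i1, , drop = FALSE], rec$fs, ann,
                rec$subject_id, rec$modality)
}

# Stimulus-locked epochs: samples x channels x epochs array plus per-epoch
# metadata (`info`) carrying artifact flags once detected.
new_epochs <- function(data, fs, t0_ms, info) {
  stopifnot(length(dim(data)) == 3L, nrow(info) == dim(data)[3])
  structure(
    list(data = data, fs = fs, t0_ms = t0_ms,
         channels = dimnames(data)[[2]], info = info),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (t0 = %g ms, %g Hz)\n",
              d[3], d[2], d[1], x$t0_ms, x$fs))
  if ("artifact" %in% names(x$info)) {
    cat(sprintf("  flagged artifactual: %d / %d\n", sum(x$info$artifact), d[3]))
  }
  invisible(x)
}
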