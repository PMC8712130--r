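#' Stimulus alphabet of the verbal n-back task
#'
#' Seven consonants are used as verbal stimuli (vowels are excluded to
#' discourage chunking); the letter `"X"` serves as the probe (target) in the
#' 0-back condition only.
#'
#' @return Character vector of the seven consonants.
#' @export
nback_alphabet <- function() c("c", "g", "k", "p", "q", "t", "v")

#' Probe letter of the 0-back condition
#' @return `"X"`.
#' @export
nback_probe <- function() "X"

#' Stimulus timing constants
#'
#' Stimuli last 500 ms in both modalities. The interstimulus interval (ISI) is
#' measured offset-to-next-onset: 2500 ms for auditory and 3000 ms for visual
#' presentation; baseline blocks use the 3000 ms ISI in both modalities.
#'
#' @param modality `"audio"` or `"video"`.
#' @param kind `"task"` or `"baseline"`.
#' @return A list with `duration_ms` and `isi_ms`.
#' @export
stimulus_timing <- function(modality = c("audio", "video"),
                            kind = c("task", "baseline")) {
  modality <- match.arg(modality)
  kind <- match.arg(kind)
  isi <- if (kind == "baseline") 3000 else if (modality == "audio") 2500 else 3000
  list(duration_ms = 500, isi_ms = isi)
}

#' Label n-back targets in a letter sequence
#'
#' A position is a target when it matches the letter presented `level`
#' positions earlier; in the 0-back condition the fixed probe letter `"X"` is
#' the target.
#'
#' @param letters Character vector of presented letters, in order.
#' @param level n-back level, one of 0, 1, 2.
#' @param probe Probe letter for the 0-back condition.
#' @return Logical vector, `TRUE` at target positions.
#' @examples
#' label_targets(c("c", "X", "g"), 0)
#' label_targets(c("c", "c", "g", "g"), 1)
#' @export
label_targets <- function(letters, level, probe = nback_probe()) {
  if (!(length(level) == 1L && level %in% 0:2)) {
    abort("`level` must be one of 0, 1, 2.")
  }
  letters <- as.character(letters)
  n <- length(letters)
  if (n == 0L) return(logical(0))
  if (level == 0) {
    letters == probe
  } else {
    flags <- rep(FALSE, n)
    if (n > level) {
      idx <- seq.int(level + 1L, n)
      flags[idx] <- letters[idx] == letters[idx - level]
    }
    flags
  }
}

# Onset schedule for a block: first onset at block_start_ms, then
# onset-to-onset asynchrony = duration + ISI.
block_onsets <- function(n_items, block_start_ms, duration_ms, isi_ms) {
  block_start_ms + (seq_len(n_items) - 1L) * (duration_ms + isi_ms)
}

#' Generate one stimulus block
#'
#' Task blocks hold 21 randomized letters with a fixed number of targets
#' (default 6 of 21, i.e. just under the nominal 30%); for level L the first L
#' positions are never targets. Baseline blocks repeat each of the seven
#' consonants exactly three times in random order and carry no task. In 0-back
#' blocks the probe `"X"` appears only at target positions; it never appears in
#' 1-/2-back blocks.
#'
#' @param level n-back level (0, 1, 2); ignored for baseline blocks.
#' @param modality `"audio"` or `"video"`.
#' @param kind `"task"` or `"baseline"`.
#' @param seed Integer seed; identical inputs and seed give identical blocks.
#' @param n_items Stimuli per block.
#' @param n_targets Targets per task block.
#' @param block_id Identifier stored with each item.
#' @param block_start_ms Onset of the first stimulus.
#' @return A tibble with one row per stimulus: `block_id`, `kind`, `level`,
#'   `modality`, `item_index` (0-based), `letter`, `onset_ms`, `duration_ms`,
#'   `is_target`.
#' @export
generate_block <- function(level, modality, kind = c("task", "baseline"),
                           seed, n_items = 21L, n_targets = 6L,
                           block_id = kind, block_start_ms = 0) {
  kind <- match.arg(kind)
  modality <- match.arg(modality, c("audio", "video"))
  if (kind == "task" && !(length(level) == 1L && level %in% 0:2)) {
    abort("`level` must be one of 0, 1, 2 for task blocks.")
  }
  timing <- stimulus_timing(modality, kind)
  alphabet <- nback_alphabet()

  letters <- with_seed(seed, {
    if (kind == "baseline") {
      sample(rep(alphabet, n_items / length(alphabet)))
    } else if (level == 0) {
      pos <- sort(sample.int(n_items, n_targets))
      out <- sample(alphabet, n_items, replace = TRUE)
      out[pos] <- nback_probe()
      out
    } else {
      admissible <- seq.int(level + 1L, n_items)
      pos <- sort(sample(admissible, n_targets))
      out <- character(n_items)
      is_tgt <- seq_len(n_items) %in% pos
      for (i in seq_len(n_items)) {
        if (is_tgt[i]) {
          out[i] <- out[i - level]
        } else if (i > level) {
          out[i] <- sample(setdiff(alphabet, out[i - level]), 1L)
        } else {
          out[i] <- sample(alphabet, 1L)
        }
      }
      out
    }
  })

  lev <- if (kind == "baseline") NA_integer_ else as.integer(level)
  targets <- if (kind == "baseline") rep(FALSE, n_items) else
    label_targets(letters, level)
  tibble(
    block_id = block_id,
    kind = kind,
    level = lev,
    modality = modality,
    item_index = seq_len(n_items) - 1L,
    letter = letters,
    onset_ms = block_onsets(n_items, block_start_ms, timing$duration_ms,
                            timing$isi_ms),
    duration_ms = timing$duration_ms,
    is_target = targets
  )
}

#' Generate a full subject-modality session plan
#'
#' One session comprises a 21-item baseline block followed by six task blocks
#' (two per n-back level) in seed-determined random order. Onsets are absolute
#' times within the session recording, which opens with a closed-eyes rest
#' segment used for individual alpha frequency estimation.
#'
#' @param subject_id Subject identifier.
#' @param modality `"audio"` or `"video"`.
#' @param seed Integer seed.
#' @param blocks_per_level Task blocks per level (2 in the full design).
#' @param closed_eyes_s Length of the opening closed-eyes rest segment.
#' @param block_gap_ms Silent gap between successive blocks.
#' @param n_targets Targets per task block.
#' @return A tibble of stimulus items (see [generate_block()]) with attributes
#'   `subject_id`, `modality`, `seed`, `closed_eyes_s`.
#' @export
generate_session <- function(subject_id, modality, seed,
                             blocks_per_level = 2L,
                             closed_eyes_s = 60,
                             block_gap_ms = 4000,
                             n_targets = 6L) {
  modality <- match.arg(modality, c("audio", "video"))
  levels <- rep(0:2, each = blocks_per_level)
  order <- with_seed(mix_seed(seed, subject_id, modality, "order"),
                     sample(seq_along(levels)))
  levels <- levels[order]

  t_ms <- closed_eyes_s * 1000 + block_gap_ms
  blocks <- vector("list", length(levels) + 1L)
  base <- generate_block(NA, modality, "baseline",
                         seed = mix_seed(seed, subject_id, modality, "baseline"),
                         block_id = "baseline", block_start_ms = t_ms)
  blocks[[1L]] <- base
  t_ms <- max(base$onset_ms) + base$duration_ms[1] +
    stimulus_timing(modality, "baseline")$isi_ms + block_gap_ms
  for (b in seq_along(levels)) {
    blk <- generate_block(levels[b], modality, "task",
                          seed = mix_seed(seed, subject_id, modality, "task", b),
                          n_targets = n_targets,
                          block_id = sprintf("task%d", b),
                          block_start_ms = t_ms)
    blocks[[b + 1L]] <- blk
    t_ms <- max(blk$onset_ms) + blk$duration_ms[1] +
      stimulus_timing(modality, "task")$isi_ms + block_gap_ms
  }
  plan <- bind_rows(blocks)
  attr(plan, "subject_id") <- subject_id
  attr(plan, "modality") <- modality
  attr(plan, "seed") <- seed
  attr(plan, "closed_eyes_s") <- closed_eyes_s
  plan
}

#' Inverse efficiency score
#'
#' IES = mean correct RT / (1 - PE), where PE is the proportion of errors. A
#' speed-accuracy composite: equals the mean RT when no errors are made and
#' grows as accuracy drops.
#'
#' @param mean_rt_correct_ms Mean reaction time over correct trials (ms).
#' @param pe Proportion of errors in `[0, 1)`.
#' @return IES in ms.
#' @examples
#' inverse_efficiency(600, 0.25) # 800
#' @export
inverse_efficiency <- function(mean_rt_correct_ms, pe) {
  if (any(pe < 0 | pe > 1)) abort("`pe` must be a proportion in [0, 1].")
  if (any(pe == 1)) {
    abort("IES is undefined when the proportion of errors is 1 (no correct trials).")
  }
  if (any(mean_rt_correct_ms <= 0)) abort("`mean_rt_correct_ms` must be positive.")
  mean_rt_correct_ms / (1 - pe)
}

#' Score responses for one n-back level
#'
#' Pools the trials of the given level across its task blocks and computes
#' accuracy (proportion of correct responses over targets and non-targets
#' jointly), mean correct reaction time, proportion of errors, and the inverse
#' efficiency score. Trials without a response count as errors.
#'
#' @param responses Tibble of trial responses with columns `block_id`,
#'   `item_index`, `response` (`"target"`, `"nontarget"`, `"none"`), `correct`,
#'   `rt_ms`.
#' @param plan Session plan from [generate_session()].
#' @param level n-back level to score.
#' @return One-row tibble: `subject_id`, `modality`, `level`, `n_trials`,
#'   `acc`, `pe`, `mean_rt_correct_ms`, `ies_ms`.
#' @export
score_condition <- function(responses, plan, level) {
  items <- dplyr::filter(plan, .data$kind == "task", .data$level == !!level)
  if (nrow(items) == 0L) abort(sprintf("No task items at level %s in the plan.", level))
  tr <- left_join(items, responses, by = c("block_id", "item_index"))
  tr$correct[is.na(tr$correct)] <- FALSE
  acc <- mean(tr$correct)
  pe <- 1 - acc
  rt_correct <- tr$rt_ms[tr$correct & !is.na(tr$rt_ms)]
  if (length(rt_correct) == 0L) {
    warn(sprintf("Level %s: no correct responses; IES undefined.", level))
    mean_rt <- NA_real_
    ies <- NA_real_
  } else {
    mean_rt <- mean(rt_correct)
    ies <- inverse_efficiency(mean_rt, pe)
  }
  tibble(
    subject_id = attr(plan, "subject_id") %||% NA_character_,
    modality = attr(plan, "modality") %||% items$modality[1],
    level = as.integer(level),
    n_trials = nrow(tr),
    acc = acc,
    pe = pe,
    mean_rt_correct_ms = mean_rt,
    ies_ms = ies
  )
}

#' Score all levels of a session
#'
#' Single-pass equivalent of calling [score_condition()] per level.
#'
#' @inheritParams score_condition
#' @return Tibble with one row per n-back level (see [score_condition()]).
#' @export
score_session <- function(responses, plan) {
  items <- dplyr::filter(plan, .data$kind == "task")
  tr <- left_join(items, responses, by = c("block_id", "item_index"))
  tr$correct[is.na(tr$correct)] <- FALSE
  out <- tr |>
    group_by(level = .data$level) |>
    summarise(
      n_trials = n(),
      acc = mean(.data$correct),
      mean_rt_correct_ms = {
        rt <- .data$rt_ms[.data$correct & !is.na(.data$rt_ms)]
        if (length(rt)) mean(rt) else NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(
      pe = 1 - .data$acc,
      ies_ms = ifelse(is.na(.data$mean_rt_correct_ms), NA_real_,
                      .data$mean_rt_correct_ms / (1 - .data$pe)),
      subject_id = attr(plan, "subject_id") %||% NA_character_,
      modality = attr(plan, "modality") %||% items$modality[1]
    ) |>
    select("subject_id", "modality", "level", "n_trials", "acc", "pe",
           "mean_rt_correct_ms", "ies_ms")
  if (anyNA(out$mean_rt_correct_ms)) {
    warn("Some level(s) had no correct responses; IES undefined there.")
  }
  out
}

#' Write / read a session event table
#'
#' Serializes the session plan (optionally joined with trial responses) as a
#' tab-separated event table, one file per subject-modality.
#'
#' @param plan Session plan.
#' @param path Output TSV path.
#' @param responses Optional responses tibble to join in.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_events_tsv <- function(plan, path, responses = NULL) {
  out <- plan
  if (!is.null(responses)) {
    out <- left_join(out, responses, by = c("block_id", "item_index"))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
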