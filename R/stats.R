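# The 2 x 3 load-by-modality statistical design: Shapiro-Wilk normality gate,
# within-subject factorial ANOVA (rank-transformed when normality is
# rejected) with partial eta squared, Duncan's multiple range test, and
# Pearson correlation.

#' Shapiro-Wilk normality check
#'
#' @param sample Numeric vector, 3 <= n <= 5000.
#' @return One-row tibble: `W`, `p`, `n`.
#' @export
normality_check <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  if (stats::sd(sample) == 0) {
    abort("Shapiro-Wilk is undefined for a constant sample.")
  }
  sw <- stats::shapiro.test(sample)
  tibble(W = unname(sw$statistic), p = sw$p.value, n = n)
}

check_cell_table <- function(table) {
  required <- c("subject", "modality", "level", "value")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(sprintf("Cell table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  counts <- table |>
    dplyr::count(.data$subject, .data$modality, .data$level)
  full <- tidyr::expand_grid(subject = unique(table$subject),
                             modality = unique(table$modality),
                             level = unique(table$level))
  chk <- left_join(full, counts, by = c("subject", "modality", "level"))
  bad <- chk[is.na(chk$n) | chk$n != 1L, ]
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Unbalanced cell table; missing or duplicated cells: %s",
      paste(utils::head(paste(bad$subject, bad$modality, bad$level, sep = ":"), 10),
            collapse = ", ")))
  }
  if (length(unique(table$subject)) < 2) abort("At least 2 subjects are required.")
  invisible(table)
}

#' Two-by-three repeated-measures factorial ANOVA
#'
#' Within-subject decomposition of a balanced subject x modality (audio/video)
#' x load (0/1/2) table: each effect (load, modality, load x modality) is
#' tested against its own subject-interaction error stratum. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`. With `normality = "auto"`,
#' cell residuals are gated through Shapiro-Wilk at `alpha`; when normality is
#' rejected, values are rank-transformed (ranks over all observations) and the
#' identical decomposition is run — preserving the factorial structure
#' including the interaction.
#'
#' @param table Tibble with columns `subject`, `modality`, `level`, `value`
#'   (one value per subject per cell).
#' @param normality `"auto"` (Shapiro gate), `"parametric"`, or `"rank"`.
#' @param alpha Significance cutoff of the normality gate.
#' @param design `"within"` (repeated measures; default) or `"between"`.
#' @return An object of class `vwm_anova`; see [tidy.vwm_anova()].
#' @export
factorial_anova <- function(table, normality = c("auto", "parametric", "rank"),
                            alpha = 0.05, design = c("within", "between")) {
  normality <- match.arg(normality)
  design <- match.arg(design)
  check_cell_table(table)

  df <- tibble(
    subject = factor(table$subject),
    modality = factor(table$modality),
    level = factor(table$level),
    value = as.numeric(table$value)
  )

  method <- "parametric"
  shapiro <- NULL
  if (normality == "auto") {
    resid <- df |>
      group_by(.data$modality, .data$level) |>
      mutate(resid = .data$value - mean(.data$value)) |>
      ungroup()
    if (stats::sd(resid$resid) > 0) {
      shapiro <- normality_check(resid$resid)
      if (shapiro$p < alpha) method <- "rank"
    }
  } else if (normality == "rank") {
    method <- "rank"
  }
  if (method == "rank") {
    df$value <- rank(df$value, ties.method = "average")
  }

  degenerate <- stats::sd(df$value) == 0
  if (design == "within") {
    fit <- stats::aov(value ~ modality * level + Error(subject / (modality * level)),
                      data = df)
    strata <- summary(fit)
    pull_stratum <- function(name) {
      s <- strata[[paste0("Error: ", name)]]
      as.data.frame(s[[1]])
    }
    eff <- list(
      modality = list(stratum = "subject:modality", row = "modality"),
      level = list(stratum = "subject:level", row = "level"),
      `modality:level` = list(stratum = "subject:modality:level",
                              row = "modality:level")
    )
    rows <- lapply(names(eff), function(e) {
      s <- pull_stratum(eff[[e]]$stratum)
      rn <- trimws(rownames(s))
      i <- match(eff[[e]]$row, rn)
      ir <- grep("Residuals", rn)
      ss_eff <- s$`Sum Sq`[i]; ss_err <- s$`Sum Sq`[ir]
      df_eff <- s$Df[i]; df_err <- s$Df[ir]
      ms_err <- ss_err / df_err
      F <- if (ss_eff == 0) 0 else (ss_eff / df_eff) / ms_err
      p <- if (ss_eff == 0) 1 else stats::pf(F, df_eff, df_err, lower.tail = FALSE)
      tibble(effect = e, df_effect = df_eff, df_error = df_err,
             ss_effect = ss_eff, ss_error = ss_err, ms_error = ms_err,
             F = F, p = p,
             partial_eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err))
    })
  } else {
    fit <- stats::aov(value ~ modality * level, data = df)
    s <- as.data.frame(summary(fit)[[1]])
    rn <- trimws(rownames(s))
    ir <- grep("Residuals", rn)
    rows <- lapply(c("modality", "level", "modality:level"), function(e) {
      i <- match(e, rn)
      ss_eff <- s$`Sum Sq`[i]; ss_err <- s$`Sum Sq`[ir]
      df_eff <- s$Df[i]; df_err <- s$Df[ir]
      F <- if (ss_eff == 0) 0 else (ss_eff / df_eff) / (ss_err / df_err)
      tibble(effect = e, df_effect = df_eff, df_error = df_err,
             ss_effect = ss_eff, ss_error = ss_err, ms_error = ss_err / df_err,
             F = F,
             p = if (ss_eff == 0) 1 else stats::pf(F, df_eff, df_err, lower.tail = FALSE),
             partial_eta_sq = if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err))
    })
  }

  table <- bind_rows(rows)
  if (degenerate) {
    # all values identical: every SS is numerically zero
    table$F <- 0
    table$p <- 1
    table$partial_eta_sq <- 0
  }
  structure(
    list(table = table, data = df, method = method,
         design = design, shapiro = shapiro, degenerate = degenerate,
         alpha = alpha),
    class = "vwm_anova"
  )
}

#' @export
print.vwm_anova <- function(x, ...) {
  cat(sprintf("<vwm_anova> 2x3 load-by-modality ANOVA (%s, %s design)\n",
              x$method, x$design))
  if (x$degenerate) cat("  note: all values identical (degenerate table)\n")
  print(as.data.frame(x$table[, c("effect", "df_effect", "df_error", "F", "p",
                                  "partial_eta_sq")]), row.names = FALSE)
  invisible(x)
}

#' Tidy / glance methods for the factorial ANOVA
#'
#' `tidy()` returns one row per effect with F, dfs, p and partial eta squared;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `vwm_anova`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vwm_anova <- function(x, ...) x$table

#' @rdname tidy.vwm_anova
#' @export
glance.vwm_anova <- function(x, ...) {
  tibble(
    n_subjects = length(unique(x$data$subject)),
    n_cells = nrow(x$data),
    method = x$method,
    design = x$design,
    shapiro_p = if (is.null(x$shapiro)) NA_real_ else x$shapiro$p,
    degenerate = x$degenerate
  )
}

# Duncan's protection level for a span of r ordered means.
duncan_alpha <- function(alpha, r) 1 - (1 - alpha)^(r - 1)

#' Duncan's multiple range test
#'
#' Stepwise post hoc comparison of ordered means after [factorial_anova()].
#' For a pair spanning `r` ranks the critical range is
#' `qtukey(1 - alpha_r, r, df_error) * sqrt(MS_error / n)` with the Duncan
#' protection level `alpha_r = 1 - (1 - alpha)^(r - 1)`; a pair is declared
#' significant only if its range exceeds the critical range and it is not
#' contained in a non-significant span (multiple-range protection rule).
#'
#' @param fit A `vwm_anova`.
#' @param effect `"level"`, `"modality"`, or `"cells"` (the six modality x
#'   level cells, tested against the interaction error stratum).
#' @param alpha Nominal significance level.
#' @return An object of class `vwm_posthoc`: tibble of pairwise comparisons
#'   with means, rank span, critical range and significance flag.
#' @export
duncan_posthoc <- function(fit, effect = c("level", "modality", "cells"),
                           alpha = 0.05) {
  effect <- match.arg(effect)
  df <- fit$data
  key <- switch(effect,
    level = df$level,
    modality = df$modality,
    cells = interaction(df$modality, df$level, sep = ":", drop = TRUE)
  )
  err_effect <- switch(effect, level = "level", modality = "modality",
                       cells = "modality:level")
  row <- fit$table[fit$table$effect == err_effect, ]
  if (nrow(row) != 1L) abort(sprintf("Effect '%s' absent from the model.", effect))
  ms_err <- row$ms_error
  df_err <- row$df_error

  means <- tapply(df$value, key, mean)
  ns <- tapply(df$value, key, length)
  if (length(unique(ns)) != 1L) abort("Unequal group sizes in post hoc.")
  n <- ns[[1]]
  ord <- order(means)
  g <- names(means)[ord]
  mo <- as.numeric(means[ord])
  k <- length(g)

  # significance of each contiguous span, widest first, with protection
  span_sig <- matrix(NA, k, k)
  for (r in k:2) {
    for (a in seq_len(k - r + 1)) {
      b <- a + r - 1L
      contained_ns <- FALSE
      if (r < k) {
        for (a2 in seq_len(k - r)) {
          for (r2 in (r + 1):k) {
            b2 <- a2 + r2 - 1L
            if (b2 > k) next
            if (a >= a2 && b <= b2 && isFALSE(span_sig[a2, b2])) contained_ns <- TRUE
          }
        }
      }
      crit <- stats::qtukey(1 - duncan_alpha(alpha, r), r, df_err) *
        sqrt(ms_err / n)
      span_sig[a, b] <- !contained_ns && (mo[b] - mo[a] > crit)
    }
  }

  pairs <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      r <- b - a + 1L
      crit <- stats::qtukey(1 - duncan_alpha(alpha, r), r, df_err) *
        sqrt(ms_err / n)
      pairs[[length(pairs) + 1L]] <- tibble(
        group1 = g[a], group2 = g[b],
        mean1 = mo[a], mean2 = mo[b],
        diff = mo[b] - mo[a],
        rank_span = r,
        critical_range = crit,
        significant = isTRUE(span_sig[a, b])
      )
    }
  }
  structure(
    list(comparisons = bind_rows(pairs), effect = effect, alpha = alpha,
         ms_error = ms_err, df_error = df_err, n_per_group = n),
    class = "vwm_posthoc"
  )
}

#' @export
print.vwm_posthoc <- function(x, ...) {
  cat(sprintf("<vwm_posthoc> Duncan multiple range test on '%s' (alpha = %g)\n",
              x$effect, x$alpha))
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}

#' @rdname tidy.vwm_anova
#' @export
tidy.vwm_posthoc <- function(x, ...) x$comparisons

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return One-row tibble: `r`, `p`, `df`, `n`, `conf_low`, `conf_high`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("At least 3 complete pairs are required.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a zero-variance input.")
  }
  ct <- stats::cor.test(x, y)
  tibble(
    r = unname(ct$estimate),
    p = ct$p.value,
    df = unname(ct$parameter),
    n = length(x),
    conf_low = ct$conf.int[1],
    conf_high = ct$conf.int[2]
  )
}
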