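test_that("the repeated-measures ANOVA matches the brute-force SS oracle", {
  # fixed 3-subject toy table, printed in full
  toy <- tibble::tribble(
    ~subject, ~modality, ~level, ~value,
    "s1", "audio", 0, 5.1,  "s1", "audio", 1, 6.3,  "s1", "audio", 2, 7.9,
    "s1", "video", 0, 4.8,  "s1", "video", 1, 5.9,  "s1", "video", 2, 7.1,
    "s2", "audio", 0, 4.2,  "s2", "audio", 1, 5.8,  "s2", "audio", 2, 6.6,
    "s2", "video", 0, 4.4,  "s2", "video", 1, 5.2,  "s2", "video", 2, 6.9,
    "s3", "audio", 0, 5.6,  "s3", "audio", 1, 6.9,  "s3", "audio", 2, 8.4,
    "s3", "video", 0, 5.0,  "s3", "video", 1, 6.1,  "s3", "video", 2, 7.7
  )
  fit <- factorial_anova(toy, normality = "parametric")
  expected <- oracle_rm_anova(toy)
  got <- tidy(fit)[, names(expected)]
  for (col in c("df_effect", "df_error", "ss_effect", "ss_error", "F", "p",
                "partial_eta_sq")) {
    expect_equal(got[[col]], expected[[col]], tolerance = 1e-10,
                 info = col)
  }
})

test_that("ANOVA agrees with the oracle on random tables of several sizes", {
  for (seed in 1:8) {
    tab <- random_cell_table(n_subjects = 3 + seed %% 4, seed = seed,
                             effect_level = 0.4 * (seed %% 2))
    fit <- factorial_anova(tab, normality = "parametric")
    expected <- oracle_rm_anova(tab)
    expect_equal(tidy(fit)$F, expected$F, tolerance = 1e-9)
    expect_equal(tidy(fit)$ss_effect, expected$ss_effect, tolerance = 1e-9)
    expect_equal(tidy(fit)$ss_error, expected$ss_error, tolerance = 1e-9)
  }
})

test_that("partial eta squared reproduces F through its identity", {
  for (seed in 1:6) {
    tab <- random_cell_table(6, seed, effect_level = 0.3)
    t1 <- tidy(factorial_anova(tab))
    F_from_eta <- (t1$partial_eta_sq / (1 - t1$partial_eta_sq)) *
      (t1$df_error / t1$df_effect)
    expect_equal(F_from_eta, t1$F, tolerance = 1e-10)
  }
})

test_that("rank-based ANOVA is invariant to strictly monotone transforms", {
  tab <- random_cell_table(8, 99, effect_level = 0.5)
  t1 <- tidy(factorial_anova(tab, normality = "rank"))
  tab2 <- tab
  tab2$value <- exp(tab2$value)        # strictly increasing transform
  t2 <- tidy(factorial_anova(tab2, normality = "rank"))
  expect_equal(t1$F, t2$F, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("the Shapiro gate routes heavy-tailed data to the rank ANOVA", {
  tab <- random_cell_table(10, 5)
  tab$value <- exp(4 * tab$value)      # strongly lognormal cells
  fit <- factorial_anova(tab, normality = "auto")
  expect_equal(fit$method, "rank")
  tabn <- random_cell_table(10, 6)
  fitn <- factorial_anova(tabn, normality = "auto")
  expect_equal(fitn$method, "parametric")
})

test_that("degenerate and malformed tables are handled explicitly", {
  tab <- random_cell_table(3, 1)
  tab$value <- 7
  fit <- factorial_anova(tab, normality = "parametric")
  expect_true(fit$degenerate)
  expect_equal(tidy(fit)$F, rep(0, 3))
  expect_equal(tidy(fit)$p, rep(1, 3))

  bad <- random_cell_table(3, 2)[-1, ]
  expect_error(factorial_anova(bad), "missing or duplicated")
  one <- random_cell_table(1, 3)
  expect_error(factorial_anova(one), "2 subjects")
})

test_that("normality_check calibrates under the null and detects skew", {
  res <- normality_check(withr::with_seed(1, rnorm(50)))
  expect_true(all(c("W", "p") %in% names(res)))
  rates <- withr::with_seed(11, {
    c(
      null = mean(replicate(300, normality_check(rnorm(50))$p < 0.05)),
      expo = mean(replicate(300, normality_check(rexp(50))$p < 0.05))
    )
  })
  expect_gt(rates[["null"]], 0.01)
  expect_lt(rates[["null"]], 0.11)
  expect_gt(rates[["expo"]], 0.80)
  expect_error(normality_check(c(1, 2)), "n")
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("Duncan's test finds no differences between identical groups", {
  tab <- random_cell_table(8, 4)      # pure noise, no effects
  fit <- factorial_anova(tab, normality = "parametric")
  ph <- duncan_posthoc(fit, "level")
  expect_equal(nrow(ph$comparisons), 3L)
  # critical ranges non-decreasing in rank span
  cr <- ph$comparisons[order(ph$comparisons$rank_span), ]
  expect_true(all(diff(cr$critical_range) >= -1e-12))
})

test_that("Duncan's test separates groups 20 sigma apart", {
  tab <- random_cell_table(8, 7)
  tab$value <- tab$value + 20 * tab$level     # separation >> error SD
  fit <- factorial_anova(tab, normality = "parametric")
  ph <- duncan_posthoc(fit, "level")
  expect_true(all(ph$comparisons$significant))
  ph_cells <- duncan_posthoc(fit, "cells")
  expect_equal(nrow(ph_cells$comparisons), choose(6, 2))
})

test_that("the multiple-range protection rule suppresses nested raw hits", {
  # construct a fit whose ordered level means are 0 < x < R with
  # C2 < x <= R <= C3: the (1,2) pair exceeds its own critical range but
  # sits inside a non-significant full span, so it must be protected
  df_err <- 20; ms_err <- 1; n <- 4
  c2 <- stats::qtukey(0.95, 2, df_err) * sqrt(ms_err / n)
  c3 <- stats::qtukey(1 - vwmeeg:::duncan_alpha(0.05, 3), 3, df_err) *
    sqrt(ms_err / n)
  expect_gt(c3, c2)
  x <- (c2 + c3) / 2
  R <- c3 * 0.999
  data <- tibble::tibble(
    subject = rep(c("a", "b"), each = 6),
    modality = rep(c("audio", "video"), 6),
    level = rep(rep(0:2, each = 2), 2),
    value = rep(rep(c(0, x, R), each = 2), 2)
  )
  fake <- structure(
    list(table = tibble::tibble(effect = "level", df_effect = 2,
                                df_error = df_err, ss_effect = 1,
                                ss_error = ms_err * df_err,
                                ms_error = ms_err, F = 1, p = 0.5,
                                partial_eta_sq = 0.1),
         data = data, method = "parametric"),
    class = "vwm_anova"
  )
  ph <- duncan_posthoc(fake, "level")
  cmp <- ph$comparisons
  pair12 <- cmp[cmp$rank_span == 2 & cmp$diff > c2, ]
  expect_gte(nrow(pair12), 1)            # raw range exceeds its critical range
  expect_false(any(cmp$significant))     # but the protection rule blocks it
  expect_error(duncan_posthoc(fake, "modality"), "absent")
})

test_that("Pearson correlation matches its closed forms and guards", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  out <- correlate(x, x + withr::with_seed(2, rnorm(20)))
  expect_equal(out$df, 18)
  expect_error(correlate(x, rep(1, 20)), "zero-variance")
  expect_error(correlate(x, 1:19), "equal length")
  # null calibration at the cohort's cell count
  rs <- withr::with_seed(9, replicate(1000, correlate(rnorm(66), rnorm(66))$r))
  expect_gte(mean(abs(rs) < 0.25), 0.95)
})
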