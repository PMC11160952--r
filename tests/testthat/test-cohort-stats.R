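test_that("Kruskal-Wallis H matches the hand-computed rank-sum formula", {
  kw <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p_value, stats::pchisq(7.2, df = 2, lower.tail = FALSE))
  # all-tied input: p = 1 by convention
  kw0 <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(1:3, factor(c("a", "a", "a"), levels = c("a", "b"))),
               "empty")
  expect_error(kruskal_wallis(1:3, c("a", "a", "a")), "2 groups")
})

test_that("Kruskal-Wallis with two groups matches the normal-approximation
           Mann-Whitney decision on tie-free data", {
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(10, mean = sample(c(0, 1), 1))
    kw <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(12, 10)))
    mw <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(kw$p_value < 0.05, mw$p.value < 0.05)
    expect_equal(kw$p_value, mw$p.value, tolerance = 1e-6)
  }
})

test_that("Wilcoxon signed-rank: exact enumeration and degenerate cases", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(w$statistic, 15)      # all ranks positive, W- = 0
  expect_equal(w$p_value, 2 / 2^5)   # exact two-sided 0.0625
  expect_equal(w$method, "wilcoxon_signed_rank_exact")

  w2 <- wilcoxon_signed_rank(c(-2, 2))
  expect_equal(w2$p_value, 1)

  # zeros dropped before ranking
  w3 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(w3$p_value, 0.0625)
  expect_equal(w3$n, 5L)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")

  # paired interface
  w4 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w4$p_value, 0.0625)
})

test_that("mixed model recovers planted effects and variance components", {
  cp <- cohort_gen_params(n_per_stage = 20, side_effect = -0.009,
                          patient_sd = 0.015, residual_sd = 0.008, seed = 31)
  m <- fit_quietly(generate_metrics_cohort(cp))
  expect_lt(abs(m$side_marginal$estimate + 0.009), 0.003)
  expect_true(m$side_marginal$ci_lower <= -0.009 &&
                -0.009 <= m$side_marginal$ci_upper)
  expect_lt(abs(sqrt(m$varcomp[["patient"]]) - 0.015), 0.006)
  expect_lt(abs(sqrt(m$varcomp[["residual"]]) - 0.008), 0.003)
  # treatment coding against the declared references
  expect_true(all(c("(Intercept)", "stagemild", "sideleft", "sexmale") %in%
                    m$fixed$term))
})

test_that("zero patient variance collapses the mixed model to OLS", {
  cp <- cohort_gen_params(n_per_stage = 10, patient_sd = 0, seed = 8)
  co <- generate_metrics_cohort(cp)
  m <- fit_quietly(co)
  expect_lte(m$varcomp[["patient"]], 1e-4)
  ols <- stats::lm(response ~ stage + side + age + hba1c + sex + stage:side,
                   data = co)
  expect_lt(abs(m$fixed$estimate[m$fixed$term == "sideleft"] -
                  stats::coef(ols)[["sideleft"]]), 1e-6)
})

test_that("estimates are invariant to row order and patient relabeling", {
  cp <- cohort_gen_params(n_per_stage = 8, seed = 14)
  co <- generate_metrics_cohort(cp)
  m1 <- fit_quietly(co)
  set.seed(1)
  perm <- co[sample(nrow(co)), ]
  perm$patient_id <- paste0("XX_", perm$patient_id)
  m2 <- fit_quietly(perm)
  expect_equal(m2$side_marginal$estimate, m1$side_marginal$estimate,
               tolerance = 1e-8)
  expect_equal(sort(m2$fixed$estimate), sort(m1$fixed$estimate),
               tolerance = 1e-8)
})

test_that("rows with missing covariates are dropped and logged", {
  co <- generate_metrics_cohort(cohort_gen_params(n_per_stage = 8, seed = 2))
  co$hba1c[co$patient_id == "P0001"] <- NA  # one patient, HbA1c unknown
  m <- fit_quietly(co)
  expect_match(m$log, "dropped 2 row", all = FALSE)
  expect_equal(m$n_eyes, nrow(co) - 2L)
})

test_that("single-sex cohorts raise a collinearity error", {
  co <- generate_metrics_cohort(cohort_gen_params(n_per_stage = 5, seed = 3))
  co$sex <- "male"
  expect_error(fit_intereye_model(co), "sex")
})

test_that("branching logic follows the F-tests", {
  # interaction planted only in PDR triggers per-stage side contrasts
  cp <- cohort_gen_params(n_per_stage = 34, side_effect = 0,
                          interaction_effects = c(0, 0, 0, 0, -0.012),
                          stage_effects = rep(0, 5), seed = 19)
  m <- fit_quietly(generate_metrics_cohort(cp))
  rep <- branch_and_contrast(m)
  expect_true(rep$interaction_triggered)
  pdr <- rep$side_by_stage[rep$side_by_stage$stage == "PDR", ]
  half_width <- (pdr$ci_upper - pdr$ci_lower) / 2
  expect_lt(abs(pdr$estimate + 0.012), half_width)

  # contrasts vs "no DR" equal differences of fitted stage means
  cp2 <- cohort_gen_params(n_per_stage = 10,
                           stage_effects = c(0, 0.02, 0.02, -0.02, -0.02),
                           seed = 23)
  m2 <- fit_quietly(generate_metrics_cohort(cp2))
  rep2 <- branch_and_contrast(m2)
  expect_true(rep2$stage_triggered)
  emm <- suppressMessages(
    as.data.frame(emmeans::emmeans(m2$fit, ~stage, lmer.df = "satterthwaite")))
  diffs <- emm$emmean[match(c("mild", "moderate", "severe", "PDR"), emm$stage)] -
    emm$emmean[emm$stage == "no"]
  expect_equal(rep2$stage_contrasts$estimate, diffs, tolerance = 1e-8)

  # a quiet interaction leaves the per-stage branch untaken
  cp3 <- cohort_gen_params(n_per_stage = 10, stage_effects = rep(0, 5),
                           side_effect = -0.009, seed = 29)
  m3 <- fit_quietly(generate_metrics_cohort(cp3))
  rep3 <- branch_and_contrast(m3)
  if (!rep3$interaction_triggered) {
    expect_null(rep3$side_by_stage)
    expect_false(is.null(rep3$side_overall$estimate))
  }
})
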