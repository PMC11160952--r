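# Cohort-level statistics: rank tests across DR stages and the linear
# mixed model for side/stage effects with interaction branching.

#' Kruskal-Wallis test across DR stages
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom. When every observation is identical the tie correction is
#' degenerate; by convention H = 0 and p = 1 are reported (no evidence
#' against the null).
#'
#' @param values Numeric vector of per-patient values (e.g. asymmetry
#'   indices).
#' @param groups Grouping factor (e.g. DR stage); every level must be
#'   non-empty.
#' @return Object of class `rank_test`: `statistic`, `p_value`, `n`
#'   (per-group sizes), `method`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n <- table(groups)
  if (any(n == 0L)) stop("empty group(s): ",
                         paste(names(n)[n == 0L], collapse = ", "))
  if (length(unique(values)) == 1L) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    res <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 n = as.integer(n), method = "kruskal_wallis"),
            class = "rank_test")
}

#' Wilcoxon signed-rank test on paired values
#'
#' Drops zero differences, ranks the absolute differences with average
#' ranks for ties, and reports a two-sided p-value: exact for n <= 25
#' without ties, normal approximation with continuity correction
#' otherwise.
#'
#' @param x Numeric vector: first member of each pair, or the paired
#'   differences themselves when `y` is `NULL`.
#' @param y Optional second member of each pair.
#' @return Object of class `rank_test` with the positive-rank-sum
#'   statistic.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n = length(d),
                 method = if (exact) "wilcoxon_signed_rank_exact"
                          else "wilcoxon_signed_rank_normal"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s: statistic %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Fit the intereye linear mixed model
#'
#' REML fit of
#' `response ~ stage + side + age + hba1c + sex + stage:side +
#' (1 | patient_id)`
#' with treatment coding (references: stage `"no"`, side `"right"`, sex
#' `"female"`). Reports Wald 95% CIs for the fixed effects,
#' Satterthwaite-denominator F-tests for stage and the stage-by-side
#' interaction, the marginal left-vs-right effect averaged over stages, and
#' the variance components. Rows with missing response or covariates are
#' dropped and logged. When the data hold a single stage the stage terms
#' are omitted (logged), so small single-stage cohorts remain analyzable; a
#' single-level sex is reported as a collinear term error.
#'
#' @param cohort Data frame with columns `patient_id, side, stage, age,
#'   sex, hba1c` and the response column.
#' @param response Name of the response column.
#' @param alpha Significance level used by the branching logic.
#' @return Object of class `intereye_lmm`.
#' @export
fit_intereye_model <- function(cohort, response = "response", alpha = 0.05) {
  req <- c("patient_id", "side", "stage", "age", "sex", "hba1c", response)
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- cohort
  dat$.response <- dat[[response]]
  keep <- stats::complete.cases(dat[, c(".response", "age", "sex", "hba1c")])
  log <- character()
  if (any(!keep)) {
    log <- c(log, sprintf("dropped %d row(s) with missing response/covariates: %s",
                          sum(!keep),
                          paste(unique(dat$patient_id[!keep]), collapse = ", ")))
    dat <- dat[keep, , drop = FALSE]
  }
  stage_levels <- intersect(c("no", "mild", "moderate", "severe", "PDR"),
                            as.character(unique(dat$stage)))
  dat$stage <- factor(as.character(dat$stage), levels = stage_levels)
  dat$side <- factor(as.character(dat$side), levels = c("right", "left"))
  dat$sex <- factor(as.character(dat$sex), levels = c("female", "male"))
  dat$sex <- droplevels(dat$sex)
  if (nlevels(dat$sex) < 2L) {
    stop("singular design: collinear term `sex` (single-sex cohort)")
  }
  has_stage <- nlevels(dat$stage) > 1L
  if (!has_stage) {
    log <- c(log, "single stage present: stage and stage:side terms omitted")
  }
  form <- if (has_stage) {
    .response ~ stage + side + age + hba1c + sex + stage:side + (1 | patient_id)
  } else {
    .response ~ side + age + hba1c + sex + (1 | patient_id)
  }
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE)

  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - alpha / 2)
  fixed <- data.frame(
    term = rownames(sm), estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    ci_lower = sm[, "Estimate"] - z * sm[, "Std. Error"],
    ci_upper = sm[, "Estimate"] + z * sm[, "Std. Error"],
    df = sm[, "df"], p_value = sm[, "Pr(>|t|)"], row.names = NULL)

  an <- stats::anova(fit, type = 3)
  ftests <- data.frame(term = rownames(an), f = an[, "F value"],
                       df1 = an[, "NumDF"], df2 = an[, "DenDF"],
                       p_value = an[, "Pr(>F)"], row.names = NULL)

  emm_side <- suppressMessages(
    emmeans::emmeans(fit, ~side, lmer.df = "satterthwaite"))
  ct <- emmeans::contrast(emm_side, "trt.vs.ctrl", ref = "right",
                          adjust = "none")
  cs <- cbind(as.data.frame(ct), stats::confint(ct, level = 1 - alpha)[,
    c("lower.CL", "upper.CL")])
  side_marginal <- list(estimate = cs$estimate[1], se = cs$SE[1],
                        ci_lower = cs$lower.CL[1], ci_upper = cs$upper.CL[1],
                        p_value = cs$p.value[1])

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(patient = vc$vcov[vc$grp == "patient_id"][1],
               residual = vc$vcov[vc$grp == "Residual"][1])

  structure(
    list(fit = fit, fixed = fixed, ftests = ftests,
         side_marginal = side_marginal, varcomp = varcomp,
         stage_f_p = if (has_stage) ftests$p_value[ftests$term == "stage"] else NA_real_,
         interaction_f_p = if (has_stage) ftests$p_value[ftests$term == "stage:side"] else NA_real_,
         alpha = alpha, response = response, has_stage = has_stage,
         n_patients = length(unique(dat$patient_id)), n_eyes = nrow(dat),
         log = log, data = dat),
    class = "intereye_lmm"
  )
}

#' @export
print.intereye_lmm <- function(x, ...) {
  cat(sprintf("Intereye linear mixed model for '%s' (%d eyes, %d patients)\n",
              x$response, x$n_eyes, x$n_patients))
  cat(sprintf("  side (left vs right, marginal): %.4g [%.4g; %.4g], p = %.3g\n",
              x$side_marginal$estimate, x$side_marginal$ci_lower,
              x$side_marginal$ci_upper, x$side_marginal$p_value))
  if (x$has_stage) {
    cat(sprintf("  F-tests: stage p = %.3g, stage:side p = %.3g\n",
                x$stage_f_p, x$interaction_f_p))
  }
  cat(sprintf("  variance components: patient %.3g, residual %.3g\n",
              x$varcomp[["patient"]], x$varcomp[["residual"]]))
  invisible(x)
}

#' @export
summary.intereye_lmm <- function(object, ...) {
  print(object)
  cat("\nFixed effects (Wald CIs):\n")
  print(object$fixed, digits = 4)
  if (length(object$log)) cat("\nNotes:", paste(object$log, collapse = "; "), "\n")
  invisible(object)
}

#' @export
coef.intereye_lmm <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

#' @export
confint.intereye_lmm <- function(object, ...) {
  m <- as.matrix(object$fixed[, c("ci_lower", "ci_upper")])
  rownames(m) <- object$fixed$term
  m
}

#' Apply the stage/interaction branching logic and emit contrasts
#'
#' Mirrors the reporting rules of the cohort analysis: when the stage
#' F-test is significant at `alpha`, each stage is compared with the
#' no-DR reference; when the stage-by-side interaction F-test is
#' significant, left-vs-right comparisons are computed within each stage,
#' otherwise the single marginal side effect is reported. No multiplicity
#' correction is applied; p-values are descriptive.
#'
#' @param model An [fit_intereye_model()] result.
#' @param alpha Significance level for the branch decisions (defaults to
#'   the model's).
#' @return Object of class `intereye_report`: list with `stage_triggered`,
#'   `interaction_triggered`, `stage_contrasts` (vs no DR),
#'   `side_by_stage` (left vs right within stage), `side_overall`.
#' @export
branch_and_contrast <- function(model, alpha = model$alpha) {
  if (!inherits(model, "intereye_lmm")) stop("`model` must be an intereye_lmm")
  contrast_frame <- function(ct, level) {
    ci <- stats::confint(ct, level = level)
    df <- as.data.frame(ct)
    df$ci_lower <- ci$lower.CL
    df$ci_upper <- ci$upper.CL
    df
  }
  stage_triggered <- isTRUE(model$stage_f_p < alpha)
  interaction_triggered <- isTRUE(model$interaction_f_p < alpha)
  stage_contrasts <- NULL
  side_by_stage <- NULL
  if (stage_triggered) {
    emm <- suppressMessages(
      emmeans::emmeans(model$fit, ~stage, lmer.df = "satterthwaite"))
    ct <- emmeans::contrast(emm, "trt.vs.ctrl", ref = "no", adjust = "none")
    stage_contrasts <- contrast_frame(ct, 1 - alpha)
  }
  if (interaction_triggered) {
    emm <- suppressMessages(
      emmeans::emmeans(model$fit, ~side | stage,
                       lmer.df = "satterthwaite"))
    ct <- emmeans::contrast(emm, "trt.vs.ctrl", ref = "right", adjust = "none")
    side_by_stage <- contrast_frame(ct, 1 - alpha)
  }
  structure(
    list(stage_triggered = stage_triggered,
         interaction_triggered = interaction_triggered,
         stage_contrasts = stage_contrasts, side_by_stage = side_by_stage,
         side_overall = model$side_marginal, alpha = alpha,
         response = model$response),
    class = "intereye_report"
  )
}

#' @export
print.intereye_report <- function(x, ...) {
  cat(sprintf("Intereye report for '%s' (alpha = %g, no multiplicity correction)\n",
              x$response, x$alpha))
  if (x$stage_triggered) {
    cat("Stage F-test significant; contrasts vs no DR:\n")
    print(x$stage_contrasts, digits = 4)
  } else {
    cat("Stage F-test not significant; no stage contrasts.\n")
  }
  if (x$interaction_triggered) {
    cat("Stage-by-side interaction significant; left vs right per stage:\n")
    print(x$side_by_stage, digits = 4)
  } else {
    cat(sprintf("Overall left vs right: %.4g [%.4g; %.4g], p = %.3g\n",
                x$side_overall$estimate, x$side_overall$ci_lower,
                x$side_overall$ci_upper, x$side_overall$p_value))
  }
  invisible(x)
}
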