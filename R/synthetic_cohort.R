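#' Parameters of the metrics-level synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a diabetic-retinopathy
#' OCTA cohort on the superficial-plexus vessel-density scale: grand mean
#' 0.218 with small stage offsets, a -0.009 left-eye offset, between-patient
#' SD 0.015 and within-eye residual SD 0.008. Age, HbA1c and sex are drawn
#' to match a typical adult diabetic cohort (age ~ N(57.2, 13.1^2),
#' HbA1c ~ N(7.34, 1.32^2), 66% male) and have no effect on the response
#' unless effects are supplied.
#'
#' @param n_per_stage Patients per DR stage; scalar or length-5 vector for
#'   the stages no/mild/moderate/severe/PDR. Each must be >= 2.
#' @param grand_mean Baseline of the response metric (reference: right eye,
#'   no DR, covariates at their cohort means).
#' @param stage_effects Named or positional length-5 additive stage offsets
#'   (first entry, "no", is conventionally 0).
#' @param side_effect Additive offset applied to left eyes.
#' @param interaction_effects Length-5 additional left-eye offsets per
#'   stage (stage-by-side interaction; first entry conventionally 0).
#' @param patient_sd SD of the patient-level random intercept (>= 0).
#' @param residual_sd Within-eye residual SD (> 0).
#' @param age_effect,hba1c_effect,sex_effect Linear covariate effects per
#'   year of age (centered at 57.2), per HbA1c unit (centered at 7.34), and
#'   for male sex.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_per_stage = 34L, grand_mean = 0.218,
                              stage_effects = c(no = 0, mild = 0.009,
                                                moderate = 0, severe = -0.005,
                                                PDR = -0.006),
                              side_effect = -0.009,
                              interaction_effects = c(0, 0, 0, 0, 0),
                              patient_sd = 0.015, residual_sd = 0.008,
                              age_effect = 0, hba1c_effect = 0,
                              sex_effect = 0, seed = 1L) {
  stages <- c("no", "mild", "moderate", "severe", "PDR")
  if (length(n_per_stage) == 1L) n_per_stage <- rep(n_per_stage, 5L)
  if (length(n_per_stage) != 5L || any(n_per_stage < 2L)) {
    stop("`n_per_stage` must give >= 2 patients for each of the 5 stages")
  }
  if (length(stage_effects) != 5L || length(interaction_effects) != 5L) {
    stop("`stage_effects` and `interaction_effects` must have length 5")
  }
  if (patient_sd < 0) stop("`patient_sd` must be >= 0")
  if (residual_sd <= 0) stop("`residual_sd` must be > 0")
  structure(
    list(stages = stages, n_per_stage = as.integer(n_per_stage),
         grand_mean = grand_mean,
         stage_effects = stats::setNames(as.numeric(stage_effects), stages),
         side_effect = side_effect,
         interaction_effects = stats::setNames(as.numeric(interaction_effects),
                                               stages),
         patient_sd = patient_sd, residual_sd = residual_sd,
         age_effect = age_effect, hba1c_effect = hba1c_effect,
         sex_effect = sex_effect, seed = as.integer(seed)),
    class = "cohort_gen_params"
  )
}

#' Generate a metrics-level synthetic cohort
#'
#' Emits one row per eye (two per patient) with the additive structure the
#' cohort mixed model assumes:
#' `response = grand_mean + stage_effect + side_effect * I(left) +
#' interaction * I(left) + covariate terms + patient intercept + residual`,
#' with the patient intercept ~ N(0, patient_sd^2) shared by fellow eyes
#' and an independent N(0, residual_sd^2) residual per eye. Age and HbA1c
#' enter centered at their cohort means so `grand_mean` keeps its
#' interpretation.
#'
#' @param params A [cohort_gen_params()] list.
#' @return Data frame with columns `patient_id, side, stage, age, sex,
#'   hba1c, response`; `stage` and `side` are factors with reference levels
#'   `"no"` and `"right"`.
#' @export
generate_metrics_cohort <- function(params = cohort_gen_params()) {
  if (!inherits(params, "cohort_gen_params")) {
    params <- do.call(cohort_gen_params, params)
  }
  rows <- vector("list", sum(params$n_per_stage))
  k <- 0L
  for (si in seq_along(params$stages)) {
    stage <- params$stages[si]
    for (i in seq_len(params$n_per_stage[si])) {
      k <- k + 1L
      set.seed(derive_seed(params$seed, k))
      age <- stats::rnorm(1, 57.2, 13.1)
      hba1c <- stats::rnorm(1, 7.34, 1.32)
      sex <- if (stats::runif(1) < 0.66) "male" else "female"
      b <- if (params$patient_sd > 0) stats::rnorm(1, 0, params$patient_sd) else 0
      eps <- stats::rnorm(2, 0, params$residual_sd)
      base <- params$grand_mean + params$stage_effects[[stage]] +
        params$age_effect * (age - 57.2) +
        params$hba1c_effect * (hba1c - 7.34) +
        params$sex_effect * (sex == "male") + b
      rows[[k]] <- data.frame(
        patient_id = sprintf("P%04d", k),
        side = c("right", "left"),
        stage = stage, age = age, sex = sex, hba1c = hba1c,
        response = c(base + eps[1],
                     base + params$side_effect +
                       params$interaction_effects[[stage]] + eps[2]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$stage <- factor(out$stage, levels = params$stages)
  out$side <- factor(out$side, levels = c("right", "left"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  out
}
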