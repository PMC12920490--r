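#' Canonical variable registry
#'
#' Every predictor and outcome handled by the pipeline has one canonical
#' column name. Roles follow the two-step model layout: 21 step-one
#' predictors (interoceptive task scores, questionnaire subscales and the
#' four physiological measures), 14 step-two exteroceptive body-representation
#' measures, and the eight SF-36 subscales as outcomes.
#'
#' @return A data.frame with columns `name`, `role`
#'   (`"interoceptive"`, `"physiological"`, `"exteroceptive"`, `"outcome"`),
#'   `unit` and `source` (the scoring stage that produces the variable).
#' @export
#' @examples
#' nrow(variable_registry())
#' table(variable_registry()$role)
variable_registry <- function() {
  reg <- rbind(
    data.frame(
      name = c("acc_d", "acc_c", "con_d", "con_c", "aw_d", "aw_c"),
      role = "interoceptive",
      unit = c("proportion", "proportion", "1-9", "1-9", "0-1", "0-1"),
      source = "intero_scoring"
    ),
    data.frame(
      name = c(paste0("maia_m", 1:8), "bpq_boa", "bpq_sup", "bpq_boa_sub"),
      role = "interoceptive",
      unit = c(rep("0-5 mean", 8), rep("item sum", 3)),
      source = "questionnaire"
    ),
    data.frame(
      name = c("mean_hr", "hf_log_power", "lf_hf", "breath_freq"),
      role = "physiological",
      unit = c("beats/min", "log(ms^2)", "ratio", "breaths/min"),
      source = "physio_signals"
    ),
    data.frame(
      name = c("delta_ar", "c_che", "c_arm", "hit",
               "auc_av", "auc_at", "auc_vt",
               "jnd_sj", "pse_pps", "jnd_toju", "jnd_tojc", "sc",
               "mre_lh", "mre_rh"),
      role = "exteroceptive",
      unit = c("BMI units", "%", "%", "count",
               "prob*percentile", "prob*percentile", "prob*percentile",
               "ms", "stimulus units", "ms", "ms", "dimensionless",
               "ms/degree", "ms/degree"),
      source = "extero_scoring"
    ),
    data.frame(
      name = c("sf36_physical_functioning", "sf36_role_physical",
               "sf36_role_emotional", "sf36_energy_fatigue",
               "sf36_emotional_wellbeing", "sf36_social_functioning",
               "sf36_bodily_pain", "sf36_general_health"),
      role = "outcome",
      unit = "0-100",
      source = "input"
    )
  )
  rownames(reg) <- NULL
  reg
}

#' Step-one predictor names (interoceptive + physiological, 21 variables)
#' @export
step1_predictors <- function() {
  reg <- variable_registry()
  reg$name[reg$role %in% c("interoceptive", "physiological")]
}

#' Step-two exteroceptive predictor names (14 variables)
#' @export
extero_predictors <- function() {
  reg <- variable_registry()
  reg$name[reg$role == "exteroceptive"]
}

#' SF-36 outcome names (eight subscales)
#' @export
sf36_outcomes <- function() {
  reg <- variable_registry()
  reg$name[reg$role == "outcome"]
}

#' Check that a cohort table carries every registry column needed for a run
#'
#' @param cohort data.frame, one row per participant.
#' @param columns character vector of required column names.
#' @keywords internal
assert_registry_columns <- function(cohort, columns) {
  missing <- setdiff(columns, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort is missing registry column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic sub-seed derivation: one user seed fans out to independent
# sub-streams by a counter hash, kept below 2^31.
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter))
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in c(counter + 1, 2654435769, counter + 97)) {
    x <- (x * 69069 + k) %% 2147483647
  }
  as.integer(x)
}
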