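#' Configuration for the two-step procedure
#'
#' @param alpha model-level significance threshold on the permutation p of
#'   the out-of-sample r (default 0.05).
#' @param n_perm permutations per model (default 1000).
#' @param k_max largest candidate component count (default 10).
#' @param seed integer master seed (required; per-model sub-seeds derive
#'   from it deterministically).
#' @param perm_scheme permutation scheme for the r null, see
#'   [permutation_inference()].
#' @param bonferroni correct the eight step-one p-values for multiple
#'   testing (off by default: each model is reported at the nominal level).
#' @param retention `"union"` (one retained set pooled across significant
#'   models, default) or `"per_model"`.
#' @export
two_step_config <- function(alpha = 0.05, n_perm = 1000L, k_max = 10L, seed,
                            perm_scheme = c("fixed_k", "full"),
                            bonferroni = FALSE,
                            retention = c("union", "per_model")) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  list(alpha = alpha, n_perm = as.integer(n_perm), k_max = as.integer(k_max),
       seed = as.integer(seed), perm_scheme = match.arg(perm_scheme),
       bonferroni = bonferroni, retention = match.arg(retention))
}

run_models <- function(cohort, predictors, outcomes, config, seed_offset) {
  X <- as.matrix(cohort[, predictors, drop = FALSE])
  out <- list()
  for (i in seq_along(outcomes)) {
    o <- outcomes[i]
    out[[o]] <- permutation_inference(
      X, cohort[[o]], K_max = config$k_max, n_perm = config$n_perm,
      seed = split_seed(config$seed, seed_offset + i),
      perm_scheme = config$perm_scheme
    )
  }
  out
}

#' Step one: eight interoceptive-only PLSR models
#'
#' One nested-CV + permutation run per SF-36 subscale, using the 21
#' interoceptive and physiological predictors. A model is significant when
#' the permutation p of its out-of-sample r falls below `config$alpha`
#' (Bonferroni-adjusted across the eight models if requested).
#'
#' @param cohort data.frame with all registry columns.
#' @param config a [two_step_config()].
#' @return List: `models` (per-outcome `plsr_cv_result`),
#'   `significant_outcomes`.
#' @export
run_step1 <- function(cohort, config) {
  preds <- step1_predictors()
  outs <- sf36_outcomes()
  assert_registry_columns(cohort, c(preds, outs))
  if (nrow(cohort) < 10) {
    stop("cohort too small for nested cross-validation (n < 10)",
         call. = FALSE)
  }
  models <- run_models(cohort, preds, outs, config, seed_offset = 100L)
  alpha <- if (config$bonferroni) config$alpha / length(outs) else config$alpha
  sig <- names(models)[vapply(models, function(m) m$p_perm < alpha,
                              logical(1))]
  list(models = models, significant_outcomes = sig, alpha = alpha)
}

#' Retained interoceptive predictors after step one
#'
#' Union, across the significant step-one models, of the predictors whose
#' weights exceeded their permutation-null interval (per-model retention
#' available via config; the union matches the single pooled retained list
#' the two-step layout reports).
#'
#' @param step1 result of [run_step1()].
#' @param retention `"union"` or `"per_model"`.
#' @return Character vector (union mode) or named list (per-model mode);
#'   empty when no model was significant.
#' @export
select_retained_predictors <- function(step1, retention = "union") {
  sig_of <- function(m) names(m$weights)[m$significant]
  per_model <- lapply(step1$models[step1$significant_outcomes], sig_of)
  if (retention == "per_model") return(per_model)
  sort(unique(as.character(unlist(per_model))))
}

#' Step two: augmented models for the significant outcomes
#'
#' Per significant step-one outcome, refits the nested-CV + permutation
#' procedure on the retained interoceptive predictors plus the 14
#' exteroceptive body-representation measures.
#'
#' @param cohort data.frame; @param retained non-empty character vector;
#' @param outcomes the significant step-one outcomes; @param config config.
#' @return List of per-outcome `plsr_cv_result`s.
#' @export
run_step2 <- function(cohort, retained, outcomes, config) {
  if (length(retained) == 0) {
    stop("retained predictor set is empty", call. = FALSE)
  }
  stopifnot(all(retained %in% step1_predictors()))
  preds <- c(retained, extero_predictors())
  assert_registry_columns(cohort, c(preds, outcomes))
  run_models(cohort, preds, outcomes, config, seed_offset = 200L)
}

#' Run the full two-step procedure
#'
#' @param cohort data.frame carrying every registry column.
#' @param config a [two_step_config()].
#' @return A `two_step_report`: `step1`, `significant_outcomes`,
#'   `retained_predictors`, `step2` (NULL after an early exit with no
#'   significant step-one model or an empty retained set), `config`.
#' @export
run_two_step <- function(cohort, config) {
  step1 <- run_step1(cohort, config)
  retained <- select_retained_predictors(step1, config$retention)
  retained_flat <- sort(unique(as.character(unlist(retained))))
  step2 <- NULL
  if (length(step1$significant_outcomes) > 0 && length(retained_flat) > 0) {
    if (config$retention == "union") {
      step2 <- run_step2(cohort, retained_flat, step1$significant_outcomes,
                         config)
    } else {
      step2 <- list()
      for (o in step1$significant_outcomes) {
        if (length(retained[[o]]) == 0) next
        step2[[o]] <- run_step2(cohort, retained[[o]], o, config)[[o]]
      }
      if (length(step2) == 0) step2 <- NULL
    }
  }
  structure(
    list(step1 = step1$models,
         significant_outcomes = step1$significant_outcomes,
         retained_predictors = retained_flat,
         step2 = step2,
         config = config),
    class = "two_step_report"
  )
}

result_to_list <- function(m) {
  list(r = m$r, p_perm = m$p_perm, modal_k = m$modal_k,
       chosen_k = m$chosen_k, predictions = m$predictions,
       weights = as.list(m$weights),
       null_lo = as.list(m$null_lo), null_hi = as.list(m$null_hi),
       significant = names(m$weights)[m$significant])
}

#' Write a two-step report to JSON plus a summary table
#'
#' The JSON file holds the machine-readable report (fit statistics,
#' weights, null intervals, per-subject predictions). The TSV summary
#' mirrors the dimension-by-outcome layout: one column per significant
#' outcome, rows for the exteroceptive, physiological and interoceptive
#' dimensions that contributed significantly.
#'
#' @param report a `two_step_report`; @param path basename (writes
#'   `<path>.json` and `<path>_summary.tsv`).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "two_step_report"))
  out <- list(
    significant_outcomes = report$significant_outcomes,
    retained_predictors = report$retained_predictors,
    step1 = lapply(report$step1, result_to_list),
    step2 = if (is.null(report$step2)) NULL else
      lapply(report$step2, result_to_list),
    config = report$config[c("alpha", "n_perm", "k_max", "seed",
                             "perm_scheme", "retention")]
  )
  json_path <- paste0(path, ".json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")

  tsv_path <- paste0(path, "_summary.tsv")
  if (length(report$significant_outcomes) == 0) {
    writeLines("no significant step-1 models", tsv_path)
  } else {
    reg <- variable_registry()
    role_of <- stats::setNames(reg$role, reg$name)
    src <- if (!is.null(report$step2)) report$step2 else
      report$step1[report$significant_outcomes]
    rows <- c("exteroceptive", "physiological", "interoceptive")
    tab <- sapply(names(src), function(o) {
      sig <- names(src[[o]]$weights)[src[[o]]$significant]
      vapply(rows, function(rr) {
        paste(sig[role_of[sig] == rr], collapse = ", ")
      }, character(1))
    })
    tab <- matrix(tab, nrow = length(rows),
                  dimnames = list(rows, names(src)))
    utils::write.table(data.frame(dimension = rows, tab,
                                  check.names = FALSE),
                       tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(c(json = json_path, summary = tsv_path))
}

#' Read back a JSON two-step report
#' @param json_path path written by [write_report()].
#' @export
read_report <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}

#' @export
print.two_step_report <- function(x, ...) {
  cat("Two-step PLSR report\n")
  cat("  step 1: ", length(x$step1), " models; significant: ",
      if (length(x$significant_outcomes))
        paste(x$significant_outcomes, collapse = ", ") else "(none)",
      "\n", sep = "")
  cat("  retained predictors: ",
      if (length(x$retained_predictors))
        paste(x$retained_predictors, collapse = ", ") else "(none)",
      "\n", sep = "")
  if (!is.null(x$step2)) {
    for (o in names(x$step2)) {
      m <- x$step2[[o]]
      cat(sprintf("  step 2 [%s]: r = %.3f, p = %.4g\n", o, m$r, m$p_perm))
    }
  } else {
    cat("  step 2: not run\n")
  }
  invisible(x)
}
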