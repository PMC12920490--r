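#!/usr/bin/env Rscript
# Run the two-step PLSR procedure on the simulated cohort: eight
# interoceptive-only models with nested leave-one-out CV and permutation
# inference, retention of significant interoceptive predictors, then
# augmented models adding the 14 exteroceptive measures for the significant
# outcomes. Writes the JSON report and the dimension-by-outcome summary.

library(bodysense)

if (!file.exists("results/cohort.csv")) {
  stop("run analysis/01_simulate_cohort.R first")
}
cohort <- read.csv("results/cohort.csv", check.names = FALSE)

cfg <- two_step_config(alpha = 0.05, n_perm = 1000, k_max = 10,
                       seed = 20260923)
report <- run_two_step(cohort, cfg)

print(report)
cat("\nstep-1 fit statistics:\n")
for (o in names(report$step1)) {
  m <- report$step1[[o]]
  cat(sprintf("  %-28s r = %5.2f  p = %.4g%s\n", o, m$r, m$p_perm,
              if (o %in% report$significant_outcomes) "  *" else ""))
}
if (!is.null(report$step2)) {
  cat("\nstep-2 significant predictors:\n")
  for (o in names(report$step2)) {
    m <- report$step2[[o]]
    cat(sprintf("  %-28s r = %5.2f  [%s]\n", o, m$r,
                paste(names(m$weights)[m$significant], collapse = ", ")))
  }
}

paths <- write_report(report, "results/two_step")
cat("\nwrote", paths["json"], "and", paths["summary"], "\n")
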