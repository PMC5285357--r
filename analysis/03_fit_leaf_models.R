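#!/usr/bin/env Rscript
# Step 3: parameterize, calibrate and test the leaf-area models.
#
# The staged workflow: genotype grouping tests on the slope ratio
# TLA/(nl*Amax), 2/3-1/3 train/test split, through-origin beta fits, scale
# parameters from the arctan closed form, per-genotype k fits, alpha
# calibration on the training shoots, and evaluation on the held-out third.

library(shootallom)

leaves <- read_leaf_table("results/data/leaves.csv")
fit <- run_parameterization(leaves, pipeline_config(seed = 1L))

dir.create("results", showWarnings = FALSE)
write_params(fit$params, "results/params.json")
write.csv(fit$report, "results/tables/fit_report.csv", row.names = FALSE)

print(fit)

gt <- fit$grouping_tests
for (st in names(gt)) {
  if (is.null(gt[[st]])) next
  cat(sprintf(
    "grouping test (%s): %s p = %.3g -> %s\n", st, gt[[st]]$method,
    gt[[st]]$p_value,
    if (gt[[st]]$pool) "pool all genotypes"
    else paste(sapply(gt[[st]]$pooled_groups, paste, collapse = "+"),
               collapse = " | ")))
}

tst <- fit$report[fit$report$stage == "test_TLA", ]
cat(sprintf("held-out totals: slope %.2f-%.2f, R2 %.2f-%.2f across %d models\n",
            min(tst$slope), max(tst$slope), min(tst$r2), max(tst$r2), nrow(tst)))
cat("parameters written to results/params.json\n")
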