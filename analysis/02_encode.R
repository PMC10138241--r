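#!/usr/bin/env Rscript
# Encode the cohort into the [0,1] matrix the Auto-CM trains on: each
# questionnaire class becomes a 0/1 indicator node (both outcomes kept),
# each continuous assay is min-max scaled on its observed range, and
# constant columns (vanadium, never detected) are dropped.

suppressPackageStartupMessages(library(autocmap))

cohort <- read_cohort("results/cohort.csv", "results/schema.yml")
em <- withCallingHandlers(
  encode_cohort(cohort),
  warning = function(w) {
    cat("note:", conditionMessage(w), "\n")
    invokeRestart("muffleWarning")
  })
write_encoded(em, "results/encoded.csv")

cat(sprintf("encoded %d records x %d nodes (dropped: %s)\n",
            length(em$records), length(em$nodes),
            if (length(em$dropped)) paste(em$dropped, collapse = ", ")
            else "none"))
cat(sprintf("all values in [%.3f, %.3f]\n", min(em$values), max(em$values)))
cat("wrote results/encoded.csv (+ .provenance.yml)\n")
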