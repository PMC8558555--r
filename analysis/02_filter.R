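#!/usr/bin/env Rscript
# Stage 2: somatic filter cascade.
#
# Reads the cohort call table, applies the five-rule filter (high-quality
# read support, population AF, synonymous, minimum VAF, matched blood /
# normal subtraction) per tumor-derived specimen, and writes the retained
# calls plus a per-specimen filter report.

library(stromaclone)

calls <- read_calls("results/cohort/calls.tsv")
clinical <- read.csv("results/cohort/clinical.csv")
filtered <- filter_cohort(calls, tcf_table = clinical)

retained <- do.call(rbind, lapply(filtered, function(x) x$profile$calls))
rownames(retained) <- NULL
write_calls_tsv(retained, "results/retained_calls.tsv")

report <- lapply(filtered, function(x)
  c(as.list(x$report$removed), list(retained = x$report$retained)))
jsonlite::write_json(report, "results/filter_report.json",
                     auto_unbox = TRUE, digits = NA)

removed <- sum(vapply(filtered, function(x) sum(x$report$removed), numeric(1)))
cat("Input calls (stroma+neoplasm):",
    sum(vapply(filtered, function(x) x$report$input, numeric(1))), "\n")
cat("Removed by the cascade:", removed, " retained:", nrow(retained), "\n")
cat("Rule attribution totals:\n")
print(Reduce(`+`, lapply(filtered, function(x) x$report$removed)))
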