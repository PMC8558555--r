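#!/usr/bin/env Rscript
# Stage 3: clonality analysis.
#
# For every patient: specimen-normalized VAFs with the >= 0.5 clonality
# rule, the shared / stroma-specific / neoplasm-specific partition, and
# binomial-mixture clone clusters for the neoplastic component
# (purity = TCF). Writes a per-mutation table and per-patient cluster
# summaries.

library(stromaclone)

retained <- read_calls("results/retained_calls.tsv")
clinical <- read.csv("results/cohort/clinical.csv")
genes <- driver_gene_list()

per_mut <- list()
cluster_summ <- list()
for (pid in unique(retained$patient_id)) {
  neo <- retained[retained$patient_id == pid & retained$component == "neoplasm", ]
  str_ <- retained[retained$patient_id == pid & retained$component == "stroma", ]
  if (nrow(neo) == 0) next
  part <- partition_mutations(str_, neo)
  tcf <- clinical$tcf[match(pid, clinical$patient_id)]
  purity <- if (is.na(tcf) || tcf <= 0) 1 else tcf
  fit <- cluster_clones(neo, purity = purity, seed = 1)
  drv <- classify_driver_events(neo, genes, warn_unscorable = FALSE)

  for (comp in c("stroma", "neoplasm")) {
    tab <- if (comp == "stroma") str_ else neo
    if (nrow(tab) == 0) next
    nv <- normalize_vafs(tab)
    nv$patient_id <- pid
    nv$component <- comp
    nv$partition <- ifelse(nv$key %in% part$shared, "shared",
                    ifelse(nv$key %in% part$stroma_specific,
                           "stroma_specific", "neoplasm_specific"))
    nv$cluster <- if (comp == "neoplasm") fit$assignment[match(nv$key, fit$keys)]
                  else NA_integer_
    nv$driver_event <- nv$key %in% drv$key[drv$is_driver_event]
    per_mut[[paste(pid, comp)]] <- nv
  }
  cl <- fit$clusters
  cl$patient_id <- pid
  cluster_summ[[pid]] <- cl
}

per_mut <- do.call(rbind, per_mut)
rownames(per_mut) <- NULL
write.table(per_mut, "results/clonality.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(cluster_summ, "results/clone_clusters.json",
                     auto_unbox = TRUE, digits = NA)

sh <- per_mut[per_mut$component == "stroma" & per_mut$partition == "shared", ]
cat("Mutations analyzed:", nrow(per_mut), "rows (specimen x mutation).\n")
cat(sprintf("Shared mutations clonal in stroma: %d/%d (%.1f%%)\n",
            sum(sh$clonal), nrow(sh), 100 * mean(sh$clonal)))
ns <- per_mut[per_mut$partition == "neoplasm_specific" &
                per_mut$component == "neoplasm", ]
cat(sprintf("Neoplasm-specific mutations clonal: %d/%d (%.1f%%)\n",
            sum(ns$clonal), nrow(ns), 100 * mean(ns$clonal)))
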