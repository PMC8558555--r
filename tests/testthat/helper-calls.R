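# Build a small MutationCall table with sensible defaults; every argument
# is recycled to the longest length.
make_calls <- function(patient_id = "P01", component = "neoplasm",
                       chrom = "1", pos = NULL, ref = "A", alt = "T",
                       gene = "TTN", protein_change = "p.X1",
                       effect = "missense", hq_alt_reads = 400L,
                       depth = 1000L, vaf = NULL, pop_af_max = 0,
                       polyphen = 0.2, sift = 0.5, copy_number = 2L) {
  n <- max(lengths(list(patient_id, component, chrom, pos, ref, alt, gene,
                        effect, hq_alt_reads, depth, vaf, polyphen, sift)))
  if (is.null(pos)) pos <- seq_len(n) * 100L
  df <- data.frame(
    patient_id = rep_len(patient_id, n),
    specimen_id = paste(rep_len(patient_id, n), rep_len(component, n), sep = "_"),
    component = rep_len(component, n),
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gene = rep_len(gene, n), protein_change = rep_len(protein_change, n),
    effect = rep_len(effect, n),
    hq_alt_reads = rep_len(as.integer(hq_alt_reads), n),
    depth = rep_len(as.integer(depth), n),
    vaf = NA_real_,
    pop_af_max = rep_len(pop_af_max, n),
    polyphen = rep_len(polyphen, n), sift = rep_len(sift, n),
    copy_number = rep_len(as.integer(copy_number), n),
    stringsAsFactors = FALSE
  )
  df$vaf <- if (is.null(vaf)) df$hq_alt_reads / df$depth else rep_len(vaf, n)
  df
}

# Shared/clonality bookkeeping over the landmark fixture, reused by several
# test files and computed once per session.
fixture_summary <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- landmark_cohort()
    genes <- driver_gene_list()
    shared_total <- 0L; shared_clonal_stroma <- 0L; both_clonal <- 0L
    nspec_total <- 0L; nspec_clonal <- 0L
    shared_drivers <- 0L; sspec_drivers <- 0L; nspec_drivers <- 0L
    for (p in unique(fx$neoplasm$patient_id)) {
      s <- fx$stroma[fx$stroma$patient_id == p, ]
      n <- fx$neoplasm[fx$neoplasm$patient_id == p, ]
      part <- partition_mutations(s, n)
      drv <- classify_driver_events(n, genes, warn_unscorable = FALSE)
      nv_n <- normalize_vafs(n)
      if (nrow(s) > 0) {
        nv_s <- normalize_vafs(s)
        sh <- nv_s$key %in% part$shared
        shared_total <- shared_total + sum(sh)
        shared_clonal_stroma <- shared_clonal_stroma + sum(nv_s$clonal[sh])
        bc <- nv_s$key[sh & nv_s$clonal]
        both_clonal <- both_clonal + sum(nv_n$clonal[nv_n$key %in% bc])
        sdrv <- classify_driver_events(s, genes, warn_unscorable = FALSE)
        sspec_drivers <- sspec_drivers +
          sum(sdrv$is_driver_event & sdrv$key %in% part$stroma_specific)
      }
      ns <- nv_n$key %in% part$neoplasm_specific
      nspec_total <- nspec_total + sum(ns)
      nspec_clonal <- nspec_clonal + sum(nv_n$clonal[ns])
      shared_drivers <- shared_drivers +
        sum(drv$is_driver_event & drv$key %in% part$shared)
      nspec_drivers <- nspec_drivers +
        sum(drv$is_driver_event & drv$key %in% part$neoplasm_specific)
    }
    cache <<- list(
      fx = fx,
      shared_total = shared_total,
      shared_clonal_stroma = shared_clonal_stroma,
      both_clonal = both_clonal,
      nspec_total = nspec_total,
      nspec_clonal = nspec_clonal,
      shared_drivers = shared_drivers,
      sspec_drivers = sspec_drivers,
      nspec_drivers = nspec_drivers
    )
    cache
  }
})
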