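## Somatic filter cascade.
##
## Five rules, applied in a fixed order with first-match attribution:
##   1. fewer than five high-quality supporting reads
##   2. population allele frequency above 1% (cross-contamination / SNP)
##   3. synonymous effect
##   4. VAF below 1% (strict <)
##   5. present (same chrom,pos,ref,alt) in matched blood or normal tissue

filter_rules <- c("min_hq_reads", "pop_af", "synonymous", "min_vaf",
                  "matched_normal")

#' Apply the five-rule somatic filter cascade to one specimen
#'
#' Rules are evaluated in the fixed order above; a call failing several
#' rules is attributed to the first. Matched-normal subtraction keys on the
#' exact `(chrom, pos, ref, alt)` tuple, with no positional fuzziness. The
#' cascade is idempotent and the retained set does not depend on the input
#' row order.
#'
#' @param calls data.frame of mutation calls for a single specimen.
#' @param matched_normal,matched_blood Optional [specimen_profile()]s (or
#'   raw call data.frames) whose variant keys are subtracted by rule 5.
#' @param pop_af_cutoff Population-AF threshold (rule 2, strict `>`).
#' @param min_hq_reads Minimum high-quality alt reads (rule 1; fewer are
#'   removed).
#' @param min_vaf VAF threshold (rule 4; strictly lower is removed).
#' @param tcf Tumor cell fraction recorded on the resulting profile.
#' @return list with `profile` (a [specimen_profile()] of retained calls)
#'   and `report` (per-rule removal counts, retained count, and the
#'   per-mutation fate label).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 1, seed = 7))
#' neo <- sim$calls[sim$calls$component == "neoplasm", ]
#' blood <- sim$calls[sim$calls$component == "blood", ]
#' res <- apply_filters(neo, matched_blood = blood)
#' res$report$removed
apply_filters <- function(calls, matched_normal = NULL, matched_blood = NULL,
                          pop_af_cutoff = 0.01, min_hq_reads = 5,
                          min_vaf = 0.01, tcf = NA_real_) {
  if (nrow(calls) > 0 && length(unique(calls$specimen_id)) > 1) {
    stop("apply_filters expects calls from a single specimen")
  }
  as_calls <- function(x) {
    if (is.null(x)) return(empty_calls())
    if (inherits(x, "specimen_profile")) x$calls else x
  }
  subtract_keys <- unique(c(mutation_key(as_calls(matched_normal)),
                            mutation_key(as_calls(matched_blood))))

  n <- nrow(calls)
  fate <- rep("retained", n)
  if (n > 0) {
    keys <- mutation_key(calls)
    checks <- list(
      min_hq_reads  = calls$hq_alt_reads < min_hq_reads,
      pop_af        = !is.na(calls$pop_af_max) & calls$pop_af_max > pop_af_cutoff,
      synonymous    = calls$effect == "synonymous",
      min_vaf       = calls$vaf < min_vaf,
      matched_normal = keys %in% subtract_keys
    )
    for (rule in filter_rules) {
      hit <- checks[[rule]] & fate == "retained"
      fate[hit] <- rule
    }
  }

  retained <- calls[fate == "retained", , drop = FALSE]
  rownames(retained) <- NULL
  removed <- vapply(filter_rules, function(r) sum(fate == r), integer(1))
  report <- list(
    input = n,
    removed = removed,
    retained = nrow(retained),
    fate = fate
  )
  stopifnot(sum(removed) + report$retained == n)
  list(profile = specimen_profile(retained, tcf = tcf), report = report)
}

#' Filter every specimen of a cohort with matched subtraction
#'
#' Convenience wrapper: splits a cohort call table by specimen, pairs each
#' tumor-derived specimen (stroma, neoplasm) with the patient's blood and
#' normal-tissue calls, and applies [apply_filters()].
#'
#' @param calls Cohort-wide mutation call table.
#' @param tcf_table Optional data.frame with `patient_id` and `tcf`.
#' @param ... Passed to [apply_filters()].
#' @return Named list (by specimen id) of `apply_filters()` results for the
#'   stroma and neoplasm specimens.
#' @export
filter_cohort <- function(calls, tcf_table = NULL, ...) {
  out <- list()
  for (pid in unique(calls$patient_id)) {
    pc <- calls[calls$patient_id == pid, , drop = FALSE]
    normal <- pc[pc$component == "normal", , drop = FALSE]
    blood <- pc[pc$component == "blood", , drop = FALSE]
    tcf <- NA_real_
    if (!is.null(tcf_table) && pid %in% tcf_table$patient_id) {
      tcf <- tcf_table$tcf[match(pid, tcf_table$patient_id)]
    }
    for (comp in c("stroma", "neoplasm")) {
      sub <- pc[pc$component == comp, , drop = FALSE]
      if (nrow(sub) == 0 && comp == "neoplasm") next
      res <- apply_filters(sub, matched_normal = normal,
                           matched_blood = blood, tcf = tcf, ...)
      out[[paste(pid, comp, sep = "_")]] <- res
    }
  }
  out
}
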