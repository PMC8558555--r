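## Evolutionary subtyping of paired stroma/neoplasm profiles.
##
## Neoplastic clone clusters, ordered by mean CCF (trunk first), are
## checked for stromal presence via the shared-mutation partition; each
## patient is then assigned one of four subtypes by an ordered predicate
## cascade:
##   C: no neoplastic mutation in stroma at all;
##   A: every neoplastic clone present in stroma and every neoplastic
##      driver event shared;
##   B: trunk present, at least one driver shared, and every trunk driver
##      shared (but not A);
##   D: everything else (trunk absent with a later clone present, or trunk
##      present without any shared driver).
## A and B together define neoplasm-like stroma.

#' Stromal presence of one neoplastic clone cluster
#'
#' A cluster counts as present in stroma when at least `presence_fraction`
#' of its member mutations are in the shared partition (inclusive
#' comparison). The threshold operationalizes "clone identified in stroma"
#' and is exposed because no canonical value exists.
#'
#' @param member_keys Mutation keys of the cluster (neoplastic component).
#' @param partition A [partition_mutations()] result.
#' @param presence_fraction Minimum shared fraction, default 0.5.
#' @return Single logical.
#' @export
clone_presence_in_stroma <- function(member_keys, partition,
                                     presence_fraction = 0.5) {
  stopifnot(length(member_keys) > 0)
  mean(member_keys %in% partition$shared) >= presence_fraction
}

#' Build the clonal trajectory of a patient's neoplasm
#'
#' Wraps a [cluster_clones()] fit into an ordered trajectory: clusters by
#' mean neoplastic CCF descending (the fit's ranking), each with its member
#' keys, driver events and stromal presence flag.
#'
#' @param clusters A [cluster_clones()] fit on the neoplastic profile.
#' @param partition A [partition_mutations()] result for the patient.
#' @param driver_calls [classify_driver_events()] output for the neoplastic
#'   profile.
#' @param presence_fraction Passed to [clone_presence_in_stroma()].
#' @return Object of class `trajectory`: list of per-cluster records
#'   (`cluster`, `mean_ccf`, `keys`, `driver_keys`, `present_in_stroma`),
#'   trunk = first.
#' @export
build_trajectory <- function(clusters, partition, driver_calls,
                             presence_fraction = 0.5) {
  driver_keys <- driver_calls$key[driver_calls$is_driver_event]
  records <- lapply(seq_len(clusters$K), function(k) {
    keys <- clusters$keys[clusters$assignment == k]
    list(
      cluster = k,
      mean_ccf = clusters$clusters$mean_ccf[k],
      keys = keys,
      driver_keys = intersect(keys, driver_keys),
      present_in_stroma = clone_presence_in_stroma(keys, partition,
                                                   presence_fraction)
    )
  })
  structure(list(clusters = records, driver_keys = driver_keys,
                 patient_id = partition$patient_id),
            class = "trajectory")
}

#' Assign a patient's evolutionary subtype
#'
#' Predicates are evaluated in the order C, A, B, D, which makes them
#' mutually exclusive and exhaustive for any patient with at least one
#' neoplastic mutation.
#'
#' @param trajectory A [build_trajectory()] result.
#' @param partition The patient's [partition_mutations()] result.
#' @return Object of class `subtype_call`: `patient_id`, `subtype`,
#'   `neoplasm_like` (subtype A or B).
#' @export
assign_subtype <- function(trajectory, partition) {
  if (length(trajectory$clusters) == 0) {
    stop("patient has no neoplastic mutations; exclude upstream")
  }
  shared <- partition$shared
  present <- vapply(trajectory$clusters, `[[`, logical(1), "present_in_stroma")
  trunk <- trajectory$clusters[[1]]
  all_drivers_shared <- all(trajectory$driver_keys %in% shared)
  trunk_drivers_shared <- all(trunk$driver_keys %in% shared)
  any_driver_shared <- any(trajectory$driver_keys %in% shared)

  subtype <- if (length(shared) == 0) {
    "C"
  } else if (all(present) && all_drivers_shared) {
    "A"
  } else if (present[1] && any_driver_shared && trunk_drivers_shared) {
    "B"
  } else {
    "D"
  }
  structure(list(
    patient_id = trajectory$patient_id,
    subtype = subtype,
    neoplasm_like = subtype %in% c("A", "B")
  ), class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("<subtype_call> %s: type %s%s\n", x$patient_id, x$subtype,
              if (x$neoplasm_like) " (neoplasm-like stroma)" else ""))
  invisible(x)
}

#' Per-gene mutation status of a stromal profile
#'
#' @param stroma [specimen_profile()] (or call data.frame) of retained
#'   stromal mutations.
#' @param genes Gene symbols to flag (default KRAS and TP53).
#' @return Named logical vector: `TRUE` iff at least one retained stromal
#'   mutation lies in the gene (any distinct mutation counts).
#' @export
stromal_gene_status <- function(stroma, genes = c("KRAS", "TP53")) {
  calls <- if (inherits(stroma, "specimen_profile")) stroma$calls else stroma
  present <- toupper(genes) %in% toupper(calls$gene)
  stats::setNames(present, genes)
}

#' Run the per-patient pipeline: partition, cluster, subtype
#'
#' Convenience wrapper gluing the clonality and subtyping stages for one
#' patient with both components filtered: partitions mutations, clusters
#' the neoplastic component (purity = TCF when available), annotates
#' drivers, and assigns the subtype plus stromal gene flags.
#'
#' @param stroma,neoplasm Filtered [specimen_profile()]s.
#' @param genes Driver gene list for [classify_driver_events()].
#' @param purity Neoplastic purity; defaults to the neoplasm profile's TCF,
#'   or 1 when unknown.
#' @param max_clusters,seed,presence_fraction Tuning knobs passed through.
#' @return One-row data.frame: `patient_id`, `subtype`, `neoplasm_like`,
#'   `stromal_kras`, `stromal_tp53`, `stromal_any`, `n_shared`,
#'   `n_stroma_specific`, `n_neoplasm_specific`, `n_clusters`.
#' @export
subtype_patient <- function(stroma, neoplasm, genes = driver_gene_list(),
                            purity = NULL, max_clusters = 6, seed = 1,
                            presence_fraction = 0.5) {
  if (nrow(neoplasm$calls) == 0) {
    stop("patient ", stroma$patient_id, " has no retained neoplastic mutations")
  }
  if (is.null(purity)) {
    purity <- if (!is.na(neoplasm$tcf) && neoplasm$tcf > 0) neoplasm$tcf else 1
  }
  partition <- partition_mutations(stroma, neoplasm)
  clusters <- cluster_clones(neoplasm, purity = purity,
                             max_clusters = max_clusters, seed = seed)
  drivers <- classify_driver_events(neoplasm, genes, warn_unscorable = FALSE)
  traj <- build_trajectory(clusters, partition, drivers, presence_fraction)
  call <- assign_subtype(traj, partition)
  status <- stromal_gene_status(stroma)
  data.frame(
    patient_id = call$patient_id,
    subtype = call$subtype,
    neoplasm_like = call$neoplasm_like,
    stromal_kras = unname(status["KRAS"]),
    stromal_tp53 = unname(status["TP53"]),
    stromal_any = nrow(stroma$calls) > 0,
    n_shared = length(partition$shared),
    n_stroma_specific = length(partition$stroma_specific),
    n_neoplasm_specific = length(partition$neoplasm_specific),
    n_clusters = clusters$K,
    stringsAsFactors = FALSE
  )
}
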