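## End-to-end cohort pipeline and ground-truth recovery experiments.

#' Run the full pipeline over a cohort call table
#'
#' Filters every specimen (matched blood/normal subtraction included),
#' then, per patient with at least one retained neoplastic mutation,
#' partitions mutations, clusters the neoplastic component (purity = TCF
#' where available), and assigns the evolutionary subtype and stromal gene
#' flags.
#'
#' @param calls Cohort-wide mutation call table (all components).
#' @param clinical Optional clinical table with `patient_id` and `tcf`.
#' @param genes Driver gene list.
#' @param seed Base seed for the per-patient clustering restarts.
#' @param presence_fraction Passed to [clone_presence_in_stroma()].
#' @param max_clusters Passed to [cluster_clones()].
#' @return list with `subtypes` (one row per analyzable patient) and
#'   `profiles` (the filtered [specimen_profile()]s and filter reports,
#'   named `<patient>_<component>`).
#' @export
analyze_cohort <- function(calls, clinical = NULL, genes = driver_gene_list(),
                           seed = 1, presence_fraction = 0.5,
                           max_clusters = 6) {
  filtered <- filter_cohort(calls, tcf_table = clinical)
  pids <- unique(calls$patient_id)
  out <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    neo <- filtered[[paste0(pid, "_neoplasm")]]
    if (is.null(neo) || nrow(neo$profile$calls) == 0) next
    str_res <- filtered[[paste0(pid, "_stroma")]]
    stroma <- if (is.null(str_res)) specimen_profile(empty_calls())
              else str_res$profile
    if (nrow(stroma$calls) == 0) {
      stroma$patient_id <- pid
      stroma$component <- "stroma"
    }
    out[[pid]] <- subtype_patient(stroma, neo$profile, genes = genes,
                                  seed = seed + i,
                                  presence_fraction = presence_fraction,
                                  max_clusters = max_clusters)
  }
  list(subtypes = do.call(rbind, out), profiles = filtered)
}

#' Subtype recovery experiment on a synthetic cohort
#'
#' Simulates a cohort with a known subtype per patient, runs the full
#' downstream pipeline (filtering, partition, clustering, subtyping) and
#' compares calls with the generator's truth.
#'
#' @param n_patients Cohort size.
#' @param seed Top-level seed.
#' @param subtype_mix Probability vector over (A, B, C, D).
#' @param ... Further arguments to [sim_config()].
#' @return list with `accuracy` (fraction of patients whose called subtype
#'   equals the target), `confusion` (truth x call table), `n`, and the
#'   merged per-patient data.frame.
#' @export
subtype_recovery <- function(n_patients = 500, seed = 1,
                             subtype_mix = c(A = 0.25, B = 0.25,
                                             C = 0.25, D = 0.25), ...) {
  cfg <- sim_config(n_patients = n_patients, subtype_mix = subtype_mix,
                    seed = seed, ...)
  sim <- simulate_cohort(cfg)
  res <- analyze_cohort(sim$calls, clinical = sim$clinical, seed = seed)
  truth <- data.frame(
    patient_id = names(sim$truth),
    true_subtype = vapply(sim$truth, `[[`, character(1), "subtype"),
    stringsAsFactors = FALSE
  )
  merged <- merge(truth, res$subtypes, by = "patient_id")
  acc <- mean(merged$subtype == merged$true_subtype)
  list(accuracy = acc,
       confusion = table(truth = merged$true_subtype, call = merged$subtype),
       n = nrow(merged),
       per_patient = merged)
}

#' Hazard-ratio recovery experiment
#'
#' Repeatedly simulates clinical records with a known neoplasm-like hazard
#' ratio and fits the univariate Cox model, recording the estimate and
#' whether the Wald 95% CI covers the truth.
#'
#' @param true_hr The simulated hazard ratio.
#' @param n Patients per replicate.
#' @param replicates Number of replicates.
#' @param seed Top-level seed.
#' @param prevalence Fraction of neoplasm-like patients per replicate.
#' @param ... Further arguments to [sim_config()].
#' @return list with `estimates` (vector of HR estimates), `mean_hr`,
#'   `coverage` (fraction of CIs covering `true_hr`).
#' @export
hr_recovery <- function(true_hr = 3.0, n = 200, replicates = 100, seed = 1,
                        prevalence = 0.5, ...) {
  cfg <- sim_config(n_patients = n, neoplasm_like_hazard_ratio = true_hr,
                    seed = seed, ...)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  est <- numeric(replicates)
  covered <- logical(replicates)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    nl <- stats::runif(n) < prevalence
    truth_tab <- data.frame(
      patient_id = sprintf("R%03d", seq_len(n)),
      neoplasm_like = nl,
      stromal_kras = nl,   # neoplasm-like stroma carries KRAS/TP53 drivers
      stromal_tp53 = nl,
      stringsAsFactors = FALSE
    )
    clin <- simulate_clinical(truth_tab, cfg, seed = rep_seeds[r] %% 1000000L + 1L)
    clin$neoplasm_like <- nl
    sr <- survival_analysis(clin, grouping = "neoplasm_like")
    est[r] <- sr$hazard_ratio
    covered[r] <- sr$ci_lower <= true_hr && true_hr <= sr$ci_upper
  }
  list(estimates = est, mean_hr = mean(est), coverage = mean(covered))
}

#' Truncal clonality calibration experiment
#'
#' Simulates cohorts at the configured depth and measures how often
#' mutations that are truly truncal (clone with neoplastic CCF 1) are
#' called clonal by the normalized-VAF rule in the filtered neoplastic
#' profile.
#'
#' @param n_patients Cohort size.
#' @param seed Top-level seed.
#' @param ... Further arguments to [sim_config()].
#' @return list with `rate` (fraction of truncal mutations called clonal)
#'   and `n_truncal`.
#' @export
truncal_clonality_calibration <- function(n_patients = 100, seed = 1, ...) {
  cfg <- sim_config(n_patients = n_patients, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  filtered <- filter_cohort(sim$calls, tcf_table = sim$clinical)
  hits <- 0L
  total <- 0L
  for (pid in names(sim$truth)) {
    truth <- sim$truth[[pid]]
    res <- filtered[[paste0(pid, "_neoplasm")]]
    if (is.null(res) || nrow(res$profile$calls) == 0) next
    nv <- normalize_vafs(res$profile)
    truncal_clone <- which(truth$ccf_neoplasm >= 1)[1]
    muts <- truth$mutations
    truncal_keys <- paste(muts$chrom, muts$pos, muts$ref, muts$alt, sep = ":")
    truncal_keys <- truncal_keys[muts$clone == truncal_clone]
    idx <- nv$key %in% truncal_keys
    hits <- hits + sum(nv$clonal[idx])
    total <- total + sum(idx)
  }
  list(rate = hits / total, n_truncal = total)
}
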