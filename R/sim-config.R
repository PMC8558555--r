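#' Simulation configuration for the synthetic paired cohort
#'
#' Bundles and validates every tunable of the synthetic stroma/neoplasm
#' cohort generator. Defaults emulate a resectable-PDAC targeted-sequencing
#' cohort: ~1000x mean depth, 2-5 clones per tumor, KRAS/TP53-dominated
#' truncal drivers, a subtype mix dominated by neoplasm-like (A/B) stroma,
#' and exponential disease-free survival with a 3-fold hazard for
#' neoplasm-like patients.
#'
#' @param n_patients Number of patients to simulate.
#' @param clone_count_range Integer length-2 vector, inclusive bounds on the
#'   number of neoplastic clones per patient (trunk included).
#' @param trunk_driver_probs Named numeric vector of per-gene probabilities
#'   that the trunk carries a hotspot/truncating driver of that gene.
#'   Supported genes: KRAS, TP53, CDKN2A, SMAD4.
#' @param passengers_per_clone Poisson mean for passenger mutations carried
#'   by each clone.
#' @param subclonal_driver_prob Probability that a non-trunk clone acquires
#'   a subclonal driver (RNF43/ARID1A/GNAS/KDM6A/TGFBR2).
#' @param subtype_mix Probability vector over evolutionary subtypes
#'   (A, B, C, D); must sum to 1. Default follows the observed cohort
#'   proportions 12:20:5:2 among stroma-informative patients.
#' @param stroma_private_rate Poisson mean for stroma-private mutations per
#'   patient (divergent stromal evolution).
#' @param germline_rate Poisson mean for germline variants per patient;
#'   these appear in blood, normal tissue and both tumor components and are
#'   the substrate of the matched-normal subtraction filter.
#' @param mean_depth Mean sequencing depth per variant (reads).
#' @param depth_dispersion Negative-binomial size parameter for depth;
#'   the default reproduces a roughly 360-1700x depth range at mean 1000.
#' @param tcf_beta List with elements `mutant` and `wildtype`, each a
#'   length-2 Beta(shape1, shape2) parameter vector for the tumor cell
#'   fraction of patients with / without neoplasm-derived stromal mutations.
#' @param stroma_neoplastic_fraction Fraction of stromal cellularity
#'   occupied by neoplasm-derived (EMT) cells; scales stromal VAFs. The
#'   underlying quantity is not observable by microimaging, so it is a free
#'   simulation parameter.
#' @param baseline_hazard Relapse hazard per month for patients without
#'   neoplasm-like stroma.
#' @param neoplasm_like_hazard_ratio Hazard multiplier for neoplasm-like
#'   (subtype A/B) patients.
#' @param censoring_horizon Administrative censoring time, months.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 4, seed = 1)
#' cfg$mean_depth
sim_config <- function(n_patients = 50,
                       clone_count_range = c(2L, 5L),
                       trunk_driver_probs = c(KRAS = 0.94, TP53 = 0.86,
                                              CDKN2A = 0.24, SMAD4 = 0.18),
                       passengers_per_clone = 4,
                       subclonal_driver_prob = 0.15,
                       subtype_mix = c(A = 12, B = 20, C = 5, D = 2) / 39,
                       stroma_private_rate = 0.33,
                       germline_rate = 2,
                       mean_depth = 1000,
                       depth_dispersion = 15,
                       tcf_beta = list(mutant = c(8, 3), wildtype = c(4, 4)),
                       stroma_neoplastic_fraction = 0.5,
                       baseline_hazard = 0.06,
                       neoplasm_like_hazard_ratio = 3.0,
                       censoring_horizon = 30,
                       seed = 1L) {
  stopifnot(is.numeric(n_patients), length(n_patients) == 1, n_patients >= 1)
  clone_count_range <- as.integer(clone_count_range)
  if (length(clone_count_range) != 2L ||
      clone_count_range[1] < 1L ||
      clone_count_range[2] < clone_count_range[1]) {
    stop("clone_count_range must be an increasing integer interval with lower bound >= 1")
  }
  if (any(trunk_driver_probs < 0 | trunk_driver_probs > 1)) {
    stop("trunk_driver_probs must lie in [0, 1]")
  }
  if (is.null(names(trunk_driver_probs)) || any(names(trunk_driver_probs) == "")) {
    stop("trunk_driver_probs must be named by gene")
  }
  if (length(subtype_mix) != 4L) stop("subtype_mix must have 4 entries (A, B, C, D)")
  if (any(subtype_mix < 0)) stop("subtype_mix must be nonnegative")
  if (abs(sum(subtype_mix)) < .Machine$double.eps) stop("subtype_mix sums to 0")
  if (abs(sum(subtype_mix) - 1) > 1e-8) stop("subtype_mix must sum to 1")
  rates <- c(passengers_per_clone, stroma_private_rate, germline_rate,
             mean_depth, depth_dispersion, baseline_hazard,
             neoplasm_like_hazard_ratio, censoring_horizon,
             subclonal_driver_prob, stroma_neoplastic_fraction)
  if (any(rates < 0)) stop("rates, probabilities and scales must be nonnegative")
  if (subclonal_driver_prob > 1 ||
      stroma_neoplastic_fraction > 1) {
    stop("probabilities/fractions must not exceed 1")
  }
  stopifnot(is.list(tcf_beta), all(c("mutant", "wildtype") %in% names(tcf_beta)),
            lengths(tcf_beta[c("mutant", "wildtype")]) == c(2L, 2L))

  structure(list(
    n_patients = as.integer(n_patients),
    clone_count_range = clone_count_range,
    trunk_driver_probs = trunk_driver_probs,
    passengers_per_clone = passengers_per_clone,
    subclonal_driver_prob = subclonal_driver_prob,
    subtype_mix = stats::setNames(as.numeric(subtype_mix), c("A", "B", "C", "D")),
    stroma_private_rate = stroma_private_rate,
    germline_rate = germline_rate,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    tcf_beta = tcf_beta,
    stroma_neoplastic_fraction = stroma_neoplastic_fraction,
    baseline_hazard = baseline_hazard,
    neoplasm_like_hazard_ratio = neoplasm_like_hazard_ratio,
    censoring_horizon = censoring_horizon,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic paired-cohort configuration\n")
  cat(sprintf("  patients: %d, clones per tumor: %d-%d, mean depth: %gx\n",
              x$n_patients, x$clone_count_range[1], x$clone_count_range[2],
              x$mean_depth))
  cat(sprintf("  subtype mix (A,B,C,D): %s\n",
              paste(sprintf("%.3f", x$subtype_mix), collapse = ", ")))
  cat(sprintf("  neoplasm-like hazard ratio: %g, baseline hazard: %g/month\n",
              x$neoplasm_like_hazard_ratio, x$baseline_hazard))
  invisible(x)
}

# Deterministic per-patient substream seeds derived from the top-level seed.
patient_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$n_patients)
}
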