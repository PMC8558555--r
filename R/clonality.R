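## Clonality analysis.
##
## Two clonality routes are computed. The reported clonal/subclonal
## dichotomy uses the specimen-normalized VAF rule (VAF divided by the
## specimen's maximum VAF; >= 0.5 is clonal). Clone structure for
## trajectory reconstruction comes from a seeded hard-assignment EM over
## binomial alt-read counts with BIC model selection, a deterministic
## desk-scale replacement for Dirichlet-process clustering: downstream
## subtype rules only consume cluster membership and mean prevalence.

#' Normalize VAFs within a specimen and call clonal status
#'
#' Each mutation's normalized VAF is its VAF divided by the maximum VAF in
#' the same specimen, so the top mutation always normalizes to 1. A
#' mutation is a clonal event when its normalized VAF is at least 0.5
#' (inclusive).
#'
#' @param profile A [specimen_profile()] or raw call data.frame.
#' @return data.frame with `key`, `gene`, `vaf`, `normalized_vaf`,
#'   `clonal`; zero rows for an empty profile.
#' @export
#' @examples
#' calls <- data.frame(patient_id = "P1", component = "stroma",
#'                     chrom = "1", pos = c(100, 200), ref = "A", alt = "T",
#'                     gene = c("KRAS", "TTN"), vaf = c(0.40, 0.19))
#' normalize_vafs(calls)   # 1.0 (clonal) and 0.475 (subclonal)
normalize_vafs <- function(profile) {
  calls <- if (inherits(profile, "specimen_profile")) profile$calls else profile
  if (nrow(calls) == 0) {
    return(data.frame(key = character(0), gene = character(0),
                      vaf = numeric(0), normalized_vaf = numeric(0),
                      clonal = logical(0), stringsAsFactors = FALSE))
  }
  max_vaf <- max(calls$vaf)
  if (max_vaf <= 0) stop("specimen maximum VAF is not positive")
  nv <- calls$vaf / max_vaf
  data.frame(
    key = mutation_key(calls),
    gene = calls$gene,
    vaf = calls$vaf,
    normalized_vaf = nv,
    clonal = nv >= 0.5,
    stringsAsFactors = FALSE
  )
}

#' Partition a patient's mutations into shared and component-specific sets
#'
#' Mutations are matched across the paired stromal and neoplastic profiles
#' on the exact `(chrom, pos, ref, alt)` key.
#'
#' @param stroma,neoplasm [specimen_profile()]s (or call data.frames) from
#'   the same patient.
#' @return Object of class `shared_partition`: disjoint key sets `shared`,
#'   `stroma_specific`, `neoplasm_specific`.
#' @export
partition_mutations <- function(stroma, neoplasm) {
  s_calls <- if (inherits(stroma, "specimen_profile")) stroma$calls else stroma
  n_calls <- if (inherits(neoplasm, "specimen_profile")) neoplasm$calls else neoplasm
  pids <- unique(c(s_calls$patient_id, n_calls$patient_id))
  pids <- pids[!is.na(pids)]
  if (length(pids) > 1) {
    stop("stroma and neoplasm profiles are from different patients: ",
         paste(pids, collapse = " vs "))
  }
  s_keys <- unique(mutation_key(s_calls))
  n_keys <- unique(mutation_key(n_calls))
  structure(list(
    patient_id = if (length(pids) == 1) pids else NA_character_,
    shared = intersect(s_keys, n_keys),
    stroma_specific = setdiff(s_keys, n_keys),
    neoplasm_specific = setdiff(n_keys, s_keys)
  ), class = "shared_partition")
}

#' @export
print.shared_partition <- function(x, ...) {
  cat(sprintf("<shared_partition> %s: %d shared, %d stroma-specific, %d neoplasm-specific\n",
              x$patient_id, length(x$shared), length(x$stroma_specific),
              length(x$neoplasm_specific)))
  invisible(x)
}

#' Cancer cell fraction from VAF, purity and copy number
#'
#' For a single mutant copy:
#' `CCF = vaf * (purity * CN + (1 - purity) * 2) / purity`,
#' clipped to `[0, 1]` (a warning reports clipping).
#'
#' @param vaf Variant allele frequency vector.
#' @param purity Tumor purity in `(0, 1]`.
#' @param copy_number Local total copy number (default 2).
#' @param mutant_copies Mutant allele copies (default 1).
#' @return CCF vector in `[0, 1]`.
#' @export
#' @examples
#' compute_ccf(0.25, purity = 1)      # 0.5
#' compute_ccf(0.25, purity = 0.5)    # 1.0
compute_ccf <- function(vaf, purity, copy_number = 2, mutant_copies = 1) {
  if (length(purity) != 1 || is.na(purity) || purity <= 0 || purity > 1) {
    stop("purity must be a single value in (0, 1]")
  }
  stopifnot(all(copy_number >= 1))
  ccf <- vaf * (purity * copy_number + (1 - purity) * 2) /
    (purity * mutant_copies)
  if (any(ccf > 1)) {
    warning(sum(ccf > 1), " CCF value(s) above 1 clipped to 1")
  }
  pmin(pmax(ccf, 0), 1)
}

# --- binomial-mixture clone clustering --------------------------------------

# Classification log-likelihood of a hard assignment: cluster success
# probabilities at their (clamped) MLE.
assignment_loglik <- function(alt, depth, assign, p_max) {
  ll <- 0
  for (k in unique(assign)) {
    idx <- assign == k
    p <- min(max(sum(alt[idx]) / sum(depth[idx]), 1e-9), p_max)
    ll <- ll + sum(stats::dbinom(alt[idx], depth[idx], p, log = TRUE))
  }
  ll
}

# One hard-EM run from an initial assignment; returns assignment, cluster
# probabilities and classification log-likelihood.
hard_em <- function(alt, depth, assign, p_max, max_iter = 200) {
  n <- length(alt)
  for (iter in seq_len(max_iter)) {
    ks <- sort(unique(assign))
    p <- vapply(ks, function(k) {
      idx <- assign == k
      min(max(sum(alt[idx]) / sum(depth[idx]), 1e-9), p_max)
    }, numeric(1))
    llmat <- vapply(seq_along(ks), function(j) {
      stats::dbinom(alt, depth, p[j], log = TRUE)
    }, numeric(n))
    llmat <- matrix(llmat, nrow = n)
    new_assign <- ks[max.col(llmat, ties.method = "first")]
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  ks <- sort(unique(assign))
  assign <- match(assign, ks)  # relabel 1..K, drop empty clusters
  p <- vapply(seq_along(ks), function(j) {
    idx <- assign == j
    min(max(sum(alt[idx]) / sum(depth[idx]), 1e-9), p_max)
  }, numeric(1))
  list(assign = assign, p = p, K = length(ks),
       loglik = assignment_loglik(alt, depth, assign, p_max))
}

# Marginal (mixture) log-likelihood of a fitted hard assignment, with
# mixing weights at the cluster proportions; used for model selection,
# where the classification likelihood would over-segment.
mixture_loglik <- function(alt, depth, assign, p) {
  K <- length(p)
  w <- tabulate(assign, nbins = K) / length(alt)
  comp <- vapply(seq_len(K), function(k) {
    log(w[k]) + stats::dbinom(alt, depth, p[k], log = TRUE)
  }, numeric(length(alt)))
  comp <- matrix(comp, nrow = length(alt))
  m <- apply(comp, 1, max)
  sum(m + log(rowSums(exp(comp - m))))
}

# Initial assignments for K clusters: quantile-spread centers, contiguous
# VAF-interval partitions (small n), and seeded jittered center draws.
em_initial_assignments <- function(alt, depth, K, n_restarts) {
  n <- length(alt)
  vaf <- alt / depth
  inits <- list()
  assign_by_centers <- function(centers) {
    d <- abs(outer(vaf, centers, "-"))
    max.col(-d, ties.method = "first")
  }
  centers_q <- stats::quantile(vaf, probs = (seq_len(K) - 0.5) / K,
                               names = FALSE, type = 7)
  inits[[1]] <- assign_by_centers(centers_q)
  if (n <= 12 && K >= 2 && choose(n - 1, K - 1) <= 500) {
    ord <- order(vaf, seq_len(n))
    cuts <- utils::combn(n - 1, K - 1)
    for (j in seq_len(ncol(cuts))) {
      bounds <- c(0, cuts[, j], n)
      a <- integer(n)
      for (k in seq_len(K)) {
        a[ord[(bounds[k] + 1):bounds[k + 1]]] <- k
      }
      inits[[length(inits) + 1]] <- a
    }
  }
  for (r in seq_len(n_restarts)) {
    centers <- sort(stats::runif(K, min(vaf), max(vaf) + 1e-9))
    inits[[length(inits) + 1]] <- assign_by_centers(centers)
  }
  inits
}

#' Cluster a specimen's mutations into clones
#'
#' Fits, for each candidate cluster count `K = 1..max_clusters`, a binomial
#' mixture over high-quality alt-read counts by hard-assignment EM (cluster
#' success probability `p_k = CCF_k * purity / 2` for copy-neutral
#' heterozygous variants), using quantile-spread, contiguous-interval and
#' seeded jittered initializations with the best classification likelihood
#' winning. `K` is then chosen by BIC on the mixture (marginal) likelihood
#' of the fitted components; ties break toward fewer clusters,
#' then lexicographically smaller membership. Clusters are ranked by mean
#' CCF descending (larger cluster first on ties, then first member index);
#' rank 1 is the trunk candidate.
#'
#' @param profile [specimen_profile()] or call data.frame with
#'   `hq_alt_reads` and `depth`.
#' @param purity Specimen purity used to convert success probabilities to
#'   CCFs; stromal specimens default to 1 (no defined stromal purity).
#' @param max_clusters Largest cluster count considered.
#' @param seed Seed for the jittered restarts (restores the caller's RNG
#'   state on exit).
#' @param n_restarts Number of jittered restarts per `K`.
#' @param select `"bic"` (default) or `"fixed_k"`: with `"fixed_k"` the fit
#'   with `K = max_clusters` components (as found by EM; empty clusters may
#'   reduce it) is returned without model selection.
#' @return Object of class `clone_clusters`: `assignment` (cluster rank per
#'   mutation), `clusters` (one row per cluster: `cluster`, `n_members`,
#'   `p`, `mean_ccf`), `loglik`, `K`, `keys`.
#' @export
cluster_clones <- function(profile, purity = 1, max_clusters = 6, seed = 1,
                           n_restarts = 10, select = c("bic", "fixed_k")) {
  select <- match.arg(select)
  calls <- if (inherits(profile, "specimen_profile")) profile$calls else profile
  if (nrow(calls) < 1) stop("cluster_clones needs at least one mutation")
  alt <- calls$hq_alt_reads
  depth <- calls$depth
  n <- length(alt)
  p_max <- purity / 2

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  k_range <- if (select == "fixed_k") max_clusters else seq_len(min(max_clusters, n))
  fits <- list()
  for (K in k_range) {
    K_eff <- min(K, n)
    if (K_eff == 1) {
      fit <- hard_em(alt, depth, rep(1L, n), p_max)
    } else {
      best <- NULL
      for (a0 in em_initial_assignments(alt, depth, K_eff, n_restarts)) {
        f <- hard_em(alt, depth, a0, p_max)
        if (is.null(best) || f$loglik > best$loglik + 1e-9 ||
            (abs(f$loglik - best$loglik) <= 1e-9 && f$K < best$K)) {
          best <- f
        }
      }
      fit <- best
    }
    # BIC on the mixture likelihood (K success probabilities + K - 1
    # weights); the classification likelihood would always reward splits
    mix_ll <- mixture_loglik(alt, depth, fit$assign, fit$p)
    fit$bic <- -2 * mix_ll + (2 * fit$K - 1) * log(n)
    fits[[length(fits) + 1]] <- fit
  }

  if (select == "bic") {
    bics <- vapply(fits, `[[`, numeric(1), "bic")
    ks <- vapply(fits, `[[`, numeric(1), "K")
    ok <- which(bics <= min(bics) + 1e-9)
    pick <- ok[which.min(ks[ok])]   # ties: fewest clusters
    fit <- fits[[pick]]
  } else {
    fit <- fits[[1]]
  }

  # rank clusters: mean CCF descending, larger cluster first, then smallest
  # first-member index (lexicographic membership)
  ccf <- pmin(2 * fit$p / purity, 1)
  sizes <- tabulate(fit$assign, nbins = fit$K)
  first_member <- vapply(seq_len(fit$K), function(k) min(which(fit$assign == k)),
                         integer(1))
  rank_order <- order(-ccf, -sizes, first_member)
  relabel <- match(seq_len(fit$K), rank_order)
  assignment <- relabel[fit$assign]

  clusters <- data.frame(
    cluster = seq_len(fit$K),
    n_members = sizes[rank_order],
    p = fit$p[rank_order],
    mean_ccf = ccf[rank_order]
  )
  structure(list(
    assignment = assignment,
    clusters = clusters,
    loglik = fit$loglik,
    K = fit$K,
    keys = mutation_key(calls),
    purity = purity
  ), class = "clone_clusters")
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("<clone_clusters> K = %d, loglik = %.2f\n", x$K, x$loglik))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Exhaustive-enumeration clustering oracle
#'
#' Brute-force maximizer of the same classification log-likelihood that
#' [cluster_clones()] optimizes: every assignment of `n` mutations to at
#' most `max_clusters` labels is scored with each cluster's success
#' probability at its clamped MLE. Exponential in `n`; intended as an
#' independent reference on small instances.
#'
#' @inheritParams cluster_clones
#' @return list with `loglik` (the global optimum) and `assignment`.
#' @export
brute_force_clusters <- function(profile, purity = 1, max_clusters = 3) {
  calls <- if (inherits(profile, "specimen_profile")) profile$calls else profile
  alt <- calls$hq_alt_reads
  depth <- calls$depth
  n <- length(alt)
  if (n > 10) stop("brute_force_clusters is limited to n <= 10")
  K <- max_clusters
  p_max <- purity / 2

  n_assign <- K^n
  labels <- matrix(0L, nrow = n_assign, ncol = n)
  idx <- 0:(n_assign - 1)
  for (i in seq_len(n)) {
    labels[, i] <- (idx %/% K^(i - 1)) %% K + 1L
  }
  total_ll <- numeric(n_assign)
  ref <- depth - alt
  for (k in seq_len(K)) {
    mk <- labels == k
    sum_alt <- mk %*% alt
    sum_dp <- mk %*% depth
    p <- pmin(pmax(ifelse(sum_dp > 0, sum_alt / sum_dp, 0), 1e-9), p_max)
    # sum of log binomial terms, constants included via lchoose
    lch <- mk %*% lchoose(depth, alt)
    total_ll <- total_ll + ifelse(sum_dp > 0,
                                  lch + sum_alt * log(p) +
                                    (sum_dp - sum_alt) * log1p(-p), 0)
  }
  best <- which.max(total_ll)
  list(loglik = total_ll[best], assignment = labels[best, ])
}
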