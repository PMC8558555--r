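## Synthetic paired stroma/neoplasm cohort generator.
##
## The generator produces, per patient: a neoplastic clone tree (trunk CCF 1,
## stick-breaking subclones), truncal hotspot drivers, Poisson passengers,
## a stromal seeding pattern realizing one of the four evolutionary subtypes
## (A: full concordance; B: trunk + drivers but missing later clones;
## C: no neoplastic mutations in stroma; D: the two discordant archetypes),
## stroma-private mutations, germline variants shared by all four specimens,
## negative-binomial depths with binomial alt counts, and exponential
## disease-free survival with a hazard multiplier for neoplasm-like stroma.

# --- driver / passenger catalogs -------------------------------------------

kras_hotspots <- function() {
  data.frame(
    gene = "KRAS", chrom = "12",
    pos = c(25398285L, 25398284L, 25398286L, 25398283L, 25380276L, 25380275L),
    ref = c("C", "C", "C", "C", "T", "T"),
    alt = c("A", "T", "G", "A", "G", "C"),
    protein_change = c("p.G12C", "p.G12D", "p.G12R", "p.G12V", "p.Q61H", "p.Q61R"),
    effect = "missense",
    weight = c(1, 11, 2, 12, 2, 1),   # observed hotspot spectrum
    stringsAsFactors = FALSE
  )
}

tp53_dbd <- function() {
  data.frame(
    gene = "TP53", chrom = "17",
    pos = c(7578406L, 7577548L, 7577538L, 7577539L, 7577121L, 7577120L, 7577094L),
    ref = c("C", "C", "C", "G", "G", "G", "C"),
    alt = c("T", "T", "T", "A", "A", "T", "T"),
    protein_change = c("p.R175H", "p.G245S", "p.R248Q", "p.R248W",
                       "p.R273C", "p.R273H", "p.R282W"),
    effect = "missense",
    weight = 1,
    stringsAsFactors = FALSE
  )
}

truncating_drivers <- function(gene) {
  switch(gene,
    CDKN2A = data.frame(gene = "CDKN2A", chrom = "9",
                        pos = c(21971120L, 21970916L),
                        ref = c("G", "C"), alt = c("A", "T"),
                        protein_change = c("p.R58*", "p.W110*"),
                        effect = "nonsense", weight = 1,
                        stringsAsFactors = FALSE),
    SMAD4 = data.frame(gene = "SMAD4", chrom = "18",
                       pos = c(48591918L, 48604676L),
                       ref = c("G", "C"), alt = c("A", "T"),
                       protein_change = c("p.W302*", "p.R361*"),
                       effect = "nonsense", weight = 1,
                       stringsAsFactors = FALSE),
    stop("no truncating catalog for gene ", gene)
  )
}

# sample one element of a vector (safe for length-1 vectors, where base
# sample() would treat the value as a range)
sample_one <- function(x) x[sample.int(length(x), 1L)]

subclonal_driver_catalog <- function() {
  data.frame(
    gene = c("RNF43", "ARID1A", "GNAS", "KDM6A", "TGFBR2"),
    chrom = c("17", "1", "20", "X", "3"),
    pos = c(56435161L, 27100181L, 57484420L, 44938563L, 30691872L),
    ref = c("AG", "C", "G", "C", "CA"),
    alt = c("A", "T", "A", "T", "C"),
    protein_change = c("p.K568Sfs*132", "p.Q1334*", "p.R201H",
                       "p.Q555*", "p.E125fs"),
    effect = c("frameshift", "nonsense", "missense", "nonsense", "frameshift"),
    weight = 1,
    stringsAsFactors = FALSE
  )
}

passenger_genes <- function() {
  c("TTN", "MUC16", "OBSCN", "CSMD3", "LRP1B", "FAT4", "RYR1", "PCDH15",
    "DNAH5", "SYNE1", "FLG", "USH2A", "XIRP2", "HMCN1", "ZFHX4")
}

# Draw one row from a weighted variant catalog.
draw_variant <- function(catalog) {
  i <- sample.int(nrow(catalog), 1L, prob = catalog$weight)
  catalog[i, c("gene", "chrom", "pos", "ref", "alt", "protein_change", "effect")]
}

# Synthetic passenger at a unique locus. `serial` keeps keys distinct
# within a patient.
draw_passenger <- function(serial) {
  gene <- sample(passenger_genes(), 1L)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1L)
  data.frame(
    gene = gene, chrom = as.character(sample(1:22, 1L)),
    pos = 5000000L + serial * 37L,
    ref = ref, alt = sample(setdiff(bases, ref), 1L),
    protein_change = sprintf("p.X%d", serial),
    effect = sample(c("missense", "inframe_indel", "other"), 1L,
                    prob = c(0.85, 0.1, 0.05)),
    stringsAsFactors = FALSE
  )
}

# --- clone trees ------------------------------------------------------------

#' Simulate one neoplastic clone tree
#'
#' Draws a clone count from `config$clone_count_range`, attaches each new
#' clone to a uniformly chosen existing clone, and assigns cancer cell
#' fractions by stick-breaking: the trunk has CCF 1 in the neoplasm and each
#' child receives a Beta(4, 2) fraction of its parent's remaining
#' (unallocated) CCF, so sibling CCFs never exceed the parent's. The trunk
#' carries hotspot/truncating drivers drawn per `config$trunk_driver_probs`;
#' each non-trunk clone may carry one subclonal driver
#' (`config$subclonal_driver_prob`) and every clone carries Poisson
#' passengers. Clones that would otherwise be empty receive one passenger so
#' that every clone is observable.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A list with elements `parent` (integer vector, `NA` for the
#'   trunk), `ccf_neoplasm`, and `mutations` (one row per mutation with its
#'   clone index, locus key, effect, scores and `is_driver` truth label).
#' @export
simulate_clone_tree <- function(config) {
  n_clones <- sample_one(seq(config$clone_count_range[1],
                             config$clone_count_range[2]))
  parent <- rep(NA_integer_, n_clones)
  ccf <- numeric(n_clones)
  ccf[1] <- 1
  avail <- numeric(n_clones)
  avail[1] <- 1
  if (n_clones > 1) {
    for (k in 2:n_clones) {
      p <- if (k == 2) 1L else sample.int(k - 1L, 1L)
      parent[k] <- p
      frac <- stats::rbeta(1, 4, 2)
      ccf[k] <- avail[p] * frac
      avail[p] <- avail[p] - ccf[k]
      avail[k] <- ccf[k]
    }
  }

  muts <- list()
  serial <- 0L
  add_mut <- function(row, clone, is_driver, pp2, sift) {
    row$clone <- clone
    row$is_driver <- is_driver
    row$polyphen <- pp2
    row$sift <- sift
    muts[[length(muts) + 1L]] <<- row
  }

  # truncal drivers
  for (gene in names(config$trunk_driver_probs)) {
    if (stats::runif(1) > config$trunk_driver_probs[[gene]]) next
    row <- switch(gene,
      KRAS = draw_variant(kras_hotspots()),
      TP53 = draw_variant(tp53_dbd()),
      draw_variant(truncating_drivers(gene)))
    if (row$effect == "missense") {
      add_mut(row, 1L, TRUE, stats::runif(1, 0.9, 1), stats::runif(1, 0, 0.04))
    } else {
      add_mut(row, 1L, TRUE, NA_real_, NA_real_)  # truncating: unscored
    }
  }

  # subclonal drivers
  if (n_clones > 1 && config$subclonal_driver_prob > 0) {
    for (k in 2:n_clones) {
      if (stats::runif(1) < config$subclonal_driver_prob) {
        row <- draw_variant(subclonal_driver_catalog())
        if (row$effect == "missense") {
          add_mut(row, k, TRUE, stats::runif(1, 0.9, 1), stats::runif(1, 0, 0.04))
        } else {
          add_mut(row, k, TRUE, NA_real_, NA_real_)
        }
      }
    }
  }

  # passengers
  for (k in seq_len(n_clones)) {
    n_pass <- stats::rpois(1, config$passengers_per_clone)
    has_any <- length(muts) > 0 &&
      any(vapply(muts, function(m) m$clone == k, logical(1)))
    if (n_pass == 0 && !has_any) n_pass <- 1L  # keep every clone observable
    for (j in seq_len(n_pass)) {
      serial <- serial + 1L
      add_mut(draw_passenger(serial), k, FALSE,
              stats::runif(1, 0, 0.6), stats::runif(1, 0.1, 1))
    }
  }

  mutations <- do.call(rbind, muts)
  mutations$mut_id <- sprintf("m%03d", seq_len(nrow(mutations)))
  rownames(mutations) <- NULL
  list(parent = parent, ccf_neoplasm = ccf, mutations = mutations)
}

# indices of the subtree rooted at `node`
subtree_of <- function(parent, node) {
  out <- node
  repeat {
    kids <- which(parent %in% out & !(seq_along(parent) %in% out))
    if (length(kids) == 0) break
    out <- c(out, kids)
  }
  sort(out)
}

#' Seed the stroma of a clone tree to realize a target subtype
#'
#' Assigns per-clone stromal CCFs (and a per-mutation stromal CCF vector,
#' needed for the suppression-based D archetypes) so that the noise-free
#' presence pattern satisfies the target subtype's defining predicate:
#' A keeps every clone in stroma; B keeps the trunk (with all its drivers)
#' but zeroes at least one non-trunk subtree; C zeroes everything; D is one
#' of two archetypes chosen 50/50 — trunk absent with one later clone
#' present, or trunk present with its driver mutations suppressed below
#' detection. Stroma-private passengers are added at Poisson rate
#' `config$stroma_private_rate`.
#'
#' @param tree Output of [simulate_clone_tree()].
#' @param target_subtype One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param config A [sim_config()].
#' @return A list: `ccf_stroma` (per clone), `mut_ccf_stroma` (per mutation
#'   row of `tree$mutations`), `private` (stroma-private mutation table,
#'   possibly empty), `d_mode` (`NA`, 1 or 2).
#' @export
seed_stroma <- function(tree, target_subtype, config) {
  target_subtype <- match.arg(target_subtype, c("A", "B", "C", "D"))
  n <- length(tree$parent)
  muts <- tree$mutations
  n_drv <- sum(muts$is_driver)
  trunk_drv <- sum(muts$is_driver & muts$clone == 1L)

  if (target_subtype %in% c("A", "B") && n_drv == 0) {
    stop("impossible target: tree has no driver event (required for A/B)")
  }
  if (target_subtype == "B" && n < 2) {
    stop("impossible target: single-clone tree cannot realize subtype B")
  }

  seed_present <- function(present) {
    s <- numeric(n)
    if (present[1]) s[1] <- stats::runif(1, 0.7, 1)
    ord <- order(seq_len(n))  # clones are created parent-before-child
    for (k in 2:max(2, n)) {
      if (n < 2) break
      if (!present[k]) next
      p <- tree$parent[k]
      s[k] <- stats::runif(1, 0.7, 1) * min(s[p], tree$ccf_neoplasm[k])
    }
    s
  }

  d_mode <- NA_integer_
  mut_ccf <- NULL
  if (target_subtype == "A") {
    present <- rep(TRUE, n)
    s <- seed_present(present)
  } else if (target_subtype == "B") {
    drop_root <- sample_one(2:n)
    absent <- subtree_of(tree$parent, drop_root)
    present <- !(seq_len(n) %in% absent)
    s <- seed_present(present)
  } else if (target_subtype == "C") {
    s <- numeric(n)
  } else {
    # D archetypes
    mode1_ok <- n >= 2
    mode2_ok <- trunk_drv >= 1 && any(!muts$is_driver & muts$clone == 1L)
    if (!mode1_ok && !mode2_ok) {
      stop("impossible target: tree cannot realize either D archetype")
    }
    d_mode <- if (mode1_ok && mode2_ok) sample(1:2, 1L) else if (mode1_ok) 1L else 2L
    if (d_mode == 1L) {
      # trunk absent, one later clone's own mutations present
      cand <- 2:n
      with_drv <- cand[cand %in% muts$clone[muts$is_driver]]
      pick <- if (length(with_drv) > 0) with_drv[sample.int(length(with_drv), 1L)]
              else cand[sample.int(length(cand), 1L)]
      s <- numeric(n)
      s[pick] <- stats::runif(1, 0.3, 0.7)
      mut_ccf <- ifelse(muts$clone == pick, s[pick], 0)
    } else {
      # trunk present but every trunk driver suppressed below detection
      s <- numeric(n)
      s[1] <- stats::runif(1, 0.5, 1)
      mut_ccf <- ifelse(muts$clone == 1L & !muts$is_driver, s[1], 0)
    }
  }

  if (is.null(mut_ccf)) mut_ccf <- s[muts$clone]

  n_priv <- stats::rpois(1, config$stroma_private_rate)
  private <- NULL
  if (n_priv > 0) {
    rows <- lapply(seq_len(n_priv), function(j) draw_passenger(9000L + j))
    private <- do.call(rbind, rows)
    private$ccf_stroma <- stats::runif(n_priv, 0.2, 0.8)
    private$polyphen <- stats::runif(n_priv, 0, 0.6)
    private$sift <- stats::runif(n_priv, 0.1, 1)
  }

  list(ccf_stroma = s, mut_ccf_stroma = mut_ccf, private = private,
       d_mode = d_mode)
}

# --- read sampling ----------------------------------------------------------

#' Sample sequencing read support for a set of mutations
#'
#' Observation model: per mutation, depth is negative binomial with mean
#' `config$mean_depth` and size `config$depth_dispersion`; the expected VAF
#' of a copy-neutral heterozygous variant (one mutant copy, copy number 2)
#' is `ccf * cell_fraction / 2`, and alt reads are binomial at that
#' probability. Germline variants should be passed with `ccf = 1` and
#' `cell_fraction = 1` (expected VAF 0.5 independent of purity).
#'
#' @param ccf Numeric vector of per-mutation cancer cell fractions in the
#'   sampled component.
#' @param cell_fraction Fraction of the specimen's cells belonging to the
#'   mutated lineage compartment (tumor cell fraction for neoplasm,
#'   neoplasm-derived fraction for stroma).
#' @param config A [sim_config()].
#' @return data.frame with `depth`, `alt`, `vaf`.
#' @export
sample_reads <- function(ccf, cell_fraction, config) {
  stopifnot(all(ccf >= 0 & ccf <= 1))
  nmut <- length(ccf)
  depth <- pmax(1L, stats::rnbinom(nmut, size = config$depth_dispersion,
                                   mu = config$mean_depth))
  evaf <- ccf * cell_fraction / 2
  alt <- stats::rbinom(nmut, depth, evaf)
  data.frame(depth = depth, alt = alt, vaf = ifelse(depth > 0, alt / depth, 0))
}

# --- per-patient assembly ---------------------------------------------------

call_columns <- c("patient_id", "specimen_id", "component", "chrom", "pos",
                  "ref", "alt", "gene", "protein_change", "effect",
                  "hq_alt_reads", "depth", "vaf", "pop_af_max",
                  "polyphen", "sift", "copy_number")

empty_calls <- function() {
  df <- data.frame(patient_id = character(), specimen_id = character(),
                   component = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   gene = character(), protein_change = character(),
                   effect = character(), hq_alt_reads = integer(),
                   depth = integer(), vaf = numeric(), pop_af_max = numeric(),
                   polyphen = numeric(), sift = numeric(),
                   copy_number = integer(), stringsAsFactors = FALSE)
  df
}

assemble_calls <- function(patient_id, component, loci, reads, pop_af) {
  if (nrow(loci) == 0) return(empty_calls())
  data.frame(
    patient_id = patient_id,
    specimen_id = paste(patient_id, component, sep = "_"),
    component = component,
    chrom = loci$chrom, pos = loci$pos, ref = loci$ref, alt = loci$alt,
    gene = loci$gene, protein_change = loci$protein_change,
    effect = loci$effect,
    hq_alt_reads = reads$alt, depth = reads$depth, vaf = reads$vaf,
    pop_af_max = pop_af,
    polyphen = loci$polyphen, sift = loci$sift,
    copy_number = 2L,
    stringsAsFactors = FALSE
  )
}

simulate_patient <- function(patient_id, target_subtype, config, seed) {
  set.seed(seed)
  tree <- NULL
  seeding <- NULL
  for (attempt in 1:100) {
    tree_try <- simulate_clone_tree(config)
    seeding_try <- tryCatch(seed_stroma(tree_try, target_subtype, config),
                            error = function(e) NULL)
    if (!is.null(seeding_try)) {
      tree <- tree_try
      seeding <- seeding_try
      break
    }
  }
  if (is.null(seeding)) {
    stop("could not realize subtype ", target_subtype,
         " for patient ", patient_id, " after 100 tree draws")
  }

  muts <- tree$mutations
  stroma_has_neoplastic <- any(seeding$mut_ccf_stroma > 0)
  grp <- if (stroma_has_neoplastic) "mutant" else "wildtype"
  tcf <- stats::rbeta(1, config$tcf_beta[[grp]][1], config$tcf_beta[[grp]][2])

  # germline variants: present in all four specimens at expected VAF 0.5
  n_germ <- stats::rpois(1, config$germline_rate)
  germ <- NULL
  if (n_germ > 0) {
    rows <- lapply(seq_len(n_germ), function(j) draw_passenger(8000L + j))
    germ <- do.call(rbind, rows)
    germ$polyphen <- NA_real_
    germ$sift <- NA_real_
    # half common (caught by the population-AF rule), half rare (caught by
    # matched blood/normal subtraction)
    germ$pop_af <- ifelse(stats::runif(n_germ) < 0.5,
                          stats::runif(n_germ, 0.05, 0.5),
                          stats::runif(n_germ, 0, 0.005))
  }

  somatic_cols <- c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                    "effect", "polyphen", "sift")

  neo_loci <- muts[, somatic_cols]
  neo_reads <- sample_reads(tree$ccf_neoplasm[muts$clone], tcf, config)
  neo <- assemble_calls(patient_id, "neoplasm", neo_loci, neo_reads, 0)

  str_loci <- muts[, somatic_cols]
  str_reads <- sample_reads(seeding$mut_ccf_stroma,
                            config$stroma_neoplastic_fraction, config)
  str_ <- assemble_calls(patient_id, "stroma", str_loci, str_reads, 0)
  if (!is.null(seeding$private)) {
    priv_reads <- sample_reads(seeding$private$ccf_stroma, 1, config)
    str_ <- rbind(str_, assemble_calls(patient_id, "stroma",
                                       seeding$private[, somatic_cols],
                                       priv_reads, 0))
  }

  blood <- normal <- empty_calls()
  if (!is.null(germ)) {
    for (comp in c("blood", "normal", "neoplasm", "stroma")) {
      reads <- sample_reads(rep(1, nrow(germ)), 1, config)
      tab <- assemble_calls(patient_id, comp, germ[, somatic_cols],
                            reads, germ$pop_af)
      if (comp == "blood") blood <- tab
      else if (comp == "normal") normal <- tab
      else if (comp == "neoplasm") neo <- rbind(neo, tab)
      else str_ <- rbind(str_, tab)
    }
  }

  # a variant caller only reports supported sites
  calls <- rbind(neo, str_, blood, normal)
  calls <- calls[calls$hq_alt_reads >= 1, , drop = FALSE]
  rownames(calls) <- NULL

  truth_muts <- muts
  truth_muts$ccf_neoplasm <- tree$ccf_neoplasm[muts$clone]
  truth_muts$ccf_stroma <- seeding$mut_ccf_stroma

  list(
    calls = calls,
    truth = list(
      patient_id = patient_id,
      subtype = target_subtype,
      neoplasm_like = target_subtype %in% c("A", "B"),
      d_mode = seeding$d_mode,
      parent = tree$parent,
      ccf_neoplasm = tree$ccf_neoplasm,
      ccf_stroma = seeding$ccf_stroma,
      mutations = truth_muts,
      stromal_kras = any(muts$gene == "KRAS" & seeding$mut_ccf_stroma > 0),
      stromal_tp53 = any(muts$gene == "TP53" & seeding$mut_ccf_stroma > 0),
      tcf = tcf
    )
  )
}

#' Simulate a complete paired cohort
#'
#' Draws each patient's target subtype from `config$subtype_mix`, builds the
#' clone tree, stromal seeding, read counts and clinical record, and returns
#' the observed call table together with the ground truth. Fully determined
#' by `config$seed` (per-patient substreams are pre-drawn from it).
#'
#' @param config A [sim_config()].
#' @return A list with `calls` (all specimens' mutation calls), `clinical`
#'   (one row per patient), `truth` (per-patient ground-truth list), and
#'   `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 2, seed = 42))
#' table(sim$calls$component)
simulate_cohort <- function(config) {
  seeds <- patient_seeds(config)
  set.seed(config$seed)
  subtypes <- sample(c("A", "B", "C", "D"), config$n_patients,
                     replace = TRUE, prob = config$subtype_mix)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(ids[i], subtypes[i], config, seeds[i])
  })
  calls <- do.call(rbind, lapply(patients, `[[`, "calls"))
  truth <- lapply(patients, `[[`, "truth")
  names(truth) <- ids

  truth_tab <- data.frame(
    patient_id = ids,
    subtype = subtypes,
    neoplasm_like = vapply(truth, `[[`, logical(1), "neoplasm_like"),
    stromal_kras = vapply(truth, `[[`, logical(1), "stromal_kras"),
    stromal_tp53 = vapply(truth, `[[`, logical(1), "stromal_tp53"),
    tcf = vapply(truth, `[[`, numeric(1), "tcf"),
    stringsAsFactors = FALSE
  )
  clinical <- simulate_clinical(truth_tab, config,
                                seed = seeds[length(seeds)] %% 1000000L + 1L)

  list(calls = calls, clinical = clinical, truth = truth, config = config)
}

#' Simulate clinical records with subtype-dependent survival
#'
#' Disease-free survival is exponential with hazard
#' `baseline_hazard * HR^neoplasm_like`; observation is censored at the
#' minimum of the event time, a uniform per-patient follow-up time (12
#' months to the horizon, emulating staggered enrolment) and the horizon.
#' Age is shifted upward for patients with stromal KRAS/TP53 mutations,
#' matching the older age observed in stroma-mutant patients; the remaining
#' covariates are drawn at the cohort's marginal frequencies.
#'
#' @param truth_tab data.frame with columns `patient_id`, `neoplasm_like`,
#'   `stromal_kras`, `stromal_tp53` and optionally `tcf`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this draw.
#' @return data.frame of clinical records (one row per patient) with
#'   covariates, `dfs_months` and `event`.
#' @export
simulate_clinical <- function(truth_tab, config, seed = config$seed + 1L) {
  set.seed(seed)
  n <- nrow(truth_tab)
  krastp53 <- truth_tab$stromal_kras | truth_tab$stromal_tp53
  age <- round(stats::rnorm(n, 63, 8) + 5 * krastp53)
  age <- pmin(pmax(age, 35), 90)

  hr <- ifelse(truth_tab$neoplasm_like, config$neoplasm_like_hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = config$baseline_hazard * hr)
  t_cens <- pmin(stats::runif(n, 12, max(12, config$censoring_horizon)),
                 config$censoring_horizon)
  if (config$censoring_horizon < 12) t_cens <- rep(config$censoring_horizon, n)
  dfs <- pmin(t_event, t_cens)
  event <- t_event <= t_cens

  data.frame(
    patient_id = truth_tab$patient_id,
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
    stage = sample(c("I", "II-IV"), n, replace = TRUE, prob = c(0.5, 0.5)),
    tumor_size_gt4cm = stats::runif(n) < 0.14,
    lymph_node = stats::runif(n) < 0.38,
    nerve_invasion = stats::runif(n) < 0.82,
    vascular_invasion = stats::runif(n) < 0.42,
    adjuvant_chemo = stats::runif(n) < 0.60,
    tcf = if ("tcf" %in% names(truth_tab)) truth_tab$tcf else NA_real_,
    dfs_months = dfs,
    event = event,
    stringsAsFactors = FALSE
  )
}
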