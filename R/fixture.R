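## Deterministic synthetic landmark cohort.
##
## A 50-patient paired stroma/neoplasm call set constructed so that every
## cohort-level marginal the pipeline reports lands on the landmark values
## it is validated against:
##   127 stromal mutations in 39 mutation-positive stromata
##     (KRAS 28 patients / 29 mutations, TP53 24, CDKN2A 9, KRAS+TP53 co 21),
##   248 neoplastic mutations in 50 patients (KRAS 47/48, TP53 43,
##     CDKN2A 12, SMAD4 9),
##   114 shared / 13 stroma-specific / 134 neoplasm-specific,
##   71 driver events among the shared set (nine genes), 2 among the
##     stroma-specific set, 57 among the neoplasm-specific set,
##   stromal clonality 99/114 shared (96 clonal in both), neoplastic
##     clonality 72/134 of the neoplasm-specific set,
##   per-gene clonality: KRAS 26/29 stroma, 46/48 neoplasm; TP53 21/24
##     stroma, 42/43 neoplasm.
## Entirely synthetic: loci are placeholder coordinates, VAFs take only the
## two values 0.4 (clonal tier) and 0.1 (subclonal tier), depth is 1000.

fixture_gene_chrom <- c(
  KRAS = "12", TP53 = "17", CDKN2A = "9", SMAD4 = "18", ARID1A = "1",
  GNAS = "20", KDM6A = "X", RNF43 = "17", TGFBR2 = "3"
)

#' Deterministic landmark cohort fixture
#'
#' Builds the synthetic paired call tables described above. Every quantity
#' is hard-wired and deterministic; the fixture exists so that the
#' pipeline's derived counts and percentages can be checked exactly
#' against the landmark values.
#'
#' @return list with `stroma` and `neoplasm` call data.frames (MutationCall
#'   layout, all rows passing the somatic filters) and `patients`
#'   (`patient_id`, `tcf`, `stroma_mutant`).
#' @export
#' @examples
#' fx <- landmark_cohort()
#' nrow(fx$stroma)    # 127
#' nrow(fx$neoplasm)  # 248
landmark_cohort <- function() {
  pid <- function(i) sprintf("P%02d", i)
  passenger_pool <- passenger_genes()
  rows <- list()
  serial <- 0L

  add <- function(patient, gene, effect, pp2, sift, vaf_stroma, vaf_neoplasm,
                  protein_change = NA_character_) {
    serial <<- serial + 1L
    if (is.na(protein_change)) protein_change <- sprintf("p.S%d", serial)
    rows[[serial]] <<- data.frame(
      patient_id = patient, gene = gene, effect = effect,
      polyphen = pp2, sift = sift,
      chrom = if (gene %in% names(fixture_gene_chrom))
                fixture_gene_chrom[[gene]] else "2",
      pos = 1000000L + serial * 10L, ref = "A", alt = "G",
      protein_change = protein_change,
      vaf_stroma = vaf_stroma, vaf_neoplasm = vaf_neoplasm,
      stringsAsFactors = FALSE
    )
  }
  missense_driver <- function(patient, gene, vs, vn, pchg = NA) {
    add(patient, gene, "missense", 0.99, 0.01, vs, vn, pchg)
  }
  truncating_driver <- function(patient, gene, effect, vs, vn, pchg = NA) {
    add(patient, gene, effect, NA_real_, NA_real_, vs, vn, pchg)
  }
  passenger <- function(patient, vs, vn) {
    add(patient, passenger_pool[serial %% length(passenger_pool) + 1L],
        "missense", 0.2, 0.5, vs, vn)
  }

  CL <- 0.4   # clonal-tier VAF
  SB <- 0.1   # subclonal-tier VAF

  ## ---- shared mutations (114) ----
  # KRAS, 28 patients; stroma-subclonal in P26, P27
  kras_pchg <- c("p.G12D", "p.G12V", "p.G12C", "p.G12R", "p.Q61H", "p.Q61R")
  for (i in 1:28) {
    vs <- if (i %in% c(26, 27)) SB else CL
    pchg <- if (i == 5) "p.G12R" else kras_pchg[(i %% 6) + 1]
    missense_driver(pid(i), "KRAS", vs, CL, pchg)
  }
  # TP53, 24 patients (P01-P21, P29-P31); stroma-subclonal in P29-P31
  for (i in c(1:21, 29:31)) {
    vs <- if (i %in% 29:31) SB else CL
    missense_driver(pid(i), "TP53", vs, CL, "p.R175H")
  }
  # CDKN2A, 9 patients
  for (i in 1:9) truncating_driver(pid(i), "CDKN2A", "nonsense", CL, CL)
  # other shared drivers (10)
  truncating_driver(pid(13), "SMAD4", "nonsense", CL, CL, "p.R361*")
  truncating_driver(pid(22), "TGFBR2", "frameshift", CL, CL)
  for (i in 32:33) truncating_driver(pid(i), "ARID1A", "nonsense", CL, CL)
  for (i in 34:35) missense_driver(pid(i), "GNAS", CL, CL, "p.R201H")
  for (i in 36:37) truncating_driver(pid(i), "KDM6A", "nonsense", CL, CL)
  for (i in 38:39) truncating_driver(pid(i), "RNF43", "frameshift", CL, CL,
                                     "p.K568Sfs*132")
  # shared passengers (43); stroma-subclonal in P01-P10,
  # neoplasm-subclonal in P16-P18
  for (i in 1:21) {
    vs <- if (i <= 10) SB else CL
    vn <- if (i %in% 16:18) SB else CL
    passenger(pid(i), vs, vn)
  }
  for (i in c(22:28, 29:31)) {  # two each
    passenger(pid(i), CL, CL)
    passenger(pid(i), CL, CL)
  }
  for (i in 32:33) passenger(pid(i), CL, CL)

  ## ---- stroma-specific mutations (13) ----
  missense_driver(pid(5), "KRAS", SB, NA_real_, "p.G12V")
  truncating_driver(pid(39), "SMAD4", "nonsense", CL, NA_real_, "p.W302*")
  for (i in c(1:4, 6:12)) passenger(pid(i), CL, NA_real_)

  ## ---- neoplasm-specific mutations (134) ----
  # KRAS: P29-P47 plus a second mutation in P01; subclonal in P29, P30
  missense_driver(pid(1), "KRAS", NA_real_, CL, "p.Q61H")
  for (i in 29:47) {
    vn <- if (i %in% c(29, 30)) SB else CL
    missense_driver(pid(i), "KRAS", NA_real_, vn, "p.G12D")
  }
  # TP53: P22-P28, P32-P43; subclonal in P22
  for (i in c(22:28, 32:43)) {
    vn <- if (i == 22) SB else CL
    missense_driver(pid(i), "TP53", NA_real_, vn, "p.R273H")
  }
  # CDKN2A P10-P12, SMAD4 P14-P21
  for (i in 10:12) truncating_driver(pid(i), "CDKN2A", "nonsense", NA_real_, CL)
  for (i in 14:21) truncating_driver(pid(i), "SMAD4", "nonsense", NA_real_, CL)
  # other neoplasm-specific drivers (7)
  for (i in 44:46) truncating_driver(pid(i), "ARID1A", "nonsense", NA_real_, CL)
  for (i in 47:48) truncating_driver(pid(i), "RNF43", "frameshift", NA_real_, CL)
  truncating_driver(pid(49), "KDM6A", "nonsense", NA_real_, CL)
  truncating_driver(pid(50), "TGFBR2", "frameshift", NA_real_, CL)
  # neoplasm-specific passengers (77): two for P01-P27, one for P28-P50;
  # subclonal except the P33-P50 singletons (18 clonal)
  for (i in 1:27) {
    passenger(pid(i), NA_real_, SB)
    passenger(pid(i), NA_real_, SB)
  }
  for (i in 28:50) {
    vn <- if (i >= 33) CL else SB
    passenger(pid(i), NA_real_, vn)
  }

  defs <- do.call(rbind, rows)

  patients <- data.frame(
    patient_id = pid(1:50),
    stroma_mutant = c(rep(TRUE, 39), rep(FALSE, 11)),
    stringsAsFactors = FALSE
  )
  patients$tcf <- ifelse(patients$stroma_mutant, 0.7, 0.5)

  emit <- function(vaf_col, component) {
    sub <- defs[!is.na(defs[[vaf_col]]), , drop = FALSE]
    vaf <- sub[[vaf_col]]
    data.frame(
      patient_id = sub$patient_id,
      specimen_id = paste(sub$patient_id, component, sep = "_"),
      component = component,
      chrom = sub$chrom, pos = sub$pos, ref = sub$ref, alt = sub$alt,
      gene = sub$gene, protein_change = sub$protein_change,
      effect = sub$effect,
      hq_alt_reads = as.integer(round(vaf * 1000)),
      depth = 1000L,
      vaf = vaf,
      pop_af_max = 0,
      polyphen = sub$polyphen, sift = sub$sift,
      copy_number = 2L,
      stringsAsFactors = FALSE
    )
  }

  list(stroma = emit("vaf_stroma", "stroma"),
       neoplasm = emit("vaf_neoplasm", "neoplasm"),
       patients = patients)
}
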