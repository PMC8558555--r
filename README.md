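# stromaclone

Clonal deconvolution and evolutionary subtyping of paired tumor-stroma and
neoplasm mutation profiles in pancreatic ductal adenocarcinoma (PDAC).

## The problem

When the fibrotic stroma and the neoplastic cell nests of a resected PDAC
are separated by laser-capture microdissection and sequenced in parallel,
most stromal specimens turn out to carry somatic mutations — frequently
canonical drivers such as KRAS codon-12/61 hotspots and TP53
DNA-binding-domain mutations — and the large majority of those mutations
are also present in the matched neoplasm. The interpretation is that
neoplasm-derived cells seed the stroma via epithelial–mesenchymal
transition, so the stromal genome records part of the tumor's clonal
history. How much of that history the stroma captures differs by patient
and predicts disease-free survival (DFS) after resection.

`stromaclone` is for analysts with per-specimen somatic call sets (VCF or
TSV) from paired microdissected components who want to go from raw calls
to a per-patient prognostic label and cohort-level statistics.

## The method

Per specimen, calls pass a five-rule somatic filter (≥ 5 high-quality
reads; population allele frequency ≤ 1%; non-synonymous; VAF ≥ 1%; absent
from matched blood and normal tissue). Driver events are harmful mutations
(PolyPhen-2 > 0.85 or SIFT < 0.05, truncating always harmful) in a curated
PDAC driver-gene list. Clonality uses the specimen-normalized VAF

    normalized VAF = VAF / max VAF in the same specimen,

with normalized VAF ≥ 0.5 defining a clonal event. Neoplastic clone
structure comes from a seeded binomial-mixture clustering of alt-read
counts (cluster k has success probability CCF_k·π/2; model size by BIC),
whose small-instance optima are verifiable against an exhaustive
enumeration oracle. Clusters, ordered by mean cancer cell fraction with
the trunk first, are matched into the stroma through the shared-mutation
partition, and each patient receives an evolutionary subtype:

* **A** — every neoplastic clone and every driver event found in stroma;
* **B** — trunk and its driver events in stroma, later clones missing;
* **C** — no neoplastic mutation in stroma at all;
* **D** — discordant patterns (trunk absent but a later clone present, or
  trunk present without any shared driver event).

Subtypes A and B define **neoplasm-like stroma**; DFS is stratified by
this flag (and by stromal KRAS/TP53 status) with Kaplan–Meier curves, the
log-rank test and Cox models (Efron ties, forward-LR multivariate
selection). A synthetic paired-cohort generator with known clone trees,
subtype-dependent stromal seeding, binomial read sampling at ~1000× and
exponential DFS provides ground truth for end-to-end validation.

## Worked example

```r
library(stromaclone)

cfg <- sim_config(n_patients = 30, seed = 2024)   # synthetic paired cohort
sim <- simulate_cohort(cfg)
res <- analyze_cohort(sim$calls, clinical = sim$clinical, seed = 2024)
table(res$subtypes$subtype)
#>  A  B  C  D
#> 12 11  6  1

head(res$subtypes[, c("patient_id", "subtype", "neoplasm_like",
                      "stromal_kras", "stromal_tp53", "n_shared")])
#>      patient_id subtype neoplasm_like stromal_kras stromal_tp53 n_shared
#> P001       P001       C         FALSE        FALSE        FALSE        0
#> P002       P002       A          TRUE         TRUE         TRUE       21
#> P003       P003       A          TRUE         TRUE         TRUE       20
#> P004       P004       A          TRUE         TRUE         TRUE       20
#> P005       P005       B          TRUE        FALSE         TRUE        3
#> P006       P006       A          TRUE         TRUE         TRUE       12

tab <- merge(sim$clinical, res$subtypes, by = "patient_id")
survival_analysis(tab, grouping = "neoplasm_like")
#> <survival_result> DFS by neoplasm_like
#>   neoplasm_like = FALSE: n = 7, events = 4, median DFS 16.8 mo
#>   neoplasm_like = TRUE: n = 23, events = 22, median DFS 3.7 mo
#>   log-rank p = 0.007384; HR = 4.210 (95% CI 1.375-12.886), p = 0.0118
```

Reading: 23 of 30 patients have neoplasm-like (type A/B) stroma; their
median DFS is 3.7 months against 16.8 months for the rest, with a Cox
hazard ratio of 4.2 — the generator's true hazard ratio is 3, and a single
30-patient draw estimates it with wide error, which is why validation uses
replicated cohorts (see below).

## The analysis workflow

The `analysis/` scripts run the pipeline as a narrative sequence, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort VCF/TSV/CSV + truth JSON
Rscript analysis/02_filter.R            # five-rule cascade + filter report
Rscript analysis/03_clonality.R         # normalized VAFs, partition, clusters
Rscript analysis/04_subtype.R           # subtypes A-D vs. simulated truth
Rscript analysis/05_survival_report.R   # prevalence, TCF, KM/Cox report
```

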