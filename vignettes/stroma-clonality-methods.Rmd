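---
title: "Methods: paired stroma/neoplasm clonality and evolutionary subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired stroma/neoplasm clonality and evolutionary subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In pancreatic ductal adenocarcinoma (PDAC), the fibrotic stroma dominates
the tumor mass. Laser-capture microdissection makes it possible to sequence
the stromal and neoplastic compartments of one resected tumor separately.
When that is done, a large fraction of stromal specimens turn out to carry
somatic mutations — including canonical drivers such as KRAS hotspot and
TP53 DNA-binding-domain mutations — and most of those mutations are also
present in the matched neoplasm. The favored explanation is
epithelial–mesenchymal transition: neoplasm-derived cells migrate into the
stroma and keep their genomes, so the stroma inherits a snapshot of the
tumor's clonal history. How much of that history the stroma captures varies
by patient, and that variation carries prognostic information.

`stromaclone` implements the full analysis chain from per-specimen mutation
calls to the patient-level prognostic label:

1. **Filtering** — a five-rule somatic filter cascade with matched blood
   and normal-tissue subtraction.
2. **Driver annotation** — a curated PDAC driver-gene list combined with a
   PolyPhen-2/SIFT harmfulness rule.
3. **Clonality** — specimen-normalized VAFs for the clonal/subclonal
   dichotomy, and a seeded binomial-mixture clustering for clone structure.
4. **Trajectory subtyping** — matching neoplastic clones into the stroma
   and assigning evolutionary subtypes A–D, with A and B together defining
   *neoplasm-like stroma*.
5. **Cohort statistics** — prevalence tables, rank correlations, two-group
   tests, and disease-free-survival stratification.
6. **Synthetic cohort generation** — a ground-truth simulator used to
   validate every downstream stage end to end.

# Models and rules

## Somatic filter cascade

Five rules are applied in a fixed order with first-match attribution:

1. fewer than five high-quality supporting reads (base quality ≥ 30,
   mapping quality ≥ 30 at the calling stage; the count arrives in the
   `AD`/`hq_alt_reads` field);
2. population allele frequency above 1% in the annotated SNP panels;
3. synonymous effect;
4. VAF strictly below 1%;
5. exact `(chrom, pos, ref, alt)` match in the patient's blood lymphocytes
   or normal tissue.

The order follows the sequence in which the rules are conventionally
stated; because removal is a set intersection, the *retained* set is
order-independent — only the per-rule attribution depends on the order,
and first-match is the documented convention. The 1% VAF cutoff is strict
(`< 1%` removed) and the matched-normal subtraction uses exact keys with
no positional window. An explicit VAF column, when present, wins over the
`AD/DP` ratio; the ratio is used only where no explicit VAF exists (the
two can differ when a caller computed VAF before quality filtering).

## Driver events

A mutation is a **driver event** iff its gene is on the curated driver
list *and* it is harmful. Harmfulness is `PolyPhen-2 > 0.85` **or**
`SIFT < 0.05`, both strict; truncating effects (nonsense, frameshift,
splice) are harmful regardless of scores because neither predictor scores
them, and stop-gains in established tumor suppressors (e.g. SMAD4 W302*)
are unambiguous. A missense mutation with both scores missing is
*unscorable* and conservatively treated as a passenger, with a logged
warning. In-frame indels are treated as score-dependent, like missense,
and are flagged in output. The packaged gene list
(`inst/extdata/pdac_driver_genes.txt`) holds the nine genes recurrently
hit in paired-component cohorts (KRAS, TP53, CDKN2A, ARID1A, GNAS, KDM6A,
RNF43, SMAD4, TGFBR2) plus the wider consensus PDAC driver set; it is a
plain text resource users can edit.

## Clonality

Absolute VAFs are not comparable across specimens: purity, and in stroma
the unknown fraction of neoplasm-derived cells, scale every VAF by an
unknown factor. Dividing by the **specimen maximum VAF** removes that
factor, which is why the normalized-VAF rule is scale-invariant (a property
the test suite checks directly). A mutation with normalized VAF ≥ 0.5
(inclusive at the boundary) is called a **clonal event**.

The **cancer cell fraction** of a mutation with one mutant copy is

$$\mathrm{CCF} = \mathrm{VAF} \cdot
  \frac{\pi C + 2(1-\pi)}{\pi},$$

with purity $\pi$ and local total copy number $C$ (default 2), clipped to
$[0,1]$ with a warning. Stromal purity has no operational definition, so
stromal CCFs use $\pi = 1$ unless the user supplies a value; the
normalized-VAF rule, not the CCF, drives all reported clonality
proportions.

## Clone clustering

Clone structure is inferred per neoplastic specimen by clustering
high-quality alt-read counts under a binomial model: cluster $k$ has
success probability $p_k = \mathrm{CCF}_k \cdot \pi / 2$. The fitting is a
**hard-assignment (classification) EM**: assign each mutation to the
cluster maximizing its binomial log-likelihood, re-estimate each $p_k$ as
the pooled alt/depth ratio (clamped to $[10^{-9}, \pi/2]$), iterate to a
fixed point. Initialization uses quantile-spread centers, every contiguous
partition of the VAF-sorted mutations (for small specimens), and seeded
jittered centers; the best classification likelihood wins, with ties
broken toward fewer clusters and then lexicographically smaller
membership. The number of clusters is selected by **BIC computed on the
mixture (marginal) likelihood** of the fitted components with $2K-1$
parameters — the classification likelihood itself always rewards a split,
so using it for selection would systematically over-segment.

This replaces Dirichlet-process samplers (PyClone-style) deliberately:
the downstream subtype rules consume only cluster membership and mean
prevalence, the EM is deterministic given a seed, and on small instances
its optimum is verifiable against exhaustive enumeration — the package
ships `brute_force_clusters()`, which maximizes the *identical*
classification objective over all assignments, as an independent oracle.

## Evolutionary subtypes

Neoplastic clusters are ordered by mean CCF descending (larger cluster
first on ties, then first-member index); the rank-1 cluster is the
**trunk**. A cluster is *present in stroma* when at least half
(`presence_fraction = 0.5`, inclusive; configurable, since no canonical
value exists) of its member mutations are in the shared partition.
Subtypes are assigned by an ordered cascade, which makes the predicates
mutually exclusive and exhaustive:

| order | subtype | predicate |
|---|---|---|
| 1 | C | shared partition empty |
| 2 | A | every cluster present and every neoplastic driver event shared |
| 3 | B | trunk present, ≥ 1 driver event shared, every *trunk* driver event shared |
| 4 | D | otherwise |

B demands all *trunk* driver events rather than all driver events anywhere:
a later-clone driver that stayed private to the neoplasm should not expel a
patient from B, but a stroma that carries the trunk without any driver
event is the second D archetype, so B must require at least one shared
driver. Stroma-private mutations are ignored by all subtype predicates
(a type-A stroma may still carry private variants). **Neoplasm-like
stroma** is defined as subtype A or B.

## Survival analysis

Disease-free survival is stratified with the product-limit Kaplan–Meier
estimator (medians reported as *unreached* — never imputed — when the
curve stays above 0.5), the log-rank test, and Cox proportional-hazards
models with the **Efron** tie approximation (a deliberate choice; SPSS
defaults to Breslow, so tied-time cohorts can differ slightly between the
two). The multivariate model uses forward likelihood-ratio selection with
entry p = 0.05 over the clinical covariates. Because the DFS analysis set
is sometimes restricted to patients followed up for over a year,
`survival_analysis()` exposes `min_followup` as an explicit option rather
than hard-coding either choice. No multiple-testing correction is applied
anywhere; p-values are reported as computed.

# The synthetic cohort generator

The generator exists so that every pipeline stage can be validated against
known truth. Per patient:

* **Clone tree** — clone count uniform on 2–5; each new clone attaches to
  a uniformly chosen existing clone; the trunk has neoplastic CCF 1 and
  each child receives a Beta(4, 2) fraction of its parent's unallocated
  CCF (stick-breaking), so sibling CCFs can never exceed the parent's.
* **Mutations** — the trunk draws hotspot/truncating drivers per gene
  (defaults KRAS 0.94, TP53 0.86, CDKN2A 0.24, SMAD4 0.18, matching
  neoplastic prevalences in resectable PDAC); non-trunk clones acquire a
  subclonal driver with probability 0.15 (RNF43/ARID1A/GNAS/KDM6A/TGFBR2);
  every clone carries Poisson(4) passengers, with one passenger forced for
  a clone that would otherwise be invisible.
* **Stromal seeding** — per target subtype, as in the table above; present
  clones receive stromal CCF `runif(0.7, 1) × min(parent stromal CCF,
  neoplastic CCF)`, so stromal CCFs respect both the tree ordering and the
  neoplastic ceiling. The D type uses its two archetypes 50/50: trunk
  absent with one later clone present, or trunk present with every trunk
  driver suppressed below detection. Both archetypes are observational
  statements about *mutation* presence, so the truth channel carries a
  per-mutation stromal CCF. Stroma-private passengers arrive at Poisson
  rate 0.33 per patient (matching 13 private mutations across 39
  informative stromata).
* **Reads** — depth is negative binomial with mean 1000 and size 15,
  which loosely reproduces a 360–1700× targeted-panel spread; expected VAF
  is `CCF × cell fraction / 2` for copy-neutral heterozygous variants, alt
  counts are binomial. The neoplastic cell fraction is the TCF, drawn
  Beta(8, 3) for patients whose stroma carries neoplasm-derived mutations
  and Beta(4, 4) otherwise (mutant-stroma patients show higher TCF). The
  stromal neoplasm-derived cell fraction is not observable by
  microimaging, so it is a free parameter (`stroma_neoplastic_fraction`,
  default 0.5). Germline variants (Poisson mean 2, expected VAF 0.5,
  half common and half rare in population panels) appear in all four
  specimens and exercise filter rules 2 and 5.
* **Survival** — DFS is exponential with hazard 0.06/month (baseline
  median ≈ 11.6 months) multiplied by 3.0 for neoplasm-like patients
  (neoplasm-like median ≈ 3.9 months), censored at the minimum of a
  uniform 12–30-month follow-up and the 30-month horizon. Age is shifted
  +5 years for stromal-KRAS/TP53 patients; the other covariates are drawn
  at the cohort's marginal frequencies.
* **Copy number** — fixed at 2 with one mutant copy; the CN column is
  honored when set on input data, but copy-number evolution is not
  simulated.
* **Randomness** — a single top-level seed; per-patient substreams are
  pre-drawn from it, so cohorts are bit-reproducible and patient *i* is
  unchanged by resizing the cohort beyond *i*.

What the generator deliberately does **not** emulate: alignment artifacts,
FFPE deamination damage, copy-number aberrations, contamination between
microdissected compartments, and mutational signatures. Recovery results
on synthetic cohorts therefore demonstrate that the pipeline's inference
is correct *under its own observation model*, not that the model captures
every failure mode of real FFPE panel data.

## The deterministic landmark fixture

`landmark_cohort()` is a separate, fully deterministic 50-patient call set
constructed so that every derived count and percentage the pipeline
reports lands exactly on the landmark values used for validation (127
stromal / 248 neoplastic mutations, 114 shared of which 99 are stromal
clonal events and 71 are driver events in nine genes, and so on). Its
VAFs take only two values — 0.4 for the clonal tier and 0.1 for the
subclonal tier — making every clonality call auditable by eye. It is
synthetic: loci are placeholder coordinates, and it should never be
mistaken for patient data.

# Numerical choices and degenerate inputs

* Clonality ties at normalized VAF exactly 0.5 are clonal (inclusive).
* Cluster-count ties in BIC go to the smaller K; likelihood ties within a
  K go to fewer non-empty clusters, then lexicographic membership.
* Cluster ranking ties (equal mean CCF) go to the larger cluster, then the
  smaller first-member index.
* `compute_ccf()` errors on purity 0 and clips CCF to [0, 1] with a
  warning; an empty specimen profile is legal everywhere except
  `cluster_clones()` and `assign_subtype()`, which require ≥ 1 mutation.
* Patients without retained neoplastic mutations are excluded from
  subtyping (the A–D predicates are undefined for them).
* Multiple distinct mutations in one gene are distinct keys throughout;
  gene-level flags mean "any mutation present".

# Validation scale

The packaged validation uses problem sizes chosen to exercise every code
path while staying desk-scale: subtype recovery on 500 patients at a
uniform subtype mix and 1000× depth (93–95% agreement with truth across
seeds; the residual errors are deep subclones whose stromal VAF falls
below the 1% detection floor, miscalling A as B, and near-CCF clone pairs
merged by BIC), hazard-ratio recovery over 100 replicates of n = 200
(mean estimate within a few percent of the true 3.0, CI coverage 94–98%),
clustering-oracle agreement on 200 instances of ≤ 8 mutations, and
truncal-clonality calibration on 100 patients (≈ 100% of truncal
mutations called clonal). The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch at any
seed.

# Known limitations

* The stromal compartment has no defined purity; stromal CCFs are
  therefore not comparable across patients in absolute terms. All
  stroma-side inference uses presence and normalized VAF, which are
  scale-free.
* The clustering stand-in assumes copy-neutral heterozygous variants; in
  CNA-dense genomes the CCF mapping `p = CCF·π/2` is wrong at altered
  loci, and a copy-number-aware clustering should replace it.
* Subtype B vs. D is sensitive to clone-cluster merging when two clones
  sit within the binomial noise floor of each other; deeper sequencing or
  more mutations per clone sharpen the boundary.
* With ~30-patient analysis sets and forward selection, the multivariate
  Cox model is exploratory; entry order can flip between near-collinear
  covariates.
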