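Package: stromaclone
Title: Clonal Deconvolution and Evolutionary Subtyping of Paired
    Tumor Stroma and Neoplasm Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired somatic mutation profiles from
    laser-capture microdissected stromal and neoplastic components of
    pancreatic ductal adenocarcinoma. Reads per-specimen mutation calls
    (minimal VCF 4.2 or flat TSV), applies a five-rule somatic filter
    cascade with matched-normal and blood subtraction, labels driver
    events from a curated gene list with PolyPhen-2/SIFT harmfulness
    rules, calls clonal status from specimen-normalized variant allele
    frequencies, clusters mutations into clones with a seeded binomial
    mixture, matches clones across components to assign each patient one
    of four evolutionary subtypes (A-D; A and B together defining
    neoplasm-like stroma), and stratifies disease-free survival by
    stromal genomic status. A synthetic paired-cohort generator with
    trunk/branch clone structure, binomial read sampling and
    subtype-dependent exponential survival provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
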