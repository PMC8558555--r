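## Mutation-call I/O: a minimal VCF 4.2 dialect and a flat TSV twin.
##
## VCF dialect: one specimen per file; INFO carries GENE, EFFECT, PCHG
## (protein change), PP2, SIFT, CN, PAF (max population allele frequency);
## FORMAT carries DP and AD (ref,alt). The sample column is named
## "<patient>_<component>". Reading goes through vcfR; writing is plain
## text because the dialect is two FORMAT keys wide.

valid_components <- c("stroma", "neoplasm", "normal", "blood")
valid_effects <- c("missense", "nonsense", "frameshift", "inframe_indel",
                   "splice", "synonymous", "other")

split_specimen_id <- function(specimen_id) {
  m <- regmatches(specimen_id,
                  regexec("^(.*)_(stroma|neoplasm|normal|blood)$", specimen_id))[[1]]
  if (length(m) != 3) {
    stop("specimen id '", specimen_id,
         "' does not end in a component label (stroma/neoplasm/normal/blood)")
  }
  list(patient_id = m[2], component = m[3])
}

#' Write mutation calls for one specimen as minimal VCF 4.2
#'
#' @param calls data.frame of mutation calls for one specimen (the column
#'   layout produced by [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  stopifnot(length(unique(calls$specimen_id)) <= 1)
  specimen <- if (nrow(calls) > 0) calls$specimen_id[1] else "specimen"
  fmt_num <- function(x) ifelse(is.na(x), ".",
                                formatC(x, digits = 10, format = "g"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=stromaclone",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Coding effect class">',
    '##INFO=<ID=PCHG,Number=1,Type=String,Description="Protein change (HGVS-p)">',
    '##INFO=<ID=PP2,Number=1,Type=Float,Description="PolyPhen-2 score">',
    '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">',
    '##INFO=<ID=CN,Number=1,Type=Integer,Description="Local copy number">',
    '##INFO=<ID=PAF,Number=1,Type=Float,Description="Max population allele frequency">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read depths (alt: baseQ>=30, mapQ>=30)">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", specimen)
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    info <- sprintf("GENE=%s;EFFECT=%s;PCHG=%s;PP2=%s;SIFT=%s;CN=%d;PAF=%s",
                    calls$gene, calls$effect, calls$protein_change,
                    fmt_num(calls$polyphen), fmt_num(calls$sift),
                    calls$copy_number, fmt_num(calls$pop_af_max))
    sample_col <- sprintf("%d:%d,%d", calls$depth,
                          calls$depth - calls$hq_alt_reads, calls$hq_alt_reads)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD\t%s",
                    calls$chrom, calls$pos, calls$ref, calls$alt, info,
                    sample_col)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write mutation calls as flat TSV
#'
#' The TSV dialect carries exactly the MutationCall columns, one row per
#' variant x specimen; unlike the VCF it can hold several specimens.
#'
#' @param calls data.frame of mutation calls.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

parse_info_field <- function(info, key, numeric = TRUE) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  val <- vapply(m, function(x) if (length(x) == 2) x[2] else ".", character(1))
  val[val %in% c(".", "")] <- NA
  if (numeric) suppressWarnings(as.numeric(val)) else val
}

#' Read mutation calls from VCF or TSV
#'
#' For VCF input, FORMAT `DP`/`AD` map to `depth` and `hq_alt_reads`, and
#' the VAF is computed as `AD_alt / DP` (the dialect has no explicit VAF
#' field); for TSV input an explicit `vaf` column wins and is only
#' recomputed where missing. Missing annotations stay `NA`, never zero.
#'
#' @param path File to read.
#' @param format `"vcf"` or `"tsv"`; default guesses from the extension.
#' @return data.frame of mutation calls (the MutationCall layout).
#' @export
read_calls <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") read_calls_vcf(path) else read_calls_tsv(path)
}

read_calls_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) return(empty_calls())
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  if (ncol(gt) < 2) stop("VCF has no sample column: ", path)
  specimen <- colnames(gt)[2]
  ids <- split_specimen_id(specimen)

  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[, 1])
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  ad_parts <- strsplit(ad, ",", fixed = TRUE)
  bad <- which(lengths(ad_parts) != 2 | is.na(dp))
  if (length(bad) > 0) {
    stop("malformed DP/AD record at data line ", bad[1], " of ", path)
  }
  alt_reads <- vapply(ad_parts, function(x) as.integer(x[2]), integer(1))

  info <- fix$INFO
  cn <- parse_info_field(info, "CN")
  out <- data.frame(
    patient_id = ids$patient_id,
    specimen_id = specimen,
    component = ids$component,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = parse_info_field(info, "GENE", numeric = FALSE),
    protein_change = parse_info_field(info, "PCHG", numeric = FALSE),
    effect = parse_info_field(info, "EFFECT", numeric = FALSE),
    hq_alt_reads = alt_reads,
    depth = dp,
    vaf = ifelse(dp > 0, alt_reads / dp, 0),
    pop_af_max = parse_info_field(info, "PAF"),
    polyphen = parse_info_field(info, "PP2"),
    sift = parse_info_field(info, "SIFT"),
    copy_number = ifelse(is.na(cn), 2L, as.integer(cn)),
    stringsAsFactors = FALSE
  )
  validate_calls(out, path)
}

read_calls_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(out) == 0) return(empty_calls())
  missing_cols <- setdiff(setdiff(call_columns, "vaf"), names(out))
  if (length(missing_cols) > 0) {
    stop("TSV ", path, " lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"vaf" %in% names(out)) out$vaf <- NA_real_
  # explicit VAF wins; recompute only where absent
  miss <- is.na(out$vaf)
  out$vaf[miss] <- ifelse(out$depth[miss] > 0,
                          out$hq_alt_reads[miss] / out$depth[miss], 0)
  out$chrom <- as.character(out$chrom)
  validate_calls(out[, call_columns], path)
}

validate_calls <- function(calls, where = "input") {
  bad_comp <- setdiff(unique(calls$component), valid_components)
  if (length(bad_comp) > 0) {
    stop("unknown component label(s) in ", where, ": ",
         paste(bad_comp, collapse = ", "))
  }
  if (any(calls$pos < 1)) stop("positions must be 1-based (>= 1) in ", where)
  if (any(calls$vaf < 0 | calls$vaf > 1, na.rm = TRUE)) {
    stop("VAF outside [0, 1] in ", where)
  }
  if (any(calls$hq_alt_reads > calls$depth, na.rm = TRUE)) {
    stop("hq_alt_reads exceeds depth in ", where)
  }
  calls
}

#' Bundle retained mutation calls for one specimen
#'
#' @param calls data.frame of mutation calls sharing one patient and
#'   component.
#' @param tcf Tumor cell fraction of the specimen (microimaging estimate),
#'   or `NA` when unknown.
#' @return An object of class `specimen_profile`: patient id, component,
#'   the call table, `tcf`, and `max_vaf` (maximum VAF over members; `NA`
#'   for an empty profile).
#' @export
specimen_profile <- function(calls, tcf = NA_real_) {
  if (nrow(calls) > 0) {
    stopifnot(length(unique(calls$patient_id)) == 1,
              length(unique(calls$component)) == 1)
  }
  structure(list(
    patient_id = if (nrow(calls) > 0) calls$patient_id[1] else NA_character_,
    component = if (nrow(calls) > 0) calls$component[1] else NA_character_,
    calls = calls,
    tcf = tcf,
    max_vaf = if (nrow(calls) > 0) max(calls$vaf) else NA_real_
  ), class = "specimen_profile")
}

#' @export
print.specimen_profile <- function(x, ...) {
  cat(sprintf("<specimen_profile> %s / %s: %d mutations, max VAF %s, TCF %s\n",
              x$patient_id, x$component, nrow(x$calls),
              ifelse(is.na(x$max_vaf), "NA", sprintf("%.3f", x$max_vaf)),
              ifelse(is.na(x$tcf), "NA", sprintf("%.2f", x$tcf))))
  invisible(x)
}

# (chrom, pos, ref, alt) key used for matched-normal subtraction and for
# pairing mutations across components
mutation_key <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF per specimen plus one cohort-wide TSV, the clinical table
#' as CSV, and the ground truth as a JSON sidecar.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$calls$specimen_id)) {
    sub <- sim$calls[sim$calls$specimen_id == sp, , drop = FALSE]
    write_calls_vcf(sub, file.path(dir, paste0(sp, ".vcf")))
  }
  write_calls_tsv(sim$calls, file.path(dir, "calls.tsv"))
  utils::write.csv(sim$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- lapply(sim$truth, function(t) {
    t$mutations <- as.list(t$mutations)
    t
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
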