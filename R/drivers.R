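## Driver-event annotation: a curated PDAC driver-gene list plus a
## two-step harmfulness rule (PolyPhen-2 > 0.85 OR SIFT < 0.05; truncating
## effects harmful regardless of scores). A driver event is a harmful
## mutation in a listed gene; everything else is a passenger event.

#' Load a driver gene list
#'
#' The packaged default list holds the consensus pancreatic-cancer driver
#' genes (KRAS, TP53, CDKN2A, SMAD4, chromatin modifiers, TGF-beta and RNA
#' maturation genes); the file format is one uppercase symbol per line with
#' `#` comments, so the resource is user-editable.
#'
#' @param path Path to a gene-list file; default is the packaged resource.
#' @return Character vector of uppercase gene symbols, class
#'   `driver_gene_list`.
#' @export
driver_gene_list <- function(path = system.file("extdata", "pdac_driver_genes.txt",
                                                package = "stromaclone")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[nzchar(genes)])
  if (length(genes) == 0) stop("driver gene list is empty: ", path)
  structure(genes, class = c("driver_gene_list", "character"))
}

truncating_effects <- c("nonsense", "frameshift", "splice")

#' Classify a mutation's harmfulness
#'
#' Harmful iff PolyPhen-2 score strictly exceeds `pp2_cutoff` OR SIFT score
#' is strictly below `sift_cutoff`. Truncating effects (nonsense,
#' frameshift, splice) are harmful regardless of scores, which PolyPhen-2
#' and SIFT do not produce for them. A missense (or in-frame) mutation with
#' both scores missing is unscorable and treated as not harmful, with a
#' warning.
#'
#' @param effect Effect class vector.
#' @param polyphen,sift Score vectors in `[0, 1]`, `NA` when missing.
#' @param pp2_cutoff,sift_cutoff Rule thresholds.
#' @param warn_unscorable Emit a warning when unscorable missense
#'   mutations are encountered.
#' @return Logical vector, `TRUE` = harmful.
#' @export
#' @examples
#' classify_harmful("nonsense", NA, NA)          # TRUE: truncating
#' classify_harmful("missense", 0.85, NA)        # FALSE: strict >
#' classify_harmful("missense", NA, 0.049)       # TRUE
classify_harmful <- function(effect, polyphen, sift,
                             pp2_cutoff = 0.85, sift_cutoff = 0.05,
                             warn_unscorable = TRUE) {
  truncating <- effect %in% truncating_effects
  by_score <- (!is.na(polyphen) & polyphen > pp2_cutoff) |
              (!is.na(sift) & sift < sift_cutoff)
  unscorable <- !truncating & is.na(polyphen) & is.na(sift)
  if (warn_unscorable && any(unscorable)) {
    warning(sum(unscorable),
            " unscorable non-truncating mutation(s) treated as not harmful")
  }
  truncating | by_score
}

#' Label driver vs passenger events in a filtered profile
#'
#' @param profile A [specimen_profile()] (or raw call data.frame) of
#'   retained mutations.
#' @param genes A [driver_gene_list()] (or plain character vector).
#' @param ... Passed to [classify_harmful()].
#' @return data.frame with the mutation key, `gene`, `in_driver_gene`,
#'   `harmful` and `is_driver_event` (= both).
#' @export
classify_driver_events <- function(profile, genes = driver_gene_list(), ...) {
  calls <- if (inherits(profile, "specimen_profile")) profile$calls else profile
  if (nrow(calls) == 0) {
    return(data.frame(key = character(0), gene = character(0),
                      in_driver_gene = logical(0), harmful = logical(0),
                      is_driver_event = logical(0), stringsAsFactors = FALSE))
  }
  in_list <- toupper(calls$gene) %in% toupper(genes)
  harmful <- classify_harmful(calls$effect, calls$polyphen, calls$sift, ...)
  data.frame(
    key = mutation_key(calls),
    gene = calls$gene,
    in_driver_gene = in_list,
    harmful = harmful,
    is_driver_event = in_list & harmful,
    stringsAsFactors = FALSE
  )
}
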