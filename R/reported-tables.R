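# Accessors for the reported characterization tables bundled with the
# package: the protein-coding gene table (start/stop codons and copy numbers,
# with edited-stop annotations like "CGA(TGA)"), the C-to-U editing transition
# multiset, and the microsatellite class counts for the Cymbidium ensifolium
# multichromosomal mitogenome. They serve as desk-scale inputs for the
# classification and aggregation operations.

reported_table <- function(name) {
  path <- system.file("extdata", name, package = "mitocharter")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reported protein-coding gene table (start/stop codons, copy numbers)
#' @return data.frame: group, gene, length_bp, start_codon, stop_codon,
#'   n_aa, copies
#' @export
reported_pcg_genes <- function() reported_table("cymbidium_pcg_genes.tsv")

#' Reported C-to-U editing transition multiset
#' @return data.frame: ref_codon, edited_codon, n_sites
#' @export
reported_editing_sites <- function() reported_table("cymbidium_editing_sites.tsv")

#' Reported microsatellite class counts
#' @return data.frame: unit_length, canonical_class, n
#' @export
reported_ssr_classes <- function() reported_table("cymbidium_ssr_classes.tsv")

#' Classify a table of editing transitions
#'
#' Runs [classify_edit()] on every row of a (ref_codon, edited_codon[,
#' n_sites]) table, carrying the multiplicities through.
#'
#' @param transitions data.frame with ref_codon, edited_codon and optionally
#'   n_sites
#' @return data.frame of [classify_edit()] rows with an `n_sites` column
#' @export
classify_edit_table <- function(transitions) {
  out <- do.call(rbind, lapply(seq_len(nrow(transitions)), function(i) {
    classify_edit(transitions$ref_codon[i], transitions$edited_codon[i])
  }))
  out$n_sites <- if ("n_sites" %in% names(transitions)) transitions$n_sites
    else rep(1L, nrow(transitions))
  out
}

#' Aggregate a microsatellite class-count table
#'
#' Summarizes a (unit_length, canonical_class, n) table into per-unit totals
#' and shares, the layout used for reporting SSR inventories.
#'
#' @param class_table data.frame with unit_length, canonical_class, n
#' @return list with `by_unit` (named counts monomer..hexamer), `total`,
#'   `unit_share_percent`
#' @export
ssr_class_summary <- function(class_table) {
  stopifnot(all(c("unit_length", "canonical_class", "n") %in%
                  names(class_table)))
  unit_names <- c("monomer", "dimer", "trimer", "tetramer", "pentamer",
                  "hexamer")
  by_unit <- vapply(1:6, function(u)
    sum(class_table$n[class_table$unit_length == u]), 0)
  names(by_unit) <- unit_names
  total <- sum(by_unit)
  list(by_unit = by_unit, total = total,
       unit_share_percent = 100 * by_unit / total)
}
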