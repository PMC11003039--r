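# C-to-U RNA editing: classification of codon transitions by amino-acid
# hydrophobicity effect, summaries of event sets, and a reference-protein
# comparative predictor (edit a genomic C to T wherever doing so reconciles
# the translation with a consensus of reference proteins).

#' Amino-acid hydrophobicity partition
#'
#' The two-class map used to label editing transitions:
#' hydrophobic = \{A, I, L, F, M, P, V, W\}, hydrophilic = the remaining 12
#' amino acids. This is the unique two-class partition consistent with the
#' standard classification of plant mitochondrial editing transitions
#' (e.g. P->S filed as hydrophobic-to-hydrophilic, S->L as
#' hydrophilic-to-hydrophobic, H->Y as hydrophilic-to-hydrophilic).
#'
#' @return named character vector over the 20 amino acids
#' @export
hydrophobicity_map <- function() {
  hydrophobic <- c("A", "I", "L", "F", "M", "P", "V", "W")
  aas <- setdiff(unique(codon_table()), "*")
  stats::setNames(ifelse(aas %in% hydrophobic, "hydrophobic", "hydrophilic"),
                  aas)
}

#' Classify a single C-to-U editing event
#'
#' Validates that `edited_codon` differs from `ref_codon` only by C->T
#' substitutions (one or two positions; plant mitochondrial editing is
#' exclusively C-to-U). Translates both codons under the standard code and
#' assigns the hydrophobicity transition class; a stop gain maps to the
#' `hydrophilic-stop` class. For double edits the reported `codon_position`
#' is the 5'-most edited position.
#'
#' @param ref_codon genomic codon (DNA alphabet)
#' @param edited_codon post-editing codon
#' @return one-row data.frame: ref_codon, edited_codon, codon_position,
#'   n_edited_bases, aa_before, aa_after ("*" for stop), transition_class
#' @export
classify_edit <- function(ref_codon, edited_codon) {
  ref_codon <- toupper(ref_codon); edited_codon <- toupper(edited_codon)
  if (nchar(ref_codon) != 3 || nchar(edited_codon) != 3 ||
      grepl("[^ACGT]", ref_codon) || grepl("[^ACGT]", edited_codon)) {
    stop("codons must be 3 bp over ACGT")
  }
  rb <- strsplit(ref_codon, "")[[1]]
  eb <- strsplit(edited_codon, "")[[1]]
  diff <- which(rb != eb)
  if (length(diff) == 0) stop("edited codon equals the reference codon")
  if (length(diff) > 2 || any(rb[diff] != "C") || any(eb[diff] != "T")) {
    stop("editing type must be C-to-U (C->T substitutions only)")
  }
  gc_map <- codon_table()
  aa_before <- gc_map[[ref_codon]]
  aa_after <- gc_map[[edited_codon]]
  if (aa_before == "*") stop("reference codon is a stop codon")
  hmap <- hydrophobicity_map()
  cls_before <- hmap[[aa_before]]
  transition_class <- if (aa_after == "*") {
    paste0(cls_before, "-stop")
  } else {
    paste0(cls_before, "-", hmap[[aa_after]])
  }
  data.frame(ref_codon = ref_codon, edited_codon = edited_codon,
             codon_position = diff[1], n_edited_bases = length(diff),
             aa_before = aa_before, aa_after = aa_after,
             transition_class = transition_class, stringsAsFactors = FALSE)
}

#' Summarize a set of editing events
#'
#' @param events data.frame of [classify_edit()] rows; an optional `n_sites`
#'   column gives per-row multiplicities (defaults to 1)
#' @return list with `n_events`, `class_counts`, `class_percent`,
#'   `unchanged_percent` (hydrophobicity unchanged), `position_counts`,
#'   `target_aa_counts` (events per post-editing amino acid, "*" = stop),
#'   `stop_gains`
#' @export
summarize_edits <- function(events) {
  classes <- c("hydrophilic-hydrophilic", "hydrophilic-hydrophobic",
               "hydrophilic-stop", "hydrophobic-hydrophilic",
               "hydrophobic-hydrophobic")
  w <- if ("n_sites" %in% names(events)) events$n_sites else
    rep(1L, nrow(events))
  n <- sum(w)
  cls <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(nrow(events))) {
    cls[events$transition_class[i]] <- cls[events$transition_class[i]] + w[i]
  }
  pct <- if (n > 0) 100 * cls / n else stats::setNames(rep(NA_real_, 5), classes)
  pos <- vapply(1:3, function(p) sum(w[events$codon_position == p]), 0)
  names(pos) <- c("pos1", "pos2", "pos3")
  aa <- tapply(w, events$aa_after, sum)
  list(n_events = n,
       class_counts = cls,
       class_percent = pct,
       unchanged_percent = if (n > 0)
         unname(pct["hydrophilic-hydrophilic"] + pct["hydrophobic-hydrophobic"])
       else NA_real_,
       position_counts = pos,
       target_aa_counts = stats::setNames(as.numeric(aa), names(aa)),
       stop_gains = sum(w[events$aa_after == "*"]))
}

# amino-acid identity substitution matrix for global protein alignment
aa_submat <- function() {
  if (is.null(.mc_cache$aa_submat)) {
    letters <- c(setdiff(unique(codon_table()), "*"), "*", "X")
    m <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1
    .mc_cache$aa_submat <- m
  }
  .mc_cache$aa_submat
}

# per-codon aligned residue of `ref` after global alignment to `trans`
aligned_reference_residues <- function(trans, ref, gap_open, gap_ext) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(trans), Biostrings::AAString(ref),
    type = "global", substitutionMatrix = aa_submat(),
    gapOpening = gap_open, gapExtension = gap_ext)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- rep(NA_character_, nchar(trans))
  i <- 0L
  for (col in seq_along(p)) {
    if (p[col] != "-") {
      i <- i + 1L
      if (s[col] != "-") out[i] <- s[col]
    }
  }
  out
}

#' Predict C-to-U editing sites from reference proteins
#'
#' The translated CDS is globally aligned to each reference protein (identity
#' scoring, affine gaps: match 1, mismatch -1, open -2, extend -0.5). At
#' codons where the unedited residue disagrees with the reference consensus,
#' the minimal C->T edit(s) at codon positions 1/2 whose translation matches
#' the consensus are proposed; a proposal is accepted when the fraction of
#' references supporting the edited residue is at least `cutoff`. Silent
#' (position-3) edits are invisible to this comparison and are never
#' proposed.
#'
#' @param cds single in-frame CDS (DNA string), optionally named
#' @param reference_proteins character vector of reference protein sequences
#' @param cutoff minimum reference support fraction (default 0.5)
#' @param gap_open,gap_ext affine gap penalties for the protein alignment
#' @return data.frame of predicted events ([classify_edit()] columns plus
#'   `gene_id`, `codon_index` 0-based, `support`)
#' @export
predict_edit_sites <- function(cds, reference_proteins, cutoff = 0.5,
                               gap_open = 2, gap_ext = 0.5) {
  stopifnot(length(reference_proteins) >= 1)
  gene_id <- if (!is.null(names(cds))) names(cds)[1] else "cds"
  cds <- toupper(cds[[1]])
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  if (grepl("[^ACGT]", cds)) stop("CDS must be over ACGT")
  codons <- split_codons(cds)
  gc_map <- codon_table()
  trans_full <- gc_map[codons]
  n_codon <- length(codons)
  has_stop <- trans_full[n_codon] == "*"
  trans <- paste0(trans_full[if (has_stop) -n_codon else TRUE], collapse = "")
  if (grepl("\\*", trans)) stop("untranslatable CDS: internal stop codon")
  refs <- toupper(gsub("\\*$", "", reference_proteins))
  ref_res <- lapply(refs, aligned_reference_residues, trans = trans,
                    gap_open = gap_open, gap_ext = gap_ext)
  events <- NULL
  for (i in seq_len(nchar(trans))) {
    obs <- vapply(ref_res, `[[`, "", i)
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) next
    tab <- sort(table(obs), decreasing = TRUE)
    consensus <- names(tab)[tab == max(tab)]
    consensus <- sort(consensus)[1]
    if (consensus == substr(trans, i, i)) next
    codon <- codons[i]
    cand <- list()
    for (pos in 1:2) {                       # single edits first (minimal)
      if (substr(codon, pos, pos) != "C") next
      new <- codon; substr(new, pos, pos) <- "T"
      if (gc_map[[new]] == consensus) cand[[length(cand) + 1]] <- new
    }
    if (length(cand) == 0 && substr(codon, 1, 1) == "C" &&
        substr(codon, 2, 2) == "C") {        # then the double edit
      new <- codon; substr(new, 1, 1) <- "T"; substr(new, 2, 2) <- "T"
      if (gc_map[[new]] == consensus) cand[[length(cand) + 1]] <- new
    }
    if (length(cand) == 0) next
    new <- cand[[1]]
    support <- mean(vapply(ref_res, function(r)
      !is.na(r[i]) && r[i] == gc_map[[new]], TRUE))
    if (support < cutoff) next
    ev <- classify_edit(codon, new)
    ev$gene_id <- gene_id
    ev$codon_index <- i - 1L
    ev$support <- support
    events <- rbind(events, ev)
  }
  if (is.null(events)) {
    events <- cbind(classify_edit("TCA", "TTA"), gene_id = "x",
                    codon_index = 0L, support = 0)[0, ]
  }
  events
}
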