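# Intracellular DNA-transfer detection: homologous fragments between genome
# pairs (mitochondrial vs plastid, mitochondrial vs nuclear), overlap-merged
# coverage on the query axis, gene-containment reports, and synteny blocks
# for collinearity/dot-plot export.

#' Find homologous fragments between two genomes
#'
#' Seeded comparison (word size `k`) across all chromosome pairs, both
#' strands. Reported fragments satisfy all three screening thresholds
#' (identity, length, Karlin-Altschul E-value with search space = product of
#' total genome lengths). Deterministic ordering by query then subject
#' coordinate.
#'
#' @param genomeA,genomeB [mc_genome()] objects or named character vectors
#'   (query and subject)
#' @param min_identity minimum alignment identity ("matching rate", default
#'   0.70)
#' @param min_len minimum fragment length in alignment columns (default 30)
#' @param max_e maximum E-value (default 1e-5)
#' @param k seed word size (default 7)
#' @param min_cov minimum seed coverage of a chained span (default 0.05 so
#'   that 70%-identity fragments remain seedable)
#' @return data.frame of `HomologyFragment`s: query_chrom, query_start,
#'   query_end, subject_chrom, subject_start, subject_end, orientation,
#'   length_bp, identity, e_value
#' @export
find_homologous_fragments <- function(genomeA, genomeB, min_identity = 0.70,
                                      min_len = 30, max_e = 1e-5, k = 7,
                                      min_cov = 0.05) {
  qa <- genome_seqs(genomeA); qb <- genome_seqs(genomeB)
  stopifnot(length(qa) > 0, length(qb) > 0)
  m <- local_matches(qa, qb, k = k, max_gap = 500, band = 50, min_seeds = 2,
                     min_cov = min_cov,
                     min_span = max(as.integer(k) + 1L, min_len - 12L),
                     trim_break_even = max(0.5, min_identity - 0.1),
                     both_strands = TRUE, self = FALSE)
  m <- m[m$matched_length_bp >= min_len & m$identity_fraction >= min_identity &
           m$e_value <= max_e, , drop = FALSE]
  out <- data.frame(
    query_chrom = m$read_id, query_start = m$read_start,
    query_end = m$read_end, subject_chrom = m$target_id,
    subject_start = m$target_start, subject_end = m$target_end,
    orientation = m$orientation, length_bp = m$matched_length_bp,
    identity = m$identity_fraction, e_value = m$e_value,
    stringsAsFactors = FALSE)
  out <- out[order(out$query_chrom, out$query_start, out$subject_chrom,
                   out$subject_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap-merged coverage of homologous fragments on the query genome
#'
#' Overlapping query intervals are merged (union) before summing, so nested
#' or duplicated subject hits do not double-count.
#'
#' @param fragments data.frame from [find_homologous_fragments()]
#' @param genome the query [mc_genome()] or named character vector
#' @return list with `per_chromosome` (chromosome, length, covered_bp,
#'   fraction), `covered_bp`, `fraction`, `unmerged_bp` (plain sum of
#'   fragment lengths, for comparison)
#' @export
merged_coverage <- function(fragments, genome) {
  seqs <- genome_seqs(genome)
  lens <- nchar(seqs)
  if (nrow(fragments)) {
    if (!all(fragments$query_chrom %in% names(seqs))) {
      stop("fragment on unknown chromosome")
    }
    if (any(fragments$query_start < 0) ||
        any(fragments$query_end > lens[fragments$query_chrom])) {
      stop("fragment coordinates out of chromosome range")
    }
  }
  per <- data.frame(chromosome = names(seqs), length = as.integer(lens),
                    covered_bp = 0L, fraction = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per))) {
    f <- fragments[fragments$query_chrom == per$chromosome[i], , drop = FALSE]
    if (nrow(f) == 0) next
    iv <- IRanges::reduce(IRanges::IRanges(start = f$query_start + 1L,
                                           end = f$query_end))
    per$covered_bp[i] <- sum(IRanges::width(iv))
    per$fraction[i] <- per$covered_bp[i] / per$length[i]
  }
  list(per_chromosome = per,
       covered_bp = sum(per$covered_bp),
       fraction = sum(per$covered_bp) / sum(per$length),
       unmerged_bp = if (nrow(fragments)) sum(fragments$query_end -
                                                fragments$query_start) else 0L)
}

#' Genes fully contained in merged homologous regions
#'
#' A gene is reported iff its full span lies within a single overlap-merged
#' homologous region on its chromosome. The reported identity is the best
#' identity among fragments fully containing the gene, falling back to the
#' best among overlapping fragments when containment only holds for the
#' merged region.
#'
#' @param fragments data.frame from [find_homologous_fragments()]
#' @param gene_models data.frame with gene_id, chrom, start, end (0-based
#'   half-open, on the query genome)
#' @return data.frame: gene_id, chrom, start, end, identity
#' @export
genes_fully_contained <- function(fragments, gene_models) {
  out <- NULL
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    f <- fragments[fragments$query_chrom == g$chrom, , drop = FALSE]
    if (nrow(f) == 0) next
    merged <- IRanges::reduce(IRanges::IRanges(start = f$query_start + 1L,
                                               end = f$query_end))
    hit <- IRanges::start(merged) <= g$start + 1L & IRanges::end(merged) >= g$end
    if (!any(hit)) next
    containing <- f$query_start <= g$start & f$query_end >= g$end
    identity <- if (any(containing)) max(f$identity[containing]) else {
      overl <- f$query_start < g$end & f$query_end > g$start
      max(f$identity[overl])
    }
    out <- rbind(out, data.frame(gene_id = g$gene_id, chrom = g$chrom,
                                 start = g$start, end = g$end,
                                 identity = identity, stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' Synteny blocks between two genomes for collinearity/dot-plot export
#'
#' Homologous fragments of at least `min_block` bp with orientation labels
#' ("forward"/"reverse") suitable for dot-plot rendering, sorted by query
#' then subject coordinate. Larger seeds are used than for short-fragment
#' screening since blocks are long.
#'
#' @param genomeA,genomeB [mc_genome()] objects or named character vectors
#' @param min_block minimum block length (default 300)
#' @param min_identity minimum block identity (default 0.70)
#' @param k seed word size (default 13)
#' @return data.frame like [find_homologous_fragments()] with orientation
#'   "forward"/"reverse"
#' @export
synteny_blocks <- function(genomeA, genomeB, min_block = 300,
                           min_identity = 0.70, k = 13) {
  f <- find_homologous_fragments(genomeA, genomeB, min_identity = min_identity,
                                 min_len = min_block, max_e = 1e-5, k = k,
                                 min_cov = 0.05)
  f[order(f$query_chrom, f$query_start, f$subject_chrom, f$subject_start), ,
    drop = FALSE]
}
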