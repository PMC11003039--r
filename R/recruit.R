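# Iterative seed-extension recruitment of mitochondrial long reads from a
# mixed read pool. Reads matching conserved mitochondrial core genes become
# candidates; the best candidates seed an iterative overlap-based expansion
# (minimum overlap 1 kb at >= 70% identity) that repeats to a fixpoint.

#' Local matches of a single read against a set of target sequences
#'
#' Thin per-read interface over [local_matches()] (k-mer anchored chaining
#' with gapped extension; both strands; identity = matches / alignment
#' columns).
#'
#' @param read single DNA string (optionally named)
#' @param targets named character vector of target sequences
#' @param k seed length (>= 11 recommended for read-scale matching)
#' @param band diagonal band width
#' @param max_gap chaining gap limit
#' @return data.frame of local matches (see [local_matches()])
#' @export
estimate_local_matches <- function(read, targets, k = 15, band = 50,
                                   max_gap = 500) {
  if (length(read) == 0 || length(targets) == 0) return(empty_matches())
  if (is.null(names(read))) names(read) <- "read"
  local_matches(read, targets, k = k, band = band, max_gap = max_gap)
}

#' Select candidate mitochondrial reads by core-gene matching
#'
#' A read is a candidate iff some local match against a core gene is longer
#' than `min_match_bp` (alignment columns).
#'
#' @param reads named character vector of reads
#' @param core_genes named character vector of conserved core-gene sequences
#' @param min_match_bp minimum match length in bp (exclusive; default 50)
#' @param ... passed to [local_matches()]
#' @return list with `candidates` (read ids) and `matches` (the gene-match
#'   table used for ranking)
#' @export
select_candidates <- function(reads, core_genes, min_match_bp = 50, ...) {
  stopifnot(length(core_genes) > 0)
  m <- local_matches(reads, core_genes, ...)
  m <- m[m$matched_length_bp > min_match_bp, , drop = FALSE]
  list(candidates = sort(unique(m$read_id)), matches = m)
}

#' Rank candidate reads for seeding
#'
#' Ranking key: (number of distinct core genes matched, total
#' identity-weighted matched bp), descending, with a deterministic tie-break
#' on read id. With `cover = TRUE` the ranked list is greedily reduced to
#' reads that add at least one core gene not yet covered — one seed per
#' chromosome-resident gene group, which a multichromosomal genome needs.
#'
#' @param matches gene-match table from [select_candidates()]
#' @param cover return a greedy core-gene covering subset
#' @return character vector of read ids, best seed first
#' @export
choose_seed <- function(matches, cover = FALSE) {
  if (is.null(matches) || nrow(matches) == 0) {
    stop("no seed: candidate set is empty")
  }
  by_read <- split(matches, matches$read_id)
  stats_df <- data.frame(
    read_id = names(by_read),
    n_genes = vapply(by_read, function(d) length(unique(d$target_id)), 0L),
    wbp = vapply(by_read, function(d)
      sum(d$identity_fraction * d$matched_length_bp), 0),
    stringsAsFactors = FALSE
  )
  ord <- order(-stats_df$n_genes, -stats_df$wbp, stats_df$read_id)
  ranked <- stats_df$read_id[ord]
  if (!cover) return(ranked)
  seen <- character(0)
  keep <- character(0)
  for (r in ranked) {
    gs <- unique(matches$target_id[matches$read_id == r])
    if (length(setdiff(gs, seen))) {
      keep <- c(keep, r)
      seen <- union(seen, gs)
    }
  }
  keep
}

#' Iterative overlap recruitment from a seed set
#'
#' At each iteration, any unrecruited read with a local match to a recruited
#' read of at least `min_overlap_bp` alignment columns and `min_identity`
#' identity is added. Matching is incremental: each iteration compares the
#' remaining pool only against the reads added in the previous iteration, so
#' the result is independent of insertion order. Stops at a fixpoint (an
#' iteration adding nothing) or after `max_iter` iterations.
#'
#' @param reads named character vector of all reads
#' @param seed_set read ids to start from (must be a subset of `reads`)
#' @param min_overlap_bp minimum overlap (alignment columns; default 1000)
#' @param min_identity minimum identity over the overlap (default 0.70)
#' @param max_iter iteration cap (default 50)
#' @param k,band,max_gap engine parameters, see [local_matches()]
#' @return a `recruitment_state` list: `recruited` (read ids), `iterations`
#'   (data.frame iter/n_added), `stop_reason` ("fixpoint" or "max_iter"),
#'   `added` (per-iteration id lists)
#' @export
recruit_iteratively <- function(reads, seed_set, min_overlap_bp = 1000,
                                min_identity = 0.70, max_iter = 50,
                                k = 15, band = 50, max_gap = 500) {
  if (max_iter <= 0) stop("max_iter must be positive")
  if (!all(seed_set %in% names(reads))) {
    stop("seed_set must be a subset of the read pool")
  }
  recruited <- unique(seed_set)
  newly <- recruited
  iters <- data.frame(iter = integer(0), n_added = integer(0))
  added <- list()
  stop_reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    pool <- setdiff(names(reads), recruited)
    if (length(pool) == 0 || length(newly) == 0) {
      iters <- rbind(iters, data.frame(iter = it, n_added = 0L))
      added[[it]] <- character(0)
      stop_reason <- "fixpoint"
      break
    }
    m <- local_matches(reads[pool], reads[newly], k = k, band = band,
                       max_gap = max_gap)
    ok <- m$matched_length_bp >= min_overlap_bp &
      m$identity_fraction >= min_identity
    new_ids <- sort(unique(m$read_id[ok]))
    iters <- rbind(iters, data.frame(iter = it, n_added = length(new_ids)))
    added[[it]] <- new_ids
    if (length(new_ids) == 0) { stop_reason <- "fixpoint"; break }
    recruited <- c(recruited, new_ids)
    newly <- new_ids
  }
  structure(list(recruited = recruited, iterations = iters,
                 stop_reason = stop_reason, added = added,
                 params = list(min_overlap_bp = min_overlap_bp,
                               min_identity = min_identity, k = k)),
            class = "recruitment_state")
}

#' @export
print.recruitment_state <- function(x, ...) {
  cat(sprintf("recruitment_state: %d reads recruited in %d iteration(s), %s\n",
              length(x$recruited), nrow(x$iterations), x$stop_reason))
  invisible(x)
}

#' Read-level recall and precision of a recruitment against origin labels
#'
#' @param state a `recruitment_state`
#' @param origins origins table from [simulate_reads()]
#' @param positive_label genome label counted as true positives (default
#'   "mito")
#' @return list with `recall`, `precision`, `tp`, `fp`, `fn`
#' @export
recruitment_scores <- function(state, origins, positive_label = "mito") {
  truth <- origins$read_id[origins$genome == positive_label]
  tp <- length(intersect(state$recruited, truth))
  fp <- length(setdiff(state$recruited, truth))
  fn <- length(setdiff(truth, state$recruited))
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       tp = tp, fp = fp, fn = fn)
}
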