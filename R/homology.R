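# Shared local-similarity layer over the compiled seed-chain-extend engine.
# All higher-level detectors (read recruitment, dispersed repeats,
# interorganellar homologous fragments, synteny blocks) call local_matches().

# Karlin-Altschul lambda for the +1/-2 scoring actually used by the engine,
# at uniform base composition: solves 0.25*e^lambda + 0.75*e^(-2*lambda) = 1.
ka_lambda <- function() {
  if (is.null(.mc_cache$lambda)) {
    f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
    .mc_cache$lambda <- stats::uniroot(f, c(1e-4, 5), tol = 1e-12)$root
  }
  .mc_cache$lambda
}

# Ungapped K for +1/-2 (documented constant, standard tabulated value).
.KA_K <- 0.621

#' Karlin-Altschul E-value of a local match
#'
#' @param score raw score: `matches - 2*(columns - matches)` under the
#'   engine's +1 match / -2 mismatch-or-gap scoring
#' @param m,n search-space lengths (total query x total subject bases)
#' @return expected number of chance matches at least this strong
#' @export
karlin_altschul_evalue <- function(score, m, n) {
  .KA_K * as.numeric(m) * as.numeric(n) * exp(-ka_lambda() * score)
}

#' Local similarity matches between two sequence pools
#'
#' k-mer anchored chaining with gapped extension. Reports each maximal chained
#' match with its matched length (alignment columns) and identity
#' (matches / alignment columns, gap columns included). Both strands are
#' searched; ambiguity codes break seeds and count as mismatches.
#'
#' @param queries,targets named character vectors of DNA sequences
#' @param k seed length (default 15)
#' @param max_gap chaining gap limit in bp (default 500)
#' @param band diagonal band width for chaining/extension (default 50)
#' @param min_seeds minimum seeds per chain (default 2)
#' @param min_cov minimum seed coverage of the chained span (default 0.10)
#' @param min_span minimum chained seed span in bp before extension
#'   (default `k + 1`)
#' @param trim_break_even break-even identity of the ungapped
#'   extension/trim scoring (mismatch penalty = t/(1-t)); detectors set this
#'   just below their identity threshold so match boundaries neither bleed
#'   into flanking sequence nor clip low-identity ends (default 0.5)
#' @param both_strands search the reverse strand too
#' @param self treat `queries`/`targets` as the same pool: each unordered pair
#'   is compared once and the trivial self-diagonal is suppressed
#' @return data.frame with one row per local match: `read_id`, `target_id`,
#'   intervals (0-based half-open, forward-strand coordinates), `orientation`
#'   ("forward"/"reverse"), `matched_length_bp` (alignment columns),
#'   `identity_fraction`, `score`, `e_value`, `n_seeds`
#' @export
local_matches <- function(queries, targets, k = 15, max_gap = 500, band = 50,
                          min_seeds = 2, min_cov = 0.10, min_span = NULL,
                          trim_break_even = 0.5, both_strands = TRUE,
                          self = FALSE) {
  stopifnot(trim_break_even >= 0.25, trim_break_even < 1)
  if (length(queries) == 0 || length(targets) == 0) {
    return(empty_matches())
  }
  if (is.null(names(queries))) names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  if (is.null(min_span)) min_span <- k + 1L
  raw <- cpp_match_pool(unname(queries), unname(targets),
                        as.integer(k), as.integer(max_gap), as.integer(band),
                        as.integer(min_seeds), as.integer(min_span),
                        as.numeric(min_cov),
                        trim_break_even / (1 - trim_break_even),
                        both_strands, self)
  if (nrow(raw) == 0) return(empty_matches())
  mm <- raw$columns - raw$matches
  score <- raw$matches - 2 * mm
  df <- data.frame(
    read_id = names(queries)[raw$qid],
    target_id = names(targets)[raw$tid],
    read_start = raw$q_start, read_end = raw$q_end,
    target_start = raw$t_start, target_end = raw$t_end,
    orientation = ifelse(raw$strand > 0, "forward", "reverse"),
    matched_length_bp = raw$columns,
    identity_fraction = raw$matches / pmax(raw$columns, 1L),
    matches = raw$matches,
    score = score,
    e_value = karlin_altschul_evalue(score, sum(nchar(queries)),
                                     sum(nchar(targets))),
    n_seeds = raw$n_seeds,
    stringsAsFactors = FALSE
  )
  if (self) df <- drop_mirror_matches(df)
  df <- dedup_matches(df)
  df[order(df$read_id, df$read_start, df$target_id, df$target_start), ,
     drop = FALSE]
}

empty_matches <- function() {
  data.frame(read_id = character(0), target_id = character(0),
             read_start = integer(0), read_end = integer(0),
             target_start = integer(0), target_end = integer(0),
             orientation = character(0), matched_length_bp = integer(0),
             identity_fraction = numeric(0), matches = integer(0),
             score = numeric(0), e_value = numeric(0), n_seeds = integer(0),
             stringsAsFactors = FALSE)
}

# In self-comparison, a hit between intervals (a, b) of the same pool can be
# reported again as (b, a) (reverse strand within one sequence, or symmetric
# cluster split). Keep the lexicographically smaller representation.
drop_mirror_matches <- function(df) {
  if (nrow(df) == 0) return(df)
  same <- df$read_id == df$target_id
  mirrored <- same & (df$read_start > df$target_start |
                        (df$read_start == df$target_start &
                           df$read_end > df$target_end))
  flip <- df[mirrored, , drop = FALSE]
  if (nrow(flip)) {
    tmp <- flip$read_start; flip$read_start <- flip$target_start
    flip$target_start <- tmp
    tmp <- flip$read_end; flip$read_end <- flip$target_end; flip$target_end <- tmp
    df[mirrored, ] <- flip
  }
  # drop residual self-overlaps (an interval matching itself reversed)
  trivial <- same & df$read_start < df$target_end & df$target_start < df$read_end &
    pmin(df$read_end, df$target_end) - pmax(df$read_start, df$target_start) >
      0.5 * df$matched_length_bp
  df <- df[!trivial, , drop = FALSE]
  df[!duplicated(df[, c("read_id", "target_id", "read_start", "read_end",
                        "target_start", "target_end", "orientation")]), ,
     drop = FALSE]
}

# Collapse near-duplicate reports of one region pair (chain splits), keeping
# the highest-scoring record among matches with >= 90% reciprocal overlap on
# both axes.
dedup_matches <- function(df) {
  if (nrow(df) <= 1) return(df)
  df <- df[order(-df$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  key <- paste(df$read_id, df$target_id, df$orientation)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-1]) {
      i <- idx[a]
      for (b in seq_len(a - 1)) {
        j <- idx[b]
        if (!keep[j]) next
        ovq <- min(df$read_end[i], df$read_end[j]) -
          max(df$read_start[i], df$read_start[j])
        ovt <- min(df$target_end[i], df$target_end[j]) -
          max(df$target_start[i], df$target_start[j])
        li <- df$read_end[i] - df$read_start[i]
        if (ovq > 0.9 * li && ovt > 0.9 * li) { keep[i] <- FALSE; break }
      }
    }
  }
  df[keep, , drop = FALSE]
}
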