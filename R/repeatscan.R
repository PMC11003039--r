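# Repeat detection: microsatellites (MISA semantics: maximal perfect runs of
# 1-6 bp units above per-unit copy minima), tandem arrays with unit > 6 bp
# (TRF-style +2/-7 weights, adjacent-copy percent match), and dispersed
# (forward/palindromic) repeats via seeded self-comparison.

misa_default_params <- c(`1` = 10, `2` = 5, `3` = 4, `4` = 3, `5` = 3, `6` = 3)

# is motif a repetition of a shorter unit?
motif_is_periodic <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif) return(TRUE)
  }
  FALSE
}

rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n), function(i) {
    paste0(substr(x, i, n), substr(x, 1, i - 1))
  }, "")
}

#' Canonical microsatellite class of a motif
#'
#' The class is formed from the lexicographic minima over all rotations of
#' the motif and of its reverse complement (sequence complementarity
#' considered), rendered as `"X/Y"` with the smaller string first, e.g.
#' `GT -> "AC/GT"`, `TTTG -> "AAAC/GTTT"`, `AT -> "AT/AT"`.
#'
#' @param motif repeat unit of length 1-6
#' @return canonical class string
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  if (nchar(motif) < 1 || nchar(motif) > 6 || grepl("[^ACGT]", motif)) {
    stop("motif must be 1-6 bp over ACGT")
  }
  a <- min(rotations(motif))
  b <- min(rotations(rc(motif)))
  paste0(min(a, b), "/", max(a, b))
}

#' Find microsatellites (SSRs)
#'
#' Maximal perfect tandem runs of 1-6 bp units with at least the per-unit
#' minimum number of complete copies (defaults: 1-10 2-5 3-4 4-3 5-3 6-3).
#' Runs whose motif is itself a repetition of a shorter unit are reported at
#' the shortest unit only. Ambiguity codes break runs. Circular chromosomes
#' are scanned with an origin-spanning window and wrap hits are deduplicated.
#'
#' @param seq single DNA string
#' @param params named vector: minimum copies per unit length 1-6
#' @param chrom chromosome name recorded in the output
#' @param circular scan across the origin as well
#' @return data.frame: chromosome, start, end (0-based half-open; end may
#'   exceed the sequence length for origin-spanning runs), motif,
#'   canonical_class, unit_length, copy_number
#' @export
find_ssrs <- function(seq, params = misa_default_params, chrom = "chr",
                      circular = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  scan_linear <- function(s) {
    chars <- strsplit(s, "")[[1]]
    valid <- chars %in% c("A", "C", "G", "T")
    out <- NULL
    for (u in 1:6) {
      minc <- params[[as.character(u)]]
      m <- length(chars) - u
      if (m < 1) next
      eq <- chars[seq_len(m)] == chars[seq_len(m) + u] &
        valid[seq_len(m)] & valid[seq_len(m) + u]
      r <- rle(eq)
      pos <- cumsum(c(1, r$lengths))
      for (j in which(r$values)) {
        i <- pos[j]               # 1-based position of first period match
        runlen <- r$lengths[j] + u  # total perfect-run length
        copies <- runlen %/% u
        if (copies < minc) next
        motif <- substr(s, i, i + u - 1)
        if (grepl("[^ACGT]", motif) || motif_is_periodic(motif)) next
        out <- rbind(out, data.frame(
          chromosome = chrom, start = i - 1L, end = i - 1L + u * copies,
          motif = motif, canonical_class = canonical_motif(motif),
          unit_length = u, copy_number = copies, stringsAsFactors = FALSE))
      }
    }
    out
  }
  out <- scan_linear(seq)
  if (circular && n > 1) {
    w <- min(n, 400L)
    wrap <- paste0(substr(seq, n - w + 1, n), substr(seq, 1, w))
    wout <- scan_linear(wrap)
    if (!is.null(wout)) {
      wout$start <- wout$start + (n - w)
      wout$end <- wout$end + (n - w)
      wout <- wout[wout$start < n & wout$end > n, , drop = FALSE] # spans origin
      out <- rbind(out, wout)
    }
  }
  if (is.null(out)) {
    out <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      canonical_class = character(0), unit_length = integer(0),
                      copy_number = integer(0), stringsAsFactors = FALSE)
  } else {
    # drop runs contained in an origin-spanning run of the same unit
    out <- out[!duplicated(out[, c("start", "unit_length")]), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))) {
        if (i == j || out$unit_length[i] != out$unit_length[j]) next
        si <- out$start[i]; ei <- out$end[i]
        sj <- out$start[j] %% n; ej <- sj + (out$end[j] - out$start[j])
        if (ej > n && (si + n) >= sj && (ei + n) <= ej) keep[i] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$start, out$unit_length), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Find tandem repeats with unit length > 6 bp
#'
#' Candidate periods are scored position-by-position against the previous
#' copy (+2 match / -7 mismatch, the TRF match/mismatch weights); maximal
#' positive-scoring segments become arrays. `percent_match` is the
#' adjacent-copy agreement (matches / compared positions). Arrays better
#' explained by a microsatellite-range period (1-6 bp) are dropped;
#' overlapping reports are merged to the highest-scoring period. Copy numbers
#' may be fractional and are reported to one decimal.
#'
#' @param seq single DNA string
#' @param min_unit minimum unit length (default 7)
#' @param max_unit maximum candidate period (default 120)
#' @param min_match minimum adjacent-copy match fraction (default 0.68)
#' @param min_score minimum array alignment score under the +2/-7 weights
#'   (default 50, the TRF minscore); suppresses chance short duplications
#' @param chrom chromosome name recorded in the output
#' @param circular scan across the origin as well
#' @return data.frame: chromosome, start, end, unit_length, copy_number,
#'   percent_match, score
#' @export
find_tandem_repeats <- function(seq, min_unit = 7, max_unit = 120,
                                min_match = 0.68, min_score = 50,
                                chrom = "chr", circular = FALSE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_unit) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), unit_length = integer(0),
                      copy_number = numeric(0), percent_match = numeric(0),
                      score = integer(0), stringsAsFactors = FALSE))
  }
  raw <- cpp_tandem_scan(seq, as.integer(min_unit), as.integer(max_unit),
                         min_match, 2L)
  raw <- raw[!raw$ssr_like & raw$score >= min_score, , drop = FALSE]
  if (circular && n > 2 * min_unit) {
    w <- min(n, 3L * max_unit)
    wrap <- paste0(substr(seq, n - w + 1, n), substr(seq, 1, w))
    wr <- cpp_tandem_scan(wrap, as.integer(min_unit), as.integer(max_unit),
                          min_match, 2L)
    wr <- wr[!wr$ssr_like & wr$score >= min_score, , drop = FALSE]
    wr$start <- wr$start + (n - w); wr$end <- wr$end + (n - w)
    wr <- wr[wr$start < n & wr$end > n, , drop = FALSE]
    raw <- rbind(raw, wr)
  }
  out <- data.frame(
    chromosome = rep(chrom, nrow(raw)), start = raw$start, end = raw$end,
    unit_length = raw$period,
    copy_number = round((raw$end - raw$start) / raw$period, 1),
    percent_match = raw$matches / pmax(raw$compared, 1L),
    score = raw$score, stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find dispersed (forward/palindromic) repeats in a chromosome set
#'
#' Seeded self-comparison (default word size 7) within and between
#' chromosomes on both strands. The trivial self-diagonal and mirror
#' duplicates are excluded; hits mostly covered by a supplied tandem/SSR
#' interval set are excluded ("remove tandem duplication"); records are
#' filtered on length, identity and Karlin-Altschul E-value with search space
#' = product of total genome lengths.
#'
#' @param chromosomes named character vector of chromosome sequences
#' @param min_len minimum repeat length (default 27)
#' @param min_identity minimum identity (default 0.90)
#' @param max_e maximum E-value (default 1e-5)
#' @param k seed word size (default 7)
#' @param exclude optional data.frame of intervals (chromosome, start, end)
#'   to exclude (e.g. tandem arrays and SSRs)
#' @return data.frame of `DispersedRecord`s: chrom_1, start_1, end_1,
#'   chrom_2, start_2, end_2, orientation ("forward"/"palindromic"),
#'   length_bp, identity, e_value
#' @export
find_dispersed_repeats <- function(chromosomes, min_len = 27,
                                   min_identity = 0.90, max_e = 1e-5, k = 7,
                                   exclude = NULL) {
  stopifnot(length(chromosomes) >= 1)
  m <- local_matches(chromosomes, chromosomes, k = k, max_gap = 500, band = 50,
                     min_seeds = 2, min_cov = 0.20,
                     min_span = max(as.integer(k) + 1L, min_len - 12L),
                     trim_break_even = max(0.5, min_identity - 0.1),
                     both_strands = TRUE, self = TRUE)
  m <- m[m$matched_length_bp >= min_len & m$identity_fraction >= min_identity &
           m$e_value <= max_e, , drop = FALSE]
  if (!is.null(exclude) && nrow(m) > 0 && nrow(exclude) > 0) {
    cov_frac <- function(chrom, s, e) {
      xs <- exclude[exclude$chromosome == chrom, , drop = FALSE]
      if (nrow(xs) == 0) return(0)
      a <- pmax(xs$start, s); b <- pmin(xs$end, e)
      ok <- b > a
      if (!any(ok)) return(0)
      iv <- IRanges::IRanges(start = a[ok] + 1L, end = b[ok])
      sum(IRanges::width(IRanges::reduce(iv))) / (e - s)
    }
    drop <- vapply(seq_len(nrow(m)), function(i) {
      cov_frac(m$read_id[i], m$read_start[i], m$read_end[i]) >= 0.8 ||
        cov_frac(m$target_id[i], m$target_start[i], m$target_end[i]) >= 0.8
    }, TRUE)
    m <- m[!drop, , drop = FALSE]
  }
  out <- data.frame(
    chrom_1 = m$read_id, start_1 = m$read_start, end_1 = m$read_end,
    chrom_2 = m$target_id, start_2 = m$target_start, end_2 = m$target_end,
    orientation = ifelse(m$orientation == "forward", "forward", "palindromic"),
    length_bp = m$matched_length_bp, identity = m$identity_fraction,
    e_value = m$e_value, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize repeat records per class and chromosome
#'
#' @param ssrs data.frame from [find_ssrs()] (possibly over many chromosomes)
#' @param tandems data.frame from [find_tandem_repeats()]
#' @param dispersed data.frame from [find_dispersed_repeats()]
#' @param bin_width histogram bin width for dispersed lengths (default 10,
#'   bins 20-29, 30-39, ...)
#' @return list with `totals` (ssr/tandem/dispersed/all), `ssr_by_unit`,
#'   `ssr_by_class` (canonical classes within unit length),
#'   `ssr_per_chromosome`, `dispersed_by_orientation`,
#'   `dispersed_length_histogram`
#' @export
repeat_summary <- function(ssrs = NULL, tandems = NULL, dispersed = NULL,
                           bin_width = 10) {
  n_ssr <- if (is.null(ssrs)) 0L else nrow(ssrs)
  n_tan <- if (is.null(tandems)) 0L else nrow(tandems)
  n_disp <- if (is.null(dispersed)) 0L else nrow(dispersed)
  unit_names <- c("monomer", "dimer", "trimer", "tetramer", "pentamer",
                  "hexamer")
  by_unit <- stats::setNames(integer(6), unit_names)
  by_class <- NULL
  per_chrom <- NULL
  if (n_ssr > 0) {
    t_unit <- table(factor(ssrs$unit_length, levels = 1:6))
    by_unit <- stats::setNames(as.integer(t_unit), unit_names)
    by_class <- as.data.frame(table(unit_length = ssrs$unit_length,
                                    canonical_class = ssrs$canonical_class),
                              stringsAsFactors = FALSE)
    by_class <- by_class[by_class$Freq > 0, , drop = FALSE]
    names(by_class)[3] <- "n"
    by_class$unit_length <- as.integer(by_class$unit_length)
    by_class <- by_class[order(by_class$unit_length, by_class$canonical_class), ]
    rownames(by_class) <- NULL
    per_chrom <- as.data.frame(table(chromosome = ssrs$chromosome),
                               stringsAsFactors = FALSE)
    names(per_chrom)[2] <- "n_ssr"
  }
  disp_or <- c(forward = 0L, palindromic = 0L)
  hist_df <- NULL
  if (n_disp > 0) {
    t_or <- table(factor(dispersed$orientation,
                         levels = c("forward", "palindromic")))
    disp_or <- stats::setNames(as.integer(t_or), names(t_or))
    b <- (dispersed$length_bp %/% bin_width) * bin_width
    t_b <- table(b)
    hist_df <- data.frame(bin_start = as.integer(names(t_b)),
                          bin_end = as.integer(names(t_b)) + bin_width - 1L,
                          n = as.integer(t_b))
  }
  list(totals = c(ssr = n_ssr, tandem = n_tan, dispersed = n_disp,
                  all = n_ssr + n_tan + n_disp),
       ssr_by_unit = by_unit,
       ssr_by_class = by_class,
       ssr_per_chromosome = per_chrom,
       dispersed_by_orientation = disp_or,
       dispersed_length_histogram = hist_df)
}
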