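# Codon-usage statistics: codon counts, positional GC, relative synonymous
# codon usage (RSCU), Wright's effective number of codons (Nc), and start/stop
# codon tallies. The standard genetic code is used throughout (plant
# mitochondria translate with the standard code).

stop_codons <- c("TAA", "TAG", "TGA")

sense_codons <- function() setdiff(names(codon_table()), stop_codons)

# synonymous families: amino acid -> codons (stops excluded)
codon_families <- function() {
  gc_map <- codon_table()
  split(sense_codons(), gc_map[sense_codons()])
}

#' Count codons across a set of in-frame CDS sequences
#'
#' Stop codons are tallied separately and excluded from RSCU/Nc families.
#' Codons containing ambiguity codes are skipped. An internal (non-terminal)
#' stop codon raises a warning naming the gene and position.
#'
#' @param cds_set named character vector of in-frame CDS sequences
#' @param unique_cds drop duplicated sequences first ("unique CDSs" mode,
#'   default TRUE); set FALSE to count every gene copy
#' @return a `codon_usage` list: `counts` (61 sense codons), `stop_counts`,
#'   `n_codons` (sense total), `n_total` (sense + stop)
#' @export
count_codons <- function(cds_set, unique_cds = TRUE) {
  counts <- stats::setNames(integer(length(sense_codons())), sense_codons())
  stops <- stats::setNames(integer(3), stop_codons)
  if (length(cds_set)) {
    if (is.null(names(cds_set))) {
      names(cds_set) <- paste0("cds", seq_along(cds_set))
    }
    if (unique_cds) cds_set <- cds_set[!duplicated(toupper(cds_set))]
    gc_map <- codon_table()
    for (gene in names(cds_set)) {
      s <- toupper(cds_set[[gene]])
      if (nchar(s) %% 3L != 0L) {
        stop(sprintf("CDS length of gene %s (%d bp) is not divisible by 3",
                     gene, nchar(s)))
      }
      codons <- split_codons(s)
      internal <- which(codons %in% stop_codons)
      internal <- internal[internal < length(codons)]
      if (length(internal)) {
        warning(sprintf("gene %s has internal stop codon(s) at codon position(s) %s",
                        gene, paste(internal, collapse = ", ")))
      }
      tab <- table(codons)
      sense_hit <- intersect(names(tab), names(counts))
      counts[sense_hit] <- counts[sense_hit] + as.integer(tab[sense_hit])
      stop_hit <- intersect(names(tab), stop_codons)
      stops[stop_hit] <- stops[stop_hit] + as.integer(tab[stop_hit])
    }
  }
  structure(list(counts = counts, stop_counts = stops,
                 n_codons = sum(counts), n_total = sum(counts) + sum(stops)),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("codon_usage: %d sense codons, %d stop codons\n",
              x$n_codons, sum(x$stop_counts)))
  invisible(x)
}

#' Positional GC content of counted codons
#'
#' @param table a `codon_usage` from [count_codons()]
#' @return named numeric vector `GC1`, `GC2`, `GC3`, `GC_all` (fractions;
#'   `GC_all` is the arithmetic mean of the three)
#' @export
positional_gc <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  if (table$n_codons == 0) stop("empty codon table")
  gcpos <- vapply(1:3, function(p) {
    is_gc <- substr(names(table$counts), p, p) %in% c("G", "C")
    sum(table$counts[is_gc]) / table$n_codons
  }, 0)
  c(GC1 = gcpos[1], GC2 = gcpos[2], GC3 = gcpos[3], GC_all = mean(gcpos))
}

#' Relative synonymous codon usage
#'
#' For codon j in a synonymous family of size n with family total N:
#' RSCU_j = n * count_j / N. Families with zero counts are omitted; stop
#' codons are excluded. Within every family with nonzero counts the mean RSCU
#' is exactly 1.
#'
#' @param table a `codon_usage` from [count_codons()]
#' @return named numeric vector of RSCU values
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  out <- numeric(0)
  for (fam in codon_families()) {
    total <- sum(table$counts[fam])
    if (total == 0) next
    out <- c(out, length(fam) * table$counts[fam] / total)
  }
  out
}

#' Wright's effective number of codons (Nc)
#'
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean of the
#' family-level homozygosity estimates F = (n * sum(p^2) - 1) / (n - 1) over
#' the families of degeneracy k (2-fold: 9 amino acids; 3-fold: Ile; 4-fold:
#' 5; 6-fold: Leu/Ser/Arg). Met and Trp contribute the constant 2. Families
#' with n < 2 or a non-positive estimate are inestimable; a degeneracy class
#' with no estimable family takes the mean of the estimable classes (Wright's
#' convention). The result is clamped at 61 (no bias); 20 is the minimum.
#'
#' @param table a `codon_usage` from [count_codons()]
#' @return Nc in `[20, 61]`
#' @export
effective_number_of_codons <- function(table) {
  stopifnot(inherits(table, "codon_usage"))
  fams <- codon_families()
  sizes <- vapply(fams, length, 0L)
  f_hat <- function(cnt) {
    n <- sum(cnt)
    if (n < 2) return(NA_real_)
    f <- (n * sum((cnt / n)^2) - 1) / (n - 1)
    if (f <= 0) NA_real_ else f
  }
  class_mean <- function(k) {
    fs <- vapply(fams[sizes == k], function(fam) f_hat(table$counts[fam]), 0)
    fs <- fs[!is.na(fs)]
    if (length(fs) == 0) NA_real_ else mean(fs)
  }
  fbar <- c(`2` = class_mean(2), `3` = class_mean(3), `4` = class_mean(4),
            `6` = class_mean(6))
  if (all(is.na(fbar))) stop("no estimable synonymous family: empty table?")
  fbar[is.na(fbar)] <- mean(fbar, na.rm = TRUE)
  nc <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  min(nc, 61)
}

#' Start/stop codon usage over annotated gene copies
#'
#' Accepts per-gene start/stop codon strings, optionally with an edited-stop
#' annotation of the form `"CGA(TGA)"`, which is counted as the post-editing
#' codon (TGA). Counts are weighted by gene copy number; fractions are over
#' total gene copies.
#'
#' @param gene_table data.frame with columns `gene`, `start_codon`,
#'   `stop_codon` and optionally `copies` (default 1)
#' @return list with `start_counts`, `start_fractions`, `stop_counts`,
#'   `stop_fractions`, `n_copies`
#' @export
start_stop_summary <- function(gene_table) {
  stopifnot(all(c("gene", "start_codon", "stop_codon") %in% names(gene_table)))
  copies <- if ("copies" %in% names(gene_table)) gene_table$copies else
    rep(1L, nrow(gene_table))
  effective <- function(x) {
    # "CGA(TGA)" -> post-editing codon inside the parentheses
    ifelse(grepl("\\(", x), sub("^.*\\(([A-Z]+)\\).*$", "\\1", x), x)
  }
  starts <- effective(toupper(gene_table$start_codon))
  stops <- effective(toupper(gene_table$stop_codon))
  bad <- !stops %in% stop_codons
  if (any(bad)) {
    stop(sprintf("unknown stop codon '%s' for gene %s",
                 stops[bad][1], gene_table$gene[bad][1]))
  }
  n <- sum(copies)
  tally <- function(x) {
    t <- tapply(copies, x, sum)
    stats::setNames(as.integer(t), names(t))
  }
  sc <- tally(starts); pc <- tally(stops)
  list(start_counts = sc, start_fractions = sc / n,
       stop_counts = pc, stop_fractions = pc / n, n_copies = n)
}
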