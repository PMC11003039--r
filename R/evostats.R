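# Molecular-evolution statistics on pre-aligned sequences: Nei-Gojobori
# (1986) Ka/Ks with pathway-averaged difference counting and Jukes-Cantor
# correction, and Nei's nucleotide diversity (pi).

# --- NG86 lookup tables (built once) ----------------------------------------

ng86_tables <- function() {
  if (!is.null(.mc_cache$ng86)) return(.mc_cache$ng86)
  gc_map <- codon_table()
  sense <- sense_codons()
  bases <- c("A", "C", "G", "T")
  # synonymous site count per codon: at each position, the fraction of the 3
  # alternative bases that leave the amino acid unchanged (changes to a stop
  # codon count as nonsynonymous)
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        new <- cd
        substr(new, pos, pos) <- b
        if (gc_map[[new]] != "*" && gc_map[[new]] == gc_map[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[[cd]] <- s
  }
  # pathway-averaged synonymous/nonsynonymous differences per codon pair:
  # enumerate all orderings of the differing positions; pathways through stop
  # codons are excluded (all pathways used if every one is blocked)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      c1 <- sense[i]; c2 <- sense[j]
      diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      ords <- perms[[as.character(length(diffpos))]]
      path_syn <- numeric(0); path_non <- numeric(0); blocked <- logical(0)
      for (ord in ords) {
        cur <- c1
        sy <- 0; no <- 0; bl <- FALSE
        for (step in ord) {
          pos <- diffpos[step]
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (gc_map[[nxt]] == "*" && nxt != c2) bl <- TRUE
          if (gc_map[[nxt]] == gc_map[[cur]]) sy <- sy + 1 else no <- no + 1
          cur <- nxt
        }
        path_syn <- c(path_syn, sy); path_non <- c(path_non, no)
        blocked <- c(blocked, bl)
      }
      use <- if (all(blocked)) rep(TRUE, length(blocked)) else !blocked
      sd_mat[i, j] <- mean(path_syn[use])
      nd_mat[i, j] <- mean(path_non[use])
    }
  }
  .mc_cache$ng86 <- list(syn_sites = syn_sites, sd = sd_mat, nd = nd_mat)
  .mc_cache$ng86
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)   # correction undefined, flagged upstream
  -0.75 * log(1 - 4 * p / 3)
}

# split two aligned sequences into comparable codon columns
comparable_codons <- function(a, b, gene_id = "gene") {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not divisible by 3")
  ca <- split_codons(a); cb <- split_codons(b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[ok]; cb <- cb[ok]
  gc_map <- codon_table()
  if (length(ca)) {
    # strip a shared trailing stop
    last <- length(ca)
    if (gc_map[[ca[last]]] == "*" || gc_map[[cb[last]]] == "*") {
      ca <- ca[-last]; cb <- cb[-last]
    }
  }
  internal <- which(vapply(ca, function(x) gc_map[[x]] == "*", TRUE) |
                      vapply(cb, function(x) gc_map[[x]] == "*", TRUE))
  if (length(internal)) {
    warning(sprintf("%s: %d codon column(s) with internal stops excluded",
                    gene_id, length(internal)))
    ca <- ca[-internal]; cb <- cb[-internal]
  }
  list(a = ca, b = cb)
}

#' Nei-Gojobori (1986) Ka/Ks for one pair of aligned coding sequences
#'
#' Synonymous/nonsynonymous site counting per codon (S + N = 3), pathway-
#' averaged difference counting for multi-substitution codons (pathways via
#' stop codons excluded), Jukes-Cantor correction. Codon columns containing
#' gaps or ambiguity codes are excluded pairwise; a shared trailing stop is
#' stripped; internal-stop columns are excluded with a warning.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (gaps as `-`, whole-codon units)
#' @param taxonA,taxonB names of the two sequences to compare (defaults: the
#'   first two)
#' @param gene_id label used in the result
#' @return data.frame row: gene_id, taxon_a, taxon_b, ka, ks, ratio (NA when
#'   Ks is 0 or a proportion exceeded 3/4), S, N, Sd, Nd, n_codons, method
#' @export
ng86_kaks <- function(alignment, taxonA = NULL, taxonB = NULL,
                      gene_id = "gene") {
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("t", seq_along(alignment))
  }
  if (is.null(taxonA)) taxonA <- names(alignment)[1]
  if (is.null(taxonB)) taxonB <- names(alignment)[2]
  cc <- comparable_codons(alignment[[taxonA]], alignment[[taxonB]], gene_id)
  if (length(cc$a) == 0) stop("zero comparable codons")
  tabs <- ng86_tables()
  S <- sum(tabs$syn_sites[cc$a] + tabs$syn_sites[cc$b]) / 2
  N <- 3 * length(cc$a) - S
  idx_a <- match(cc$a, names(tabs$syn_sites))
  idx_b <- match(cc$b, names(tabs$syn_sites))
  Sd <- sum(tabs$sd[cbind(idx_a, idx_b)])
  Nd <- sum(tabs$nd[cbind(idx_a, idx_b)])
  pS <- Sd / S; pN <- Nd / N
  ks <- jc_correct(pS); ka <- jc_correct(pN)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  data.frame(gene_id = gene_id, taxon_a = taxonA, taxon_b = taxonB,
             ka = ka, ks = ks, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd,
             n_codons = length(cc$a), method = "NG86",
             stringsAsFactors = FALSE)
}

#' Selection label from a Ka/Ks ratio
#' @param ratio Ka/Ks value(s)
#' @return "positive" (> 1), "neutral" (= 1), "purifying" (< 1) or NA
#' @export
selection_label <- function(ratio) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio > 1, "positive",
                ifelse(ratio == 1, "neutral", "purifying")))
}

#' Pairwise Ka/Ks table across shared genes
#'
#' One NG86 result per unordered taxon pair per gene, plus per-gene summary
#' statistics of the ratio. Genes with fewer than two taxa are skipped with a
#' warning.
#'
#' @param alignments named list of codon alignments (each a named character
#'   vector of aligned sequences)
#' @return list with `pairs` (long-format data.frame) and `per_gene`
#'   (gene_id, n_pairs, mean/median/min/max ratio over defined ratios)
#' @export
pairwise_kaks_table <- function(alignments) {
  pairs <- NULL
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (length(aln) < 2) {
      warning(sprintf("gene %s skipped: fewer than 2 taxa", gene))
      next
    }
    taxa <- names(aln)
    for (i in seq_len(length(taxa) - 1)) {
      for (j in seq(i + 1, length(taxa))) {
        pairs <- rbind(pairs, ng86_kaks(aln, taxa[i], taxa[j], gene_id = gene))
      }
    }
  }
  if (is.null(pairs)) stop("no gene with >= 2 taxa")
  per_gene <- do.call(rbind, lapply(split(pairs, pairs$gene_id), function(d) {
    r <- d$ratio[!is.na(d$ratio)]
    data.frame(gene_id = d$gene_id[1], n_pairs = nrow(d),
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               median_ratio = if (length(r)) stats::median(r) else NA_real_,
               min_ratio = if (length(r)) min(r) else NA_real_,
               max_ratio = if (length(r)) max(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(pairs = pairs, per_gene = per_gene)
}

#' Nucleotide diversity (Nei's pi)
#'
#' Pi = 2 / (n (n - 1)) * sum over pairs of d_ij / L_ij, where d_ij is the
#' number of differing sites and L_ij the number of comparable sites of the
#' pair. In "pairwise" deletion mode (default) each pair uses its own
#' gap/ambiguity-free sites; "complete" deletion restricts all pairs to
#' columns that are unambiguous in every sequence.
#'
#' @param alignment named character vector of equal-length aligned sequences
#' @param deletion "pairwise" (default) or "complete"
#' @param gene_id label used in the result
#' @return data.frame row: gene_id, n_sequences, n_sites_used (mean
#'   comparable sites per pair), pi
#' @export
nucleotide_diversity <- function(alignment, deletion = c("pairwise", "complete"),
                                 gene_id = "gene") {
  deletion <- match.arg(deletion)
  n <- length(alignment)
  if (n < 2) stop("nucleotide diversity needs at least 2 sequences")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("aligned sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  if (deletion == "complete") {
    keep <- apply(good, 2, all)
    mat <- mat[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  tot <- 0; l_used <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- good[i, ] & good[j, ]
      L <- sum(ok)
      if (L == 0) stop("a sequence pair has no comparable sites")
      d <- sum(mat[i, ok] != mat[j, ok])
      tot <- tot + d / L
      l_used <- c(l_used, L)
    }
  }
  pi <- 2 * tot / (n * (n - 1))
  data.frame(gene_id = gene_id, n_sequences = n,
             n_sites_used = mean(l_used), pi = pi, stringsAsFactors = FALSE)
}

#' Simulate neutral divergence of a coding sequence
#'
#' Starting from a random stop-free CDS, applies `p_sub` expected uniform
#' substitutions per site independently to two copies. Substitutions are not
#' constrained in any way (a biased redraw would skew the synonymous/
#' nonsynonymous balance); codon columns where a stop arises are excluded by
#' [ng86_kaks()] with a warning, as for any alignment. Used to check that the
#' NG86 estimator returns Ka/Ks near 1 when synonymous and nonsynonymous
#' changes are equally likely.
#'
#' @param n_codons number of codons
#' @param p_sub expected substitutions per site per lineage
#' @param seed RNG seed
#' @return named character vector of two diverged in-frame sequences
#' @export
simulate_neutral_pair <- function(n_codons, p_sub, seed = 1L) {
  set.seed(seed)
  root <- random_cds(n_codons + 2)
  root <- substr(root, 1, 3 * n_codons) # stop-free in-frame root
  bases <- c("A", "C", "G", "T")
  mutate_lineage <- function(s) {
    chars <- strsplit(s, "")[[1]]
    hits <- which(stats::runif(length(chars)) < p_sub)
    for (i in hits) chars[i] <- sample(setdiff(bases, chars[i]), 1)
    paste0(chars, collapse = "")
  }
  c(a = mutate_lineage(root), b = mutate_lineage(root))
}
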