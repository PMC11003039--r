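# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

# memoized simulation fixtures so several test files can share one genome
cached_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

rdna <- function(n, gc = 0.5) mitocharter:::random_dna(n, gc)
revcomp <- function(x) mitocharter:::rc(x)
mutate_n <- function(x, n) mitocharter:::mutate_substitutions(x, n)$seq

# the 10-chromosome ~300 kb fixture used by the planted-recovery checks
recovery_fixture <- function() {
  cached_fixture("recovery", function() {
    cfg <- sim_config(n_chromosomes = 10, chrom_length_range = c(25000, 35000),
                      rng_seed = 5)
    sim <- generate_mitogenome(cfg)
    comp <- generate_companion_genomes(sim, cfg)
    list(cfg = cfg, sim = sim, comp = comp)
  })
}

# --- independent Needleman-Wunsch identity oracle (Biostrings) ---------------

nw_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# --- independent NG86 oracle -------------------------------------------------
# Recursive pathway enumeration, written without the package's lookup tables.

oracle_gc <- Biostrings::GENETIC_CODE

oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_gc[[alt]] != "*" && oracle_gc[[alt]] == oracle_gc[[codon]]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# returns data.frame of per-pathway (syn, nonsyn, blocked)
oracle_pathways <- function(c1, c2) {
  if (c1 == c2) return(data.frame(syn = 0, nonsyn = 0, blocked = FALSE))
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  out <- NULL
  for (p in diffpos) {
    nxt <- c1
    substr(nxt, p, p) <- substr(c2, p, p)
    step_syn <- oracle_gc[[nxt]] == oracle_gc[[c1]]
    step_blocked <- oracle_gc[[nxt]] == "*" && nxt != c2
    rest <- oracle_pathways(nxt, c2)
    out <- rbind(out, data.frame(syn = rest$syn + as.numeric(step_syn),
                                 nonsyn = rest$nonsyn + as.numeric(!step_syn),
                                 blocked = rest$blocked | step_blocked))
  }
  out
}

oracle_pair_diffs <- function(c1, c2) {
  pw <- oracle_pathways(c1, c2)
  use <- if (all(pw$blocked)) rep(TRUE, nrow(pw)) else !pw$blocked
  c(sd = mean(pw$syn[use]), nd = mean(pw$nonsyn[use]))
}

oracle_jc <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# full oracle Ka/Ks for two aligned in-frame sequences over ACGT (no gaps)
oracle_kaks <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracle_syn_sites(ca[i]) + oracle_syn_sites(cb[i])) / 2
    d <- oracle_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(ca) - S
  list(ka = oracle_jc(Nd / N), ks = oracle_jc(Sd / S), S = S, N = N,
       Sd = Sd, Nd = Nd)
}

# direct pairwise-difference oracle for nucleotide diversity
oracle_pi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    tot <- tot + sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  2 * tot / (n * (n - 1))
}
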