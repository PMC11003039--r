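# Small shared sequence helpers. Coordinates throughout the package are
# 0-based half-open on the forward strand; GFF3 emission converts to 1-based
# inclusive.

#' Reverse complement of a character sequence
#' @param x single DNA string
#' @return reverse-complemented string
#' @keywords internal
#' @noRd
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of a string; ambiguity codes excluded from the denominator
#' @noRd
gc_fraction <- function(x) {
  b <- table(factor(strsplit(toupper(x), "")[[1]], levels = c("A", "C", "G", "T")))
  tot <- sum(b)
  if (tot == 0) stop("sequence has no unambiguous bases")
  unname((b[["G"]] + b[["C"]]) / tot)
}

#' Random i.i.d. DNA with a target GC content
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Apply `n_sub` substitutions at distinct positions, each to a different base
#' @return list(seq, positions) with 0-based positions
#' @noRd
mutate_substitutions <- function(x, n_sub) {
  if (n_sub == 0) return(list(seq = x, positions = integer(0)))
  chars <- strsplit(x, "")[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (i in pos) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(seq = paste0(chars, collapse = ""), positions = sort(pos - 1L))
}

#' Standard genetic code keyed by DNA codons; stops are "*"
#' @noRd
codon_table <- function() Biostrings::GENETIC_CODE

#' Translate an in-frame DNA CDS to a protein string (stops as "*")
#' @noRd
translate_cds <- function(x) {
  if (nchar(x) %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  paste0(unname(codon_table()[codons]), collapse = "")
}

#' Split an in-frame CDS into codons
#' @noRd
split_codons <- function(x) {
  substring(toupper(x), seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Write sequences as wrapped FASTA (70 columns)
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read a (multi-)FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param seqs named character vector
#' @param path output file
#' @param qual_char quality character applied to every base
#' @return `path`, invisibly
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@", names(seqs)[i]), seqs[[i]], "+",
                 strrep(qual_char, nchar(seqs[[i]]))), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a named character vector (qualities dropped)
#' @param path FASTQ file
#' @return named character vector of read sequences
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(set), names(set))
}
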