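test_that("generated chromosomes respect count, length range and topology", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length_range = c(9000, 12000),
                    rng_seed = 3)
  sim <- generate_mitogenome(cfg)
  expect_length(sim$genome$seq, 4)
  expect_true(all(nchar(sim$genome$seq) >= 9000 &
                    nchar(sim$genome$seq) <= 12000))
  expect_true(all(sim$genome$topology == "circular"))
})

test_that("a single chromosome with an empty plan yields an empty manifest", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(5000, 5000),
                    n_genes_per_chrom = 0, ssr_plan = list(),
                    tandem_plan = list(), dispersed_plan = list(),
                    rng_seed = 2)
  sim <- generate_mitogenome(cfg)
  expect_length(sim$genome$seq, 1)
  expect_equal(nrow(sim$manifest), 0)
})

test_that("realized GC tracks the target composition", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(100000, 100000),
                    gc_target = 0.44, n_genes_per_chrom = 0, ssr_plan = list(),
                    tandem_plan = list(), dispersed_plan = list(),
                    rng_seed = 99)
  sim <- generate_mitogenome(cfg)
  gc <- mitocharter:::gc_fraction(sim$genome$seq[[1]])
  expect_lt(abs(gc - 0.44), 0.01)
})

test_that("identical configs give byte-identical FASTA/FASTQ/manifest outputs", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_range = c(8000, 9000),
                    rng_seed = 17,
                    read_params = list(mean_len = 2000, error_rate = 0.03,
                                       depth = 3))
  s1 <- generate_mitogenome(cfg)
  s2 <- generate_mitogenome(cfg)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$manifest, s2$manifest)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1$genome$seq, f1); write_fasta(s2$genome$seq, f2)
  expect_identical(readLines(f1), readLines(f2))
  r1 <- simulate_reads(list(mito = s1$genome), cfg$read_params, seed = 17)
  r2 <- simulate_reads(list(mito = s2$genome), cfg$read_params, seed = 17)
  q1 <- tempfile(); q2 <- tempfile()
  write_fastq(r1$reads, q1); write_fastq(r2$reads, q2)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("planted genes have a valid start and stop and a complete manifest", {
  fx <- recovery_fixture()
  cds <- extract_cds(fx$sim$genome, fx$sim$genes)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  last <- substring(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # no internal stops
  for (s in cds) {
    codons <- mitocharter:::split_codons(s)
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  # manifest covers every planted feature kind and stays inside chromosomes
  expect_setequal(unique(fx$sim$manifest$kind),
                  c("gene", "ssr", "tandem", "dispersed"))
  lens <- nchar(fx$sim$genome$seq)
  expect_true(all(fx$sim$manifest$end <= lens[fx$sim$manifest$chrom]))
  expect_true(all(fx$sim$manifest$start >= 0))
})

test_that("every identity-1 planted feature is recoverable by string search", {
  fx <- recovery_fixture()
  man <- fx$sim$manifest
  seqs <- fx$sim$genome$seq
  ssr <- man[man$kind == "ssr", ]
  for (i in seq_len(nrow(ssr))) {
    r <- ssr[i, ]
    motif <- sub("x.*", "", r$payload)
    copies <- as.integer(sub(".*x", "", r$payload))
    expect_identical(substr(seqs[[r$chrom]], r$start + 1,
                            r$start + nchar(motif) * copies),
                     strrep(motif, copies))
  }
  disp <- man[man$kind == "dispersed" & man$identity == 1, ]
  for (i in seq_len(nrow(disp))) {
    r <- disp[i, ]
    src <- substr(seqs[[r$chrom]], r$start + 1, r$end)
    dst <- substr(seqs[[r$partner_chrom]], r$partner_start + 1, r$partner_end)
    if (r$payload == "palindromic") dst <- revcomp(dst)
    expect_identical(src, dst)
  }
})

test_that("an infeasible plan errors and names the chromosome", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(400, 400),
                    n_genes_per_chrom = 1, ssr_plan = list(),
                    tandem_plan = list(), dispersed_plan = list(),
                    rng_seed = 1)
  expect_error(generate_mitogenome(cfg), "chromosome chr1")
})

test_that("companion genomes share segments at the requested identity", {
  fx <- recovery_fixture()
  man <- fx$comp$manifest
  mseq <- fx$sim$genome$seq
  pseq <- c(fx$comp$plastome$seq, fx$comp$nuclear$seq)
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    src <- substr(mseq[[r$chrom]], r$start + 1, r$end)
    dst <- substr(pseq[[r$partner_chrom]], r$partner_start + 1, r$partner_end)
    ham <- mean(strsplit(src, "")[[1]] == strsplit(dst, "")[[1]])
    expect_equal(ham, r$identity, tolerance = 1e-9)
  }
  # identity 1.0 segments are exact shared substrings
  exact <- man[man$identity == 1, ][1, ]
  seg <- substr(mseq[[exact$chrom]], exact$start + 1, exact$end)
  expect_true(grepl(seg, pseq[[exact$partner_chrom]], fixed = TRUE))
})

test_that("insert identity outside [0, 1] is rejected", {
  expect_error(sim_config(plastid_insert_spec = list(c(100, 1.2))), "identity")
  expect_error(sim_config(plastid_insert_spec = list(c(100, -0.1))), "identity")
})

test_that("error-free reads are exact substrings modulo strand and wrap", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_range = c(6000, 6000),
                    n_genes_per_chrom = 0, ssr_plan = list(),
                    tandem_plan = list(), dispersed_plan = list(),
                    rng_seed = 8,
                    read_params = list(mean_len = 1500, error_rate = 0,
                                       depth = 5))
  sim <- generate_mitogenome(cfg)
  rd <- simulate_reads(list(mito = sim$genome), cfg$read_params, seed = 8)
  doubled <- strrep(sim$genome$seq[[1]], 2) # circular template
  for (i in seq_len(nrow(rd$origins))) {
    o <- rd$origins[i, ]
    raw <- rd$reads[[o$read_id]]
    if (o$strand == "-") raw <- revcomp(raw)
    expect_identical(raw, substr(doubled, o$start + 1, o$end))
  }
  # total bases approximately depth * genome length
  expect_lt(abs(sum(rd$origins$length) - 5 * 6000) / (5 * 6000), 0.1)
})

test_that("long reads on short linear chromosomes are rejected", {
  g <- mc_genome(c(n1 = rdna(800)), topology = "linear")
  expect_error(simulate_reads(list(nuc = g),
                              list(mean_len = 2000, error_rate = 0, depth = 2)),
               "linear")
})

test_that("editing truth plants only C-to-U changes at codon positions 1-2", {
  cds <- c(g1 = paste0("ATG", strrep("TCA", 30), "TAA"),
           g2 = paste0("ATG", strrep("CCT", 30), "TGA"))
  tr <- apply_editing_truth(cds, editing_rate = 10, seed = 4)
  expect_gt(nrow(tr$events), 0)
  expect_true(all(tr$events$codon_position %in% 1:2))
  for (i in seq_len(nrow(tr$events))) {
    ev <- tr$events[i, ]
    ref <- strsplit(ev$ref_codon, "")[[1]]
    ed <- strsplit(ev$edited_codon, "")[[1]]
    d <- which(ref != ed)
    expect_true(all(ref[d] == "C") && all(ed[d] == "T"))
    # the edited codon is present in the edited transcript at that index
    got <- substr(tr$edited[[ev$gene_id]], 3 * ev$codon_index + 1,
                  3 * ev$codon_index + 3)
    expect_identical(got, ev$edited_codon)
  }
})

test_that("editing rate zero or a C-free CDS yields no events", {
  cds <- c(g = paste0("ATG", strrep("AAA", 20), "TAA"))
  expect_equal(nrow(apply_editing_truth(cds, 50, seed = 1)$events), 0)
  cds2 <- c(g = paste0("ATG", strrep("TCA", 20), "TAA"))
  tr <- apply_editing_truth(cds2, 0, seed = 1)
  expect_identical(tr$edited, cds2)
})

test_that("a planted TCA codon edits to TTA with amino change S to L", {
  cds <- c(g = "ATGTCATAA")
  tr <- apply_editing_truth(cds, editing_rate = 50, seed = 2)
  expect_equal(nrow(tr$events), 1)
  expect_identical(tr$events$ref_codon, "TCA")
  expect_identical(tr$events$edited_codon, "TTA")
  expect_identical(tr$events$aa_before, "S")
  expect_identical(tr$events$aa_after, "L")
})

test_that("GFF3 emission round-trips gene models including origin wrap", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("c1", "c1"),
                      start = c(100L, 4900L), end = c(400L, 5200L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_gff3(genes, path, c(c1 = 5000L))
  back <- read_gff3_genes(path)
  back <- back[order(back$gene_id), ]
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  # the wrapped gene is emitted as two parts sharing an ID
  raw <- readLines(path)
  expect_equal(sum(grepl("\tgene\t", raw) & grepl("ID=gB", raw)), 2)
})

test_that("extract_cds is strand-aware and supports origin wrap", {
  seqs <- c(c1 = rdna(2000))
  cds <- "ATGAAACCCGGGTAA"
  seqs["c1"] <- paste0(cds, substr(seqs["c1"], nchar(cds) + 1, 2000))
  genes <- data.frame(gene_id = "g", chrom = "c1", start = 0L,
                      end = nchar(cds), strand = "+", stringsAsFactors = FALSE)
  expect_identical(unname(extract_cds(seqs, genes)["g"]), cds)
  # reverse strand
  seqs2 <- c(c1 = paste0(revcomp(cds), rdna(100)))
  genes2 <- data.frame(gene_id = "g", chrom = "c1", start = 0L,
                       end = nchar(cds), strand = "-", stringsAsFactors = FALSE)
  expect_identical(unname(extract_cds(seqs2, genes2)["g"]), cds)
  # wrap: last 6 bases + first 9 bases
  seqs3 <- c(c1 = paste0(substr(cds, 7, 15), rdna(200), substr(cds, 1, 6)))
  genes3 <- data.frame(gene_id = "g", chrom = "c1", start = 209L,
                       end = 224L, strand = "+", stringsAsFactors = FALSE)
  expect_identical(unname(extract_cds(seqs3, genes3)["g"]), cds)
})
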