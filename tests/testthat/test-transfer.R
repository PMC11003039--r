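test_that("homologous fragments honour all three screening thresholds", {
  set.seed(81)
  mito <- c(m1 = rdna(8000))
  seg <- substr(mito[["m1"]], 2001, 7000)               # 5 kb shared segment
  plast <- c(p1 = paste0(rdna(3000), seg, rdna(3000)))
  f <- find_homologous_fragments(mito, plast)
  expect_equal(nrow(f), 1)
  expect_gte(f$length_bp, 5000 * 0.99)
  expect_equal(f$identity, 1.0)
  expect_lte(f$e_value, 1e-5)
  # a 25 bp identical segment is below the length threshold
  seg25 <- substr(mito[["m1"]], 501, 525)
  plast25 <- c(p1 = paste0(rdna(2000), seg25, rdna(2000)))
  f25 <- find_homologous_fragments(mito, plast25)
  expect_false(any(f25$query_start < 525 & f25$query_end > 500 &
                     f25$length_bp < 30))
  expect_true(all(f25$length_bp >= 30))
  # a 500 bp segment degraded to ~60% identity is below the matching rate
  seg60 <- mutate_n(substr(mito[["m1"]], 1001, 1500), 200)
  plast60 <- c(p1 = paste0(rdna(2000), seg60, rdna(2000)))
  f60 <- find_homologous_fragments(mito, plast60)
  expect_true(all(f60$identity >= 0.70))
  expect_false(any(f60$length_bp > 400))
})

test_that("coverage merges overlapping query intervals before summing", {
  g <- c(c1 = rdna(1000))
  fr <- data.frame(query_chrom = c("c1", "c1"), query_start = c(0, 50),
                   query_end = c(100, 150), subject_chrom = "p",
                   subject_start = c(0, 0), subject_end = c(100, 100),
                   orientation = "forward", length_bp = 100, identity = 1,
                   e_value = 0, stringsAsFactors = FALSE)
  cov <- merged_coverage(fr, g)
  expect_equal(cov$covered_bp, 150)
  expect_equal(cov$fraction, 0.15)
  expect_equal(cov$unmerged_bp, 200)
  # no fragments
  cov0 <- merged_coverage(fr[0, ], g)
  expect_equal(cov0$covered_bp, 0)
  expect_equal(cov0$fraction, 0)
  # out-of-range coordinates error
  bad <- fr; bad$query_end[1] <- 2000
  expect_error(merged_coverage(bad, g), "out of")
})

test_that("gene containment requires the full span inside a merged region", {
  fr <- data.frame(query_chrom = "c1", query_start = c(0, 150),
                   query_end = c(200, 400), subject_chrom = "p",
                   subject_start = 0, subject_end = 100,
                   orientation = "forward", length_bp = 100,
                   identity = c(0.9, 0.95), e_value = 0,
                   stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("in1", "part", "span"),
                      chrom = "c1", start = c(10L, 350L, 120L),
                      end = c(100L, 500L, 380L), stringsAsFactors = FALSE)
  got <- genes_fully_contained(fr, genes)
  expect_setequal(got$gene_id, c("in1", "span"))
  expect_equal(got$identity[got$gene_id == "in1"], 0.9)
  # "span" is only contained in the merged region; best overlapping identity
  expect_equal(got$identity[got$gene_id == "span"], 0.95)
})

test_that("planted genes inside transfer segments are the ones reported", {
  set.seed(82)
  mito <- c(m1 = rdna(20000))
  # two genes inside the shared segment, one outside
  genes <- data.frame(gene_id = c("gin1", "gin2", "gout"), chrom = "m1",
                      start = c(3000L, 6000L, 15000L),
                      end = c(3600L, 6900L, 15900L), strand = "+",
                      stringsAsFactors = FALSE)
  seg <- substr(mito[["m1"]], 2001, 8000)
  plast <- c(p1 = paste0(rdna(2000), seg, rdna(2000)))
  f <- find_homologous_fragments(mito, plast)
  got <- genes_fully_contained(f, genes)
  expect_setequal(got$gene_id, c("gin1", "gin2"))
})

test_that("fragment search is symmetric up to query/subject role swap", {
  set.seed(83)
  a <- c(a1 = rdna(6000))
  seg <- substr(a[["a1"]], 1001, 1400)
  b <- c(b1 = paste0(rdna(2500), mutate_n(seg, 20), rdna(2500)))
  fab <- find_homologous_fragments(a, b)
  fba <- find_homologous_fragments(b, a)
  expect_equal(nrow(fab), nrow(fba))
  expect_equal(sort(fab$length_bp), sort(fba$length_bp))
  expect_equal(fab$query_start, fba$subject_start)
  expect_equal(fab$subject_start, fba$query_start)
})

test_that("tightening thresholds never increases fragments or coverage", {
  fx <- recovery_fixture()
  mito <- fx$sim$genome
  plast <- fx$comp$plastome
  base <- find_homologous_fragments(mito, plast)
  tighter_id <- find_homologous_fragments(mito, plast, min_identity = 0.9)
  tighter_len <- find_homologous_fragments(mito, plast, min_len = 300)
  tighter_e <- find_homologous_fragments(mito, plast, max_e = 1e-30)
  expect_lte(nrow(tighter_id), nrow(base))
  expect_lte(nrow(tighter_len), nrow(base))
  expect_lte(nrow(tighter_e), nrow(base))
  expect_lte(merged_coverage(tighter_len, mito)$covered_bp,
             merged_coverage(base, mito)$covered_bp)
})

test_that("synteny blocks of a genome against itself are full-length forward", {
  set.seed(84)
  g <- c(c1 = rdna(8000), c2 = rdna(7000))
  blocks <- synteny_blocks(g, g)
  self <- blocks[blocks$query_chrom == blocks$subject_chrom &
                   blocks$orientation == "forward", ]
  expect_setequal(self$query_chrom, c("c1", "c2"))
  for (ch in c("c1", "c2")) {
    b <- self[self$query_chrom == ch, ]
    expect_gte(max(b$length_bp), nchar(g[[ch]]) * 0.999)
  }
  # against the reverse complement: reverse-orientation blocks only
  grc <- stats::setNames(vapply(g, revcomp, ""), names(g))
  blocks_rc <- synteny_blocks(g, grc)
  big <- blocks_rc[blocks_rc$length_bp > 1000, ]
  expect_true(all(big$orientation == "reverse"))
})

test_that("shuffling chromosome order changes labels, not the block set", {
  set.seed(85)
  g <- c(c1 = rdna(6000), c2 = rdna(6000), c3 = rdna(6000))
  shuffled <- g[c(3, 1, 2)]
  b1 <- synteny_blocks(g, g)
  b2 <- synteny_blocks(g, shuffled)
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(sort(b1$length_bp), sort(b2$length_bp))
})

test_that("planted transfer segments are recovered with reciprocal overlap", {
  fx <- recovery_fixture()
  f <- find_homologous_fragments(fx$sim$genome, fx$comp$plastome)
  man <- fx$comp$manifest[fx$comp$manifest$partner_genome == "plastid", ]
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    hit <- f[f$query_chrom == r$chrom & f$query_start < r$end &
               f$query_end > r$start, ]
    expect_gte(nrow(hit), 1)
    ov <- max(pmin(hit$query_end, r$end) - pmax(hit$query_start, r$start))
    expect_gte(ov / (r$end - r$start), 0.95)
  }
})
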