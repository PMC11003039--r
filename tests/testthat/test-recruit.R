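test_that("an exact substring is reported as one full-length identity-1 match", {
  set.seed(42)
  t <- rdna(10000)
  r <- substr(t, 3001, 5000)
  m <- estimate_local_matches(c(read = r), c(tg = t))
  expect_equal(nrow(m), 1)
  expect_gte(m$matched_length_bp, 2000 * 0.99)
  expect_equal(m$identity_fraction, 1.0)
  expect_identical(m$orientation, "forward")
  # reverse-complemented read is found on the reverse strand at the same locus
  m2 <- estimate_local_matches(c(read = revcomp(r)), c(tg = t))
  expect_identical(m2$orientation, "reverse")
  expect_equal(m2$target_start, 3000)
  expect_equal(m2$target_end, 5000)
})

test_that("unrelated random sequences produce no match of 50 bp or more", {
  set.seed(7)
  hits <- 0
  for (i in 1:100) {
    m <- estimate_local_matches(c(r = rdna(10000)), c(t = rdna(10000)))
    hits <- hits + sum(m$matched_length_bp >= 50)
  }
  expect_equal(hits, 0)
})

test_that("reported identity agrees with Needleman-Wunsch on the planted interval", {
  set.seed(11)
  for (trial in 1:5) {
    t <- rdna(10000)
    r <- mutate_n(substr(t, 2001, 4000), 200) # 10% substitutions
    m <- estimate_local_matches(c(read = r), c(tg = t))
    m <- m[which.max(m$matched_length_bp), ]
    ref <- nw_identity(r, substr(t, 2001, 4000))
    expect_lt(abs(m$identity_fraction - ref), 0.03)
    expect_lt(abs(m$identity_fraction - 0.90), 0.03)
  }
})

test_that("candidate selection applies the match-length threshold", {
  set.seed(3)
  gene <- rdna(1500)
  bg <- rdna(9000)
  read_full <- paste0(rdna(2000), gene, rdna(2000))   # contains the gene
  read_short <- paste0(rdna(3000), substr(gene, 1, 40), rdna(3000))
  reads <- c(full = read_full, short = read_short, none = rdna(6000))
  sel <- select_candidates(reads, c(geneA = gene))
  expect_identical(sel$candidates, "full")
  # threshold off: any read with any local match qualifies
  sel0 <- select_candidates(reads, c(geneA = gene), min_match_bp = 0)
  expect_true("full" %in% sel0$candidates)
  expect_error(select_candidates(reads, character(0)))
})

test_that("seed ranking prefers more genes, then identity-weighted bp, then id", {
  m <- data.frame(
    read_id = c("B", "A", "A", "A", "C", "D"),
    target_id = c("g1", "g1", "g2", "g3", "g1", "g1"),
    matched_length_bp = c(900, 300, 300, 300, 500, 500),
    identity_fraction = c(1, 1, 1, 1, 0.9, 0.8),
    stringsAsFactors = FALSE)
  ranked <- choose_seed(m)
  expect_identical(ranked[1], "A")          # 3 genes beat 1 long match
  expect_identical(ranked[2], "B")          # highest weighted bp among 1-gene
  expect_identical(ranked[3], "C")          # 450 beats 400
  # deterministic tie-break on read id
  m2 <- m[m$read_id %in% c("C", "D"), ]
  m2$identity_fraction <- 1; m2$matched_length_bp <- 500
  expect_identical(choose_seed(m2), c("C", "D"))
  # single candidate is the seed; empty candidates error
  expect_identical(choose_seed(m[m$read_id == "B", ]), "B")
  expect_error(choose_seed(m[0, ]), "no seed")
})

test_that("covering mode keeps one seed per uncovered core gene", {
  m <- data.frame(
    read_id = c("A", "A", "B", "C"),
    target_id = c("g1", "g2", "g1", "g3"),
    matched_length_bp = c(500, 500, 900, 400),
    identity_fraction = 1, stringsAsFactors = FALSE)
  expect_setequal(choose_seed(m, cover = TRUE), c("A", "C"))
})

test_that("recruitment applies the overlap and identity thresholds", {
  set.seed(21)
  bg <- rdna(30000)
  seed_read <- substr(bg, 1, 5000)
  good <- substr(bg, 3801, 9000)    # 1200 bp overlap with the seed
  short <- paste0(substr(bg, 4501, 5000), rdna(4000)) # only 500 bp overlap
  reads <- c(s = seed_read, good = good, short = short)
  st <- recruit_iteratively(reads, "s", max_iter = 5)
  expect_setequal(st$recruited, c("s", "good"))
  expect_identical(st$stop_reason, "fixpoint")
  expect_error(recruit_iteratively(reads, "s", max_iter = 0), "max_iter")
  expect_error(recruit_iteratively(reads, "zzz"), "subset")
})

test_that("a three-read chain is recruited transitively to a fixpoint", {
  set.seed(31)
  chrom <- rdna(20000)
  seed_read <- substr(chrom, 1, 5000)
  r1 <- substr(chrom, 3501, 9500)    # overlaps seed by 1500
  r2 <- substr(chrom, 8001, 14000)   # overlaps r1 by 1500, seed by 0
  reads <- c(s = seed_read, r1 = r1, r2 = r2)
  st <- recruit_iteratively(reads, "s", max_iter = 10)
  expect_identical(st$added[[1]], "r1")
  expect_identical(st$added[[2]], "r2")
  expect_equal(st$iterations$n_added, c(1, 1, 0))
  expect_identical(st$stop_reason, "fixpoint")
})

test_that("tightening thresholds never enlarges the recruited set", {
  set.seed(41)
  chrom <- rdna(15000)
  reads <- c(s = substr(chrom, 1, 5000),
             a = mutate_n(substr(chrom, 3001, 8000), 400),
             b = substr(chrom, 7001, 12000),
             junk = rdna(5000))
  loose <- recruit_iteratively(reads, "s", min_overlap_bp = 1000,
                               min_identity = 0.70, max_iter = 10)
  tight_id <- recruit_iteratively(reads, "s", min_overlap_bp = 1000,
                                  min_identity = 0.95, max_iter = 10)
  tight_ov <- recruit_iteratively(reads, "s", min_overlap_bp = 3000,
                                  min_identity = 0.70, max_iter = 10)
  expect_true(all(tight_id$recruited %in% loose$recruited))
  expect_true(all(tight_ov$recruited %in% loose$recruited))
  expect_false("junk" %in% loose$recruited)
  # recruited set grows weakly over iterations by construction of the log
  expect_true(all(loose$iterations$n_added >= 0))
})

test_that("after a fixpoint no unrecruited read satisfies the predicate", {
  set.seed(51)
  chrom <- rdna(12000)
  reads <- c(s = substr(chrom, 1, 4000),
             near = substr(chrom, 3201, 7200),
             far = paste0(substr(chrom, 7301, 7800), rdna(3500)),
             other = rdna(4000))
  st <- recruit_iteratively(reads, "s", max_iter = 10)
  expect_identical(st$stop_reason, "fixpoint")
  left <- setdiff(names(reads), st$recruited)
  if (length(left)) {
    m <- local_matches(reads[left], reads[st$recruited])
    expect_false(any(m$matched_length_bp >= 1000 & m$identity_fraction >= 0.70))
  }
})
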