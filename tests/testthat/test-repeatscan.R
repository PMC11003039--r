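test_that("SSR detection follows the per-unit copy minima", {
  set.seed(61)
  s <- paste0(rdna(500), strrep("A", 12), rdna(300), strrep("AC", 5),
              rdna(200), strrep("AC", 4), rdna(100))
  ssrs <- find_ssrs(s)
  expect_equal(nrow(ssrs), 2)
  mono <- ssrs[ssrs$unit_length == 1, ]
  expect_identical(mono$canonical_class, "A/T")
  expect_gte(mono$copy_number, 12)
  di <- ssrs[ssrs$unit_length == 2, ]
  expect_identical(di$canonical_class, "AC/GT")
  expect_gte(di$copy_number, 5)
  # the 4-copy dimer run is below the minimum of 5 and is not reported
  expect_false(any(ssrs$start > 820 & ssrs$unit_length == 2 &
                     ssrs$start < 1030))
})

test_that("SSR records satisfy the interval/copy arithmetic", {
  set.seed(62)
  s <- paste0(rdna(200), strrep("AAG", 6), rdna(200), strrep("AAAC", 4),
              rdna(200))
  ssrs <- find_ssrs(s)
  expect_true(all(ssrs$end - ssrs$start ==
                    ssrs$unit_length * ssrs$copy_number))
  expect_true(all(c("AAG/CTT", "AAAC/GTTT") %in% ssrs$canonical_class))
})

test_that("motifs that repeat a shorter unit are reported at the shortest unit", {
  set.seed(63)
  s <- paste0(rdna(300), strrep("AT", 8), rdna(300))
  ssrs <- find_ssrs(s)
  at <- ssrs[ssrs$canonical_class == "AT/AT", ]
  expect_true(all(at$unit_length == 2))  # never as ATAT (unit 4)
})

test_that("canonical classes match the complementary-rotation rule", {
  expect_identical(canonical_motif("GT"), "AC/GT")
  expect_identical(canonical_motif("TTTG"), "AAAC/GTTT")
  expect_identical(canonical_motif("AT"), "AT/AT")
  expect_identical(canonical_motif("A"), "A/T")
  expect_identical(canonical_motif("GAA"), "AAG/CTT")
  expect_identical(canonical_motif("CCTCT"), "AGAGG/CCTCT")
  expect_error(canonical_motif("ANA"), "ACGT")
  expect_error(canonical_motif("AATTCCG"), "1-6")
})

test_that("SSR scan is reverse-complement invariant in classes and copies", {
  set.seed(64)
  s <- paste0(rdna(400), strrep("AAG", 5), rdna(150), strrep("T", 11),
              rdna(400))
  a <- find_ssrs(s)
  b <- find_ssrs(revcomp(s))
  key <- function(d) sort(paste(d$canonical_class, d$copy_number))
  expect_identical(key(a), key(b))
  # coordinates mirror
  n <- nchar(s)
  expect_setequal(b$start, n - a$end)
})

test_that("tandem arrays are detected with correct unit and match fraction", {
  set.seed(65)
  unit <- rdna(9)
  s <- paste0(rdna(400), strrep(unit, 4), rdna(400))
  td <- find_tandem_repeats(s)
  expect_equal(nrow(td), 1)
  expect_equal(td$unit_length, 9)
  expect_equal(td$percent_match, 1.0)
  expect_gte(td$copy_number, 4)
  # 20 bp unit x3 with one substitution: detected, match fraction >= 0.9
  u20 <- rdna(20)
  arr <- mutate_n(strrep(u20, 3), 1)
  s2 <- paste0(rdna(300), arr, rdna(300))
  td2 <- find_tandem_repeats(s2)
  expect_equal(nrow(td2), 1)
  expect_gte(td2$percent_match, 0.9)
})

test_that("random sequence yields no tandem array above the match threshold", {
  set.seed(66)
  hits <- 0
  for (i in 1:100) hits <- hits + nrow(find_tandem_repeats(rdna(1000)))
  expect_equal(hits, 0)
})

test_that("microsatellite-range arrays are not reported as tandem repeats", {
  set.seed(67)
  s <- paste0(rdna(300), strrep("ACT", 12), rdna(300))
  td <- find_tandem_repeats(s)
  expect_equal(nrow(td), 0)   # a 36 bp trimer run is an SSR, not a >6 bp array
})

test_that("dispersed repeats are found in both orientations with identity", {
  set.seed(68)
  c1 <- rdna(5000)
  seg <- substr(c1, 1001, 1100)
  c2 <- paste0(rdna(2000), seg, rdna(2000))
  c3 <- paste0(rdna(1500), revcomp(seg), rdna(1500))
  d <- find_dispersed_repeats(c(a = c1, b = c2, d = c3))
  fwd <- d[d$chrom_1 == "a" & d$chrom_2 == "b", ]
  expect_equal(nrow(fwd), 1)
  expect_identical(fwd$orientation, "forward")
  expect_gte(fwd$length_bp, 100)
  pal <- d[d$chrom_1 == "a" & d$chrom_2 == "d", ]
  expect_identical(pal$orientation, "palindromic")
  # a copy with 5% substitutions reports identity within 0.02 of planted
  seg2 <- mutate_n(seg, 5)
  c4 <- paste0(rdna(1000), seg2, rdna(1000))
  d2 <- find_dispersed_repeats(c(a = c1, e = c4))
  expect_equal(nrow(d2), 1)
  expect_lt(abs(d2$identity - 0.95), 0.02)
})

test_that("dispersed records are deduplicated and orientation flips on revcomp", {
  set.seed(69)
  c1 <- rdna(4000)
  seg <- substr(c1, 501, 600)
  c2 <- paste0(rdna(1500), seg, rdna(1500))
  d <- find_dispersed_repeats(c(a = c1, b = c2))
  # no mirrored (b, a) duplicate of the (a, b) record
  expect_equal(nrow(d), 1)
  expect_identical(d$chrom_1, "a")
  # reverse-complementing one chromosome flips the orientation label
  d2 <- find_dispersed_repeats(c(a = c1, b = revcomp(c2)))
  expect_equal(nrow(d2), 1)
  expect_identical(d2$orientation, "palindromic")
})

test_that("hits inside tandem arrays are excluded when intervals are supplied", {
  set.seed(70)
  unit <- rdna(30)
  arr <- strrep(unit, 4)
  c1 <- paste0(rdna(1000), arr, rdna(1000))
  c2 <- paste0(rdna(800), arr, rdna(800))
  excl <- rbind(
    data.frame(chromosome = "a", start = 1000, end = 1000 + nchar(arr)),
    data.frame(chromosome = "b", start = 800, end = 800 + nchar(arr)))
  d_with <- find_dispersed_repeats(c(a = c1, b = c2), exclude = excl)
  d_without <- find_dispersed_repeats(c(a = c1, b = c2))
  expect_gt(nrow(d_without), nrow(d_with))
})

test_that("repeat summaries aggregate counts, classes and length bins", {
  set.seed(71)
  s1 <- paste0(rdna(300), strrep("A", 12), rdna(200), strrep("AAAC", 3),
               rdna(300))
  ssrs <- find_ssrs(s1, chrom = "c1")
  disp <- data.frame(chrom_1 = "c1", start_1 = c(0, 50, 100),
                     end_1 = c(35, 95, 160), chrom_2 = "c1",
                     start_2 = c(500, 600, 700), end_2 = c(535, 645, 760),
                     orientation = c("forward", "palindromic", "palindromic"),
                     length_bp = c(35, 45, 60), identity = 1,
                     e_value = 0, stringsAsFactors = FALSE)
  rs <- repeat_summary(ssrs = ssrs, tandems = NULL, dispersed = disp)
  expect_equal(unname(rs$totals[["all"]]), nrow(ssrs) + 3)
  expect_equal(unname(rs$dispersed_by_orientation),
               c(1L, 2L))
  expect_equal(rs$dispersed_length_histogram$bin_start, c(30, 40, 60))
  empty <- repeat_summary()
  expect_equal(unname(empty$totals), c(0L, 0L, 0L, 0L))
})

test_that("planted SSRs on the recovery fixture are found at exact coordinates", {
  fx <- recovery_fixture()
  man <- fx$sim$manifest[fx$sim$manifest$kind == "ssr", ]
  for (ch in unique(man$chrom)) {
    found <- find_ssrs(fx$sim$genome$seq[[ch]], chrom = ch, circular = TRUE)
    planted <- man[man$chrom == ch, ]
    for (i in seq_len(nrow(planted))) {
      r <- planted[i, ]
      motif <- sub("x.*", "", r$payload)
      copies <- as.integer(sub(".*x", "", r$payload))
      hit <- found[found$canonical_class == canonical_motif(motif) &
                     found$copy_number >= copies &
                     pmin(found$end, r$end) - pmax(found$start, r$start) >=
                       (r$end - r$start) - nchar(motif), ]
      expect_gte(nrow(hit), 1)
    }
  }
})
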