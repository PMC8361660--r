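# HRD scar scores against the brute-force definition scan, boundaries,
# merge invariance, composite classification

g <- toyGenomeBuild()

test_that("diploid heterozygous genomes score zero and classify negative", {
  dip <- do.call(rbind, lapply(chromNames(g), function(ch)
    seg_row(ch, 0, 100e6, 2L, 1L, 1L)))
  p <- SegmentProfile("d", dip, g)
  sc <- hrdScores(p, g)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(0, 0, 0))
  expect_false(isHRDPositive(hrdClassify(sc)))
})

test_that("LOH length boundary is strict and whole-chromosome LOH is excluded", {
  mk <- function(len) SegmentProfile("p", rbind(
    seg_row("chr1", 0, 30e6, 2L, 1L, 1L),
    seg_row("chr1", 30e6, 30e6 + len, 2L, 2L, 0L),
    seg_row("chr1", 30e6 + len, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(mk(20e6), g)$loh, 1)   # 20 Mb CNLOH
  expect_equal(hrdScores(mk(15e6), g)$loh, 0)   # 15.0 Mb exactly: strict >
  whole <- SegmentProfile("w", seg_row("chr1", 0, 100e6, 2L, 2L, 0L), g)
  expect_equal(hrdScores(whole, g)$loh, 0)
  expect_equal(hrdScores(whole, g,
                         exclude_whole_chrom_loh = FALSE)$loh, 1)
})

test_that("TAI requires terminal anchoring within one arm, longer than 11 Mb", {
  term <- SegmentProfile("t", rbind(
    seg_row("chr1", 0, 12e6, 3L, 2L, 1L),
    seg_row("chr1", 12e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(term, g)$tai, 1)
  short <- SegmentProfile("s", rbind(
    seg_row("chr1", 0, 11e6, 3L, 2L, 1L),    # 11.0 Mb exactly
    seg_row("chr1", 11e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(short, g)$tai, 0)
  interstitial <- SegmentProfile("i", rbind(
    seg_row("chr1", 0, 20e6, 2L, 1L, 1L),
    seg_row("chr1", 20e6, 40e6, 3L, 2L, 1L),
    seg_row("chr1", 40e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(interstitial, g)$tai, 0)
  crossing <- SegmentProfile("x", rbind(
    seg_row("chr1", 0, 60e6, 3L, 2L, 1L),    # crosses the centromere
    seg_row("chr1", 60e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(crossing, g)$tai, 0)
})

test_that("LST filters small segments then counts long-flank state changes", {
  two <- SegmentProfile("l", rbind(
    seg_row("chr1", 0, 20e6, 4L, 2L, 2L),
    seg_row("chr1", 20e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(two, g)$lst, 1)
  # a < 3 Mb interruption is removed and identical flanks re-merge
  interrupted <- SegmentProfile("i", rbind(
    seg_row("chr1", 0, 20e6, 4L, 2L, 2L),
    seg_row("chr1", 20e6, 22e6, 3L, 2L, 1L),
    seg_row("chr1", 22e6, 100e6, 4L, 2L, 2L)), g)
  expect_equal(hrdScores(interrupted, g)$lst, 0)
  # flank of exactly 10 Mb does not qualify (strict >)
  shortflank <- SegmentProfile("s", rbind(
    seg_row("chr1", 0, 10e6, 4L, 2L, 2L),
    seg_row("chr1", 10e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(hrdScores(shortflank, g)$lst, 0)
})

test_that("scores match the brute-force definition scan on random profiles", {
  set.seed(2024)
  for (i in 1:500) {
    p <- random_profile(g)
    sc <- hrdScores(p, g)
    expect_equal(c(sc$loh, sc$tai, sc$lst), unname(brute_hrd(p, g)))
  }
})

test_that("scores are invariant under segment splitting", {
  set.seed(77)
  for (i in 1:50) {
    p <- plantScarProfile(c(sample(0:2, 1), sample(0:2, 1),
                            sample(0:4, 1)), g)
    sc0 <- hrdScores(p, g)
    seg <- segments(p)
    # split random segments into identical-state pieces
    rows <- list()
    for (k in seq_len(nrow(seg))) {
      s <- seg[k, ]
      if (runif(1) < 0.4 && s$end - s$start > 2e6) {
        mid <- (s$start + s$end) / 2
        a <- s; a$end <- mid; b <- s; b$start <- mid
        rows[[k]] <- rbind(a, b)
      } else rows[[k]] <- s
    }
    ps <- SegmentProfile("split", do.call(rbind, rows), g)
    sc1 <- hrdScores(ps, g)
    expect_equal(sc1[c("loh", "tai", "lst")], sc0[c("loh", "tai", "lst")])
  }
})

test_that("composite classification follows the 42 threshold and BRCA route", {
  pos <- hrdClassify(c(14, 14, 14))
  expect_true(isHRDPositive(pos))
  expect_equal(scarTotal(pos), 42L)
  neg <- hrdClassify(c(14, 14, 13))
  expect_false(isHRDPositive(neg))
  brca <- hrdClassify(c(0, 0, 0), brca_status = "pathogenic")
  expect_true(isHRDPositive(brca))
  # strictly-greater variant of the cutoff
  expect_false(isHRDPositive(hrdClassify(c(14, 14, 14), rule = "gt")))
  expect_true(isHRDPositive(hrdClassify(c(14, 14, 15), rule = "gt")))
  # ploidy-adjusted LST is reported alongside the raw count
  p <- plantScarProfile(c(0, 0, 2), g)
  sc <- hrdScores(p, g)
  expect_equal(sc$lst_adjusted, sc$lst - 15.5 * (ploidy(p) - 2))
})

test_that("profiles without allele decomposition are rejected", {
  seg <- seg_row("chr1", 0, 100e6, 2L, 1L, 1L)
  p <- SegmentProfile("p", seg, g)
  p@segments$minor_cn <- NA_integer_
  expect_error(hrdScores(p, g), "decomposition")
})
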