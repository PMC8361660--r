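# CNA burden, Jaccard, event classification, complex-event detection

g <- toyGenomeBuild()

test_that("altered fraction counts non-diploid autosomal bases", {
  dip <- SegmentProfile("d", seg_row("chr1", 0, 100e6, 2L, 1L, 1L), g)
  expect_equal(alteredFraction(dip, g), 0)
  onegain <- SegmentProfile("gn", rbind(
    seg_row("chr1", 0, 100e6, 3L, 2L, 1L),
    seg_row("chr2", 0, 100e6, 2L, 1L, 1L)), g)
  expect_equal(alteredFraction(onegain, g), 0.1)
  mixed <- SegmentProfile("m", rbind(
    seg_row("chr1", 0, 25e6, 1L, 1L, 0L),
    seg_row("chr1", 25e6, 100e6, 2L, 1L, 1L),
    seg_row("chr3", 50e6, 90e6, 5L, 3L, 2L)), g)
  expect_equal(alteredFraction(mixed, g), (25e6 + 40e6) / 1e9)
  expect_error(alteredFraction(SegmentProfile("e", seg_row("chr1", 1, 2,
    2L, 1L, 1L)[0, ], g), g), "no autosomal")
})

test_that("CNA Jaccard compares direction of alteration base by base", {
  a <- SegmentProfile("a", rbind(seg_row("chr1", 0, 30e6, 3L, 2L, 1L),
                                 seg_row("chr1", 30e6, 100e6, 2L, 1L, 1L)), g)
  b <- SegmentProfile("b", rbind(seg_row("chr1", 0, 10e6, 2L, 1L, 1L),
                                 seg_row("chr1", 10e6, 40e6, 3L, 2L, 1L),
                                 seg_row("chr1", 40e6, 100e6, 2L, 1L, 1L)), g)
  expect_equal(jaccardCNA(a, b, g), 20e6 / 40e6)
  expect_equal(jaccardCNA(a, a, g), 1.0)
  c2 <- SegmentProfile("c", seg_row("chr2", 0, 30e6, 1L, 1L, 0L), g)
  expect_equal(jaccardCNA(a, c2, g), 0.0)
  # same bases altered in opposite directions do not count as shared
  d <- SegmentProfile("d", seg_row("chr1", 0, 30e6, 1L, 1L, 0L), g)
  expect_equal(jaccardCNA(a, d, g), 0.0)
  dip <- SegmentProfile("n", seg_row("chr1", 0, 100e6, 2L, 1L, 1L), g)
  expect_message(res <- jaccardCNA(dip, dip, g), "neutral")
  expect_equal(res, 1.0)
  # symmetry
  expect_equal(jaccardCNA(a, b, g), jaccardCNA(b, a, g))
})

test_that("event classification applies copy and length thresholds strictly", {
  p <- SegmentProfile("p", rbind(
    seg_row("chr1", 0, 2e6, 0L, 0L, 0L),        # biallelic del, focal
    seg_row("chr1", 2e6, 100e6, 2L, 1L, 1L),
    seg_row("chr2", 0, 1e6, 5L, 3L, 2L),        # amplification, focal
    seg_row("chr2", 1e6, 100e6, 2L, 1L, 1L),
    seg_row("chr3", 0, 9.99e6, 3L, 2L, 1L),     # gain, focal (strict <)
    seg_row("chr4", 0, 10e6, 3L, 2L, 1L),       # gain, broad (10.0 Mb)
    seg_row("chr5", 0, 50e6, 1L, 1L, 0L)), g)
  ev <- classifyCNAEvents(p, g)
  get <- function(ch) ev[ev$chrom == ch, ]
  expect_equal(get("chr1")$kind, "biallelic_deletion")
  expect_equal(get("chr1")$scope, "focal")
  expect_equal(get("chr2")$kind, "amplification")
  expect_equal(get("chr3")$scope, "focal")
  expect_equal(get("chr4")$scope, "broad")
  expect_equal(get("chr5")$kind, "loss")
  # adjacent same-direction segments merge before classification
  p2 <- SegmentProfile("q", rbind(
    seg_row("chr1", 0, 6e6, 3L, 2L, 1L),
    seg_row("chr1", 6e6, 12e6, 5L, 3L, 2L)), g)
  ev2 <- classifyCNAEvents(p2, g)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "amplification")   # run reaches 5 copies
  expect_equal(ev2$scope, "broad")          # merged length 12 Mb
})

test_that("planted oscillations and staircases are detected as complex events", {
  dip <- SegmentProfile("d", seg_row("chr1", 0, 100e6, 2L, 1L, 1L), g)
  expect_equal(nrow(detectComplexEvents(dip, g)), 0)

  base <- plantScarProfile(c(0, 0, 0), g)
  ct <- osteoevo:::.overlay_complex(base, g, "chr2", "chromothripsis")
  ev <- detectComplexEvents(ct, g)
  ev_ct <- ev[ev$complex_kind == "chromothripsis", ]
  expect_equal(nrow(ev_ct), 1)
  expect_equal(ev_ct$chrom, "chr2")
  # the call spans the planted 12-switch interval
  expect_lte(ev_ct$start, 5e6)
  expect_gte(ev_ct$end, 31e6)

  sa <- osteoevo:::.overlay_complex(base, g, "chr3", "staircase")
  ev <- detectComplexEvents(sa, g)
  ev_sa <- ev[grepl("staircase", ev$complex_kind), ]
  expect_equal(ev_sa$complex_kind, "staircase_telomeric")
  expect_equal(ev_sa$chrom, "chr3")

  # centromere-anchored ascent
  p_cen <- SegmentProfile("c", rbind(
    seg_row("chr4", 0, 20e6, 2L, 1L, 1L),
    seg_row("chr4", 20e6, 30e6, 3L, 2L, 1L),
    seg_row("chr4", 30e6, 40e6, 4L, 2L, 2L),
    seg_row("chr4", 40e6, 45e6, 5L, 3L, 2L),   # tops out at the centromere
    seg_row("chr4", 45e6, 100e6, 2L, 1L, 1L)), g)
  ev <- detectComplexEvents(p_cen, g)
  expect_true("staircase_centromeric" %in% ev$complex_kind)
})

test_that("scores and burdens ignore sex chromosomes", {
  gs <- GenomeBuild(data.frame(
    name = c("chr1", "chrX"), length = 100e6,
    centromere_start = 45e6, centromere_end = 55e6,
    is_sex = c(FALSE, TRUE)))
  p <- SegmentProfile("x", rbind(
    seg_row("chr1", 0, 100e6, 2L, 1L, 1L),
    seg_row("chrX", 0, 100e6, 5L, 5L, 0L)), gs)  # wild X ignored
  expect_equal(alteredFraction(p, gs), 0)
  sc <- hrdScores(p, gs)
  expect_equal(c(sc$loh, sc$tai, sc$lst), c(0, 0, 0))
  expect_equal(nrow(classifyCNAEvents(p, gs)), 0)
})
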