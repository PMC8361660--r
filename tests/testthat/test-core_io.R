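# genome-build, variant, segment and tree I/O

test_that("toy genome build loads with correct totals and invariants hold", {
  g <- toyGenomeBuild()
  expect_equal(length(chromNames(g)), 10)
  expect_equal(sum(chromLengths(g)), 1e9)
  expect_equal(autosomeNames(g), chromNames(g))

  path <- withr::local_tempfile(fileext = ".tsv")
  writeGenomeBuild(g, path)
  g2 <- loadGenomeBuild(path)
  expect_equal(g2@chromosomes, g@chromosomes)

  shipped <- loadGenomeBuild(system.file("extdata", "genome_toy.tsv",
                                         package = "osteoevo"))
  expect_equal(shipped@chromosomes$length, g@chromosomes$length)
})

test_that("genome build reader rejects invariant violations naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#name\tlength\tcentromere_start\tcentromere_end\tis_sex",
               "chr1\t100\t40\t120\t0"), path)
  expect_error(loadGenomeBuild(path), "line 2.*chr1")
  writeLines(c("#name\tlength\tcentromere_start\tcentromere_end\tis_sex",
               "chr1\t100\t40\t60\t0", "chr2\t100\t40"), path)
  expect_error(loadGenomeBuild(path), "malformed row at line 3")
})

test_that("variant tables round-trip through both dialects identically", {
  v <- make_variants(3, pos = c(100, 200, 300), ref = c("C", "G", "A"),
                     alt = c("T", "A", "G"),
                     effect = c("missense", "synonymous", "truncating"),
                     context = c("ACA", "TGT", NA),
                     samples = list(S1 = c(1, 0, 1), S2 = c(0, 1, 1)))
  v$mq_rank_sum[2] <- NA  # absent metric preserved, record retained
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantTable(v, tsv, "annotated_tsv")
  writeVariantTable(v, vcf, "vcf_subset")
  r1 <- readVariantTable(tsv, "annotated_tsv")
  r2 <- readVariantTable(vcf, "vcf_subset")
  expect_equal(r1, v, ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(is.na(r1$mq_rank_sum[2]))
  expect_true(is.na(r2$mq_rank_sum[2]))
  # same record set from both dialects
  expect_equal(r2[order(variantKey(r2)), names(r1)],
               r1[order(variantKey(r1)), ], ignore_attr = TRUE,
               tolerance = 1e-6)
  # presence flags match GT != 0/0
  expect_equal(r2$S1, c(1L, 0L, 1L))
  expect_equal(r2$S2, c(0L, 1L, 1L))
})

test_that("variant reader rejects invalid records instead of repairing", {
  v <- make_variants(1, effect = "weird")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(v, tsv)
  expect_error(readVariantTable(tsv), "unknown effect")
  v2 <- make_variants(1, samples = list(S1 = 0))
  writeVariantTable(v2, tsv)
  expect_error(readVariantTable(tsv), "at least one sample")
  v3 <- make_variants(1, context = "AAA")  # middle base != ref C
  writeVariantTable(v3, tsv)
  expect_error(readVariantTable(tsv), "middle base")
})

test_that("segment profiles compute length-weighted autosomal ploidy", {
  g <- toyGenomeBuild()
  p <- SegmentProfile("s", seg_row("chr1", 0, 100e6, 2L, 1L, 1L), g)
  expect_equal(ploidy(p), 2.0)
  whole <- do.call(rbind, lapply(chromNames(g), function(ch)
    seg_row(ch, 0, 100e6, 4L, 2L, 2L)))
  expect_equal(ploidy(SegmentProfile("s", whole, g)), 4.0)
  mixed <- rbind(seg_row("chr1", 0, 30e6, 4L, 2L, 2L),
                 seg_row("chr1", 30e6, 100e6, 2L, 1L, 1L))
  expect_equal(ploidy(SegmentProfile("s", mixed, g)),
               (30 * 4 + 70 * 2) / 100)
})

test_that("segment table round-trips and rejects overlaps naming the sample", {
  g <- toyGenomeBuild()
  p <- plantScarProfile(c(1, 1, 1), g, sample_id = "A")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSegmentTable(list(p), path)
  r <- readSegmentTable(path, g)
  expect_equal(segments(r$A), segments(p), ignore_attr = TRUE)
  expect_equal(ploidy(r$A), ploidy(p))

  writeLines(c("#sample\tchrom\tstart\tend\ttotal_cn\tmajor_cn\tminor_cn",
               "B\tchr1\t0\t50\t2\t1\t1", "B\tchr1\t40\t80\t2\t1\t1"),
             path)
  expect_error(readSegmentTable(path, g), "sample B.*overlap")
})

test_that("newick writer round-trips topology and serializes supports", {
  tr <- ape::read.tree(text = "((A,B),C,NORMAL);")
  path <- withr::local_tempfile(fileext = ".nwk")
  writeTreeNewick(tr, path)
  back <- readTreeNewick(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_true(ape::all.equal.phylo(ape::unroot(back), ape::unroot(tr),
                                   use.edge.length = FALSE))

  m <- perfect_matrix(3, per_edge = 2)
  ph <- inferPhylogeny(m, bootstrap_reps = 20, seed = 1)
  writeTreeNewick(ph, path)
  txt <- readLines(path)
  expect_match(txt, "0\\.\\d{3}")   # supports with three decimals
  back <- readTreeNewick(path)
  expect_equal(sum(back$edge.length), ncol(m))  # lengths = variant counts

  bad <- tr; bad$tip.label[1] <- ""
  expect_error(writeTreeNewick(bad, path), "labeled")
})
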