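# Homologous-recombination-deficiency genomic scar scores.
#
# Definitions (all strict inequalities; autosomes only; segments with
# identical allele-specific state merged before counting):
#   LOH: merged segments with minor copy number 0 and at least one copy
#        retained, longer than 15 Mb, not spanning an entire chromosome.
#   TAI: merged allele-imbalanced segments (major != minor) longer than
#        11 Mb, with one boundary at a chromosome terminus, entirely within
#        one arm (not crossing the centromere).
#   LST: after deleting segments shorter than 3 Mb and re-merging identical
#        flanking states, junctions where both flanking segments are longer
#        than 10 Mb and the allele-specific state changes.

#' HRD genomic scar component scores
#'
#' Computes the LOH, TAI and LST counts of one allele-specific copy-number
#' profile. The composite classification is done by [hrdClassify()].
#'
#' @param profile a [SegmentProfile-class] with major/minor decomposition.
#' @param genome a [GenomeBuild-class].
#' @param exclude_whole_chrom_loh exclude LOH segments spanning an entire
#'   chromosome (default `TRUE`, following the original score definition).
#' @param telomere_tol tolerance (bp) for a segment boundary to count as
#'   reaching a chromosome terminus (default 0: the segment must touch the
#'   chromosome end coordinate exactly).
#' @param lst_min_length flanking-segment length (bp) above which a
#'   junction can count as a large-scale transition.
#' @param lst_filter length (bp) below which segments are removed before
#'   LST counting.
#' @return list with integer `loh`, `tai`, `lst`, and numeric
#'   `lst_adjusted` (linear ploidy correction `lst - 15.5 * (ploidy - 2)`,
#'   reported alongside the raw count).
#' @seealso [hrdClassify()], [plantScarProfile()]
#' @export
hrdScores <- function(profile, genome, exclude_whole_chrom_loh = TRUE,
                      telomere_tol = 0, lst_min_length = 10e6,
                      lst_filter = 3e6) {
  seg <- .autosomal_segments(profile, genome)
  if (nrow(seg) == 0) stop("profile has no autosomal segments")
  if (any(is.na(seg$major_cn)) || any(is.na(seg$minor_cn)))
    stop("profile lacks major/minor allele decomposition")
  seg <- .merge_identical(seg)
  lens <- chromLengths(genome)
  cent <- centromeres(genome)
  len <- seg$end - seg$start

  # LOH
  is_loh <- seg$minor_cn == 0 & seg$total_cn >= 1 & len > 15e6
  if (exclude_whole_chrom_loh) {
    whole <- seg$start <= telomere_tol &
      seg$end >= lens[seg$chrom] - telomere_tol
    is_loh <- is_loh & !whole
  }
  loh <- sum(is_loh)

  # TAI
  cs <- cent$centromere_start[match(seg$chrom, cent$name)]
  ce <- cent$centromere_end[match(seg$chrom, cent$name)]
  p_term <- seg$start <= telomere_tol & seg$end <= ce
  q_term <- seg$end >= lens[seg$chrom] - telomere_tol & seg$start >= cs
  tai <- sum(seg$major_cn != seg$minor_cn & len > 11e6 &
               (p_term | q_term) &
               !(seg$start <= telomere_tol &
                 seg$end >= lens[seg$chrom] - telomere_tol))

  # LST
  small <- (seg$end - seg$start) < lst_filter
  lseg <- .merge_identical(seg[!small, , drop = FALSE])
  lst <- 0L
  if (nrow(lseg) > 1) {
    same_chrom <- lseg$chrom[-1] == lseg$chrom[-nrow(lseg)]
    llen <- lseg$end - lseg$start
    big_pair <- llen[-1] > lst_min_length &
      llen[-nrow(lseg)] > lst_min_length
    state_change <- lseg$major_cn[-1] != lseg$major_cn[-nrow(lseg)] |
      lseg$minor_cn[-1] != lseg$minor_cn[-nrow(lseg)]
    lst <- sum(same_chrom & big_pair & state_change)
  }
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst),
       lst_adjusted = lst - 15.5 * (ploidy(profile) - 2))
}

#' Composite HRD classification
#'
#' A sample is HRD-positive when the summed scar score (LOH + TAI + LST)
#' reaches the threshold (default 42, the raw-sum convention) or when a
#' pathogenic BRCA1/BRCA2 mutation is reported, whichever route fires.
#'
#' @param scores list with `loh`, `tai`, `lst` (e.g. from [hrdScores()]),
#'   or a numeric length-3 vector.
#' @param threshold composite threshold (default 42).
#' @param brca_status `"wildtype"` or `"pathogenic"`.
#' @param rule `"ge"` (positive at threshold or higher, default) or `"gt"`
#'   (strictly above threshold).
#' @return an [HRDResult-class].
#' @export
hrdClassify <- function(scores, threshold = 42,
                        brca_status = c("wildtype", "pathogenic"),
                        rule = c("ge", "gt")) {
  brca_status <- match.arg(brca_status)
  rule <- match.arg(rule)
  if (is.numeric(scores) && length(scores) >= 3)
    scores <- list(loh = scores[[1]], tai = scores[[2]], lst = scores[[3]])
  stopifnot(scores$loh >= 0, scores$tai >= 0, scores$lst >= 0)
  total <- as.integer(scores$loh + scores$tai + scores$lst)
  score_pos <- if (rule == "ge") total >= threshold else total > threshold
  eff_threshold <- if (rule == "ge") threshold else threshold + 1e-9
  new("HRDResult", loh = as.integer(scores$loh),
      tai = as.integer(scores$tai), lst = as.integer(scores$lst),
      total = total,
      lst_adjusted = if (!is.null(scores$lst_adjusted))
        scores$lst_adjusted else as.numeric(scores$lst),
      positive = score_pos || brca_status == "pathogenic",
      brca_status = brca_status, threshold = eff_threshold)
}
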