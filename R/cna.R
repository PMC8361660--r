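# Copy-number analytics: genome-wide burden, pairwise Jaccard similarity,
# focal/broad and amplification/deletion event classification, and
# detection of chromothripsis-like oscillations and centromere/telomere
# anchored staircase amplifications. Sex chromosomes are excluded from all
# computations here (they are carried through I/O only).

.autosomal_segments <- function(profile, genome) {
  s <- segments(profile)
  s[s$chrom %in% autosomeNames(genome), , drop = FALSE]
}

# merge consecutive segments (per chromosome) with identical allele state
.merge_identical <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  key <- paste(seg$chrom, seg$total_cn, seg$major_cn, seg$minor_cn)
  newrun <- c(TRUE, key[-1] != key[-nrow(seg)])
  grp <- cumsum(newrun)
  out <- seg[newrun, , drop = FALSE]
  out$end <- tapply(seg$end, grp, max)
  rownames(out) <- NULL
  out
}

#' Fraction of the autosomal genome altered by copy number
#'
#' Autosomal bases with total copy number different from 2, divided by the
#' total autosomal length of the build; uncovered regions count as neutral.
#'
#' @param profile a [SegmentProfile-class].
#' @param genome a [GenomeBuild-class].
#' @return numeric in \[0, 1\].
#' @export
alteredFraction <- function(profile, genome) {
  seg <- .autosomal_segments(profile, genome)
  if (nrow(seg) == 0) stop("profile has no autosomal segments")
  altered <- sum((seg$end - seg$start)[seg$total_cn != 2])
  total <- sum(chromLengths(genome)[autosomeNames(genome)])
  altered / total
}

# piecewise CNA direction (-1 loss, 0 neutral, +1 gain) per base, evaluated
# at the union of breakpoints of two profiles on one chromosome
.direction_track <- function(seg, L) {
  # returns function(starts, ends) -> direction of each interval
  function(starts, ends) {
    out <- integer(length(starts))
    for (i in seq_along(starts)) {
      hit <- which(seg$start <= starts[i] & seg$end >= ends[i])
      out[i] <- if (length(hit)) sign(seg$total_cn[hit[1]] - 2L) else 0L
    }
    out
  }
}

#' Jaccard similarity of two copy-number profiles
#'
#' Every autosomal base is classified as loss, neutral, or gain by total
#' copy number versus 2; the similarity is the number of bases altered in
#' both profiles *in the same direction* over the number altered in either.
#' Two fully neutral profiles are defined as similarity 1 (with a notice).
#'
#' @param a,b [SegmentProfile-class] objects on the same build.
#' @param genome a [GenomeBuild-class].
#' @return numeric in \[0, 1\].
#' @export
jaccardCNA <- function(a, b, genome) {
  sa <- .autosomal_segments(a, genome)
  sb <- .autosomal_segments(b, genome)
  num <- 0; den <- 0
  for (ch in autosomeNames(genome)) {
    xa <- sa[sa$chrom == ch, , drop = FALSE]
    xb <- sb[sb$chrom == ch, , drop = FALSE]
    if (!nrow(xa) && !nrow(xb)) next
    L <- chromLengths(genome)[[ch]]
    bp <- sort(unique(c(0, L, xa$start, xa$end, xb$start, xb$end)))
    bp <- bp[bp >= 0 & bp <= L]
    starts <- bp[-length(bp)]; ends <- bp[-1]
    da <- .direction_track(xa, L)(starts, ends)
    db <- .direction_track(xb, L)(starts, ends)
    w <- ends - starts
    num <- num + sum(w[da != 0 & da == db])
    den <- den + sum(w[da != 0 | db != 0])
  }
  if (den == 0) {
    message("both profiles fully copy-neutral; Jaccard defined as 1")
    return(1.0)
  }
  num / den
}

#' Classify copy-number events
#'
#' Adjacent same-direction segments are merged, then each merged run is
#' classified: gain (total > 2) or loss (total < 2); upgraded to
#' amplification when the run reaches `amp_threshold` copies (default 5+)
#' or to biallelic deletion when both copies are lost; focal when shorter
#' than `focal_threshold` (default the common 10 Mb cytogenetic cutoff,
#' strict), else broad.
#'
#' @param profile a [SegmentProfile-class].
#' @param genome a [GenomeBuild-class].
#' @param amp_threshold total copy number at or above which a gain is an
#'   amplification.
#' @param focal_threshold length (bp) below which an event is focal.
#' @return data.frame of events: `chrom`, `start`, `end`, `kind`
#'   (gain/loss/amplification/biallelic_deletion), `scope` (focal/broad),
#'   `total_cn` (extreme copy number of the run).
#' @export
classifyCNAEvents <- function(profile, genome, amp_threshold = 5,
                              focal_threshold = 10e6) {
  seg <- .autosomal_segments(profile, genome)
  seg <- seg[seg$total_cn != 2, , drop = FALSE]
  if (nrow(seg) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), kind = character(0),
                      scope = character(0), total_cn = integer(0)))
  dir <- sign(seg$total_cn - 2L)
  key <- paste(seg$chrom, dir)
  newrun <- c(TRUE, key[-1] != key[-nrow(seg)] |
                seg$start[-1] != seg$end[-nrow(seg)])
  grp <- cumsum(newrun)
  ev <- data.frame(
    chrom = tapply(seg$chrom, grp, `[`, 1),
    start = as.numeric(tapply(seg$start, grp, min)),
    end = as.numeric(tapply(seg$end, grp, max)),
    dir = tapply(dir, grp, `[`, 1),
    total_cn = as.integer(ifelse(tapply(dir, grp, `[`, 1) > 0,
                                 tapply(seg$total_cn, grp, max),
                                 tapply(seg$total_cn, grp, min))))
  ev$kind <- ifelse(ev$dir > 0,
                    ifelse(ev$total_cn >= amp_threshold, "amplification",
                           "gain"),
                    ifelse(ev$total_cn == 0, "biallelic_deletion", "loss"))
  ev$scope <- ifelse(ev$end - ev$start < focal_threshold, "focal", "broad")
  rownames(ev) <- NULL
  ev[, c("chrom", "start", "end", "kind", "scope", "total_cn")]
}

#' Detect chromothripsis-like oscillations and staircase amplifications
#'
#' Chromothripsis: a maximal run of consecutive segments oscillating among
#' at most `max_states` distinct total copy numbers with at least
#' `min_oscillations` state switches. Staircase: a run of at least
#' `min_steps` strictly monotonically changing total copy numbers whose
#' highest-copy boundary lies within `anchor_window` of a centromere edge
#' (centromeric) or a chromosome end (telomeric).
#'
#' @param profile a [SegmentProfile-class].
#' @param genome a [GenomeBuild-class].
#' @param params list overriding `min_oscillations` (10), `max_states` (3),
#'   `min_steps` (3), `anchor_window` (1e6).
#' @return data.frame `chrom`, `start`, `end`, `complex_kind`
#'   (chromothripsis / staircase_centromeric / staircase_telomeric),
#'   `n_segments`.
#' @export
detectComplexEvents <- function(profile, genome, params = list()) {
  p <- utils::modifyList(list(min_oscillations = 10, max_states = 3,
                              min_steps = 3, anchor_window = 1e6), params)
  out <- list()
  cent <- centromeres(genome)
  allseg <- .merge_identical(.autosomal_segments(profile, genome))
  for (ch in autosomeNames(genome)) {
    seg <- allseg[allseg$chrom == ch, , drop = FALSE]
    if (nrow(seg) < 2) next
    cn <- seg$total_cn
    L <- chromLengths(genome)[[ch]]
    ci <- cent[cent$name == ch, ]
    # chromothripsis: greedy maximal windows
    i <- 1L
    while (i <= length(cn)) {
      j <- i
      states <- cn[i]
      while (j < length(cn) &&
             length(unique(c(states, cn[j + 1]))) <= p$max_states) {
        j <- j + 1L
        states <- unique(c(states, cn[j]))
      }
      switches <- if (j > i) sum(cn[i:(j - 1)] != cn[(i + 1):j]) else 0L
      if (switches >= p$min_oscillations) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = seg$start[i], end = seg$end[j],
          complex_kind = "chromothripsis", n_segments = j - i + 1L)
        i <- j + 1L
      } else i <- i + 1L
    }
    # staircases: strictly monotone runs, anchored at the high-copy end
    d <- sign(diff(cn))
    runs <- rle(d)
    pos <- cumsum(c(1, runs$lengths))
    for (k in seq_along(runs$lengths)) {
      if (runs$values[k] == 0) next
      i0 <- pos[k]; i1 <- pos[k + 1]     # segments i0..i1 form the run
      nseg <- i1 - i0 + 1L
      if (nseg < p$min_steps) next
      if (runs$values[k] > 0) {          # rising toward the q side
        anchor <- seg$end[i1]
        kind <- if (abs(L - anchor) <= p$anchor_window) "staircase_telomeric"
        else if (abs(anchor - ci$centromere_start) <= p$anchor_window ||
                 abs(anchor - ci$centromere_end) <= p$anchor_window)
          "staircase_centromeric" else NA
      } else {                           # rising toward the p side
        anchor <- seg$start[i0]
        kind <- if (anchor <= p$anchor_window) "staircase_telomeric"
        else if (abs(anchor - ci$centromere_start) <= p$anchor_window ||
                 abs(anchor - ci$centromere_end) <= p$anchor_window)
          "staircase_centromeric" else NA
      }
      if (!is.na(kind))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = seg$start[i0], end = seg$end[i1],
          complex_kind = kind, n_segments = nseg)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), complex_kind = character(0),
                      n_segments = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
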