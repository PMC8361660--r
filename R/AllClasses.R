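#' @import methods
NULL

# ---------------------------------------------------------------------------
# GenomeBuild
# ---------------------------------------------------------------------------

#' Genome build: chromosome lengths and centromere anchors
#'
#' A `GenomeBuild` carries the coordinate frame every range-based computation
#' in the package uses: ordered chromosomes with their lengths, centromere
#' intervals, and a sex-chromosome flag. Centromere and telomere anchors are
#' what the telomeric-allelic-imbalance score and staircase detection test
#' against; sex chromosomes are carried through I/O but excluded from all
#' scar and burden computations.
#'
#' @slot chromosomes a `data.frame` with columns `name`, `length`,
#'   `centromere_start`, `centromere_end` (base pairs, 0-based half-open
#'   interval) and logical `is_sex`.
#' @seealso [loadGenomeBuild()], [toyGenomeBuild()], [grch37GenomeBuild()]
#' @export
setClass("GenomeBuild", representation(chromosomes = "data.frame"))

setValidity("GenomeBuild", function(object) {
  ch <- object@chromosomes
  need <- c("name", "length", "centromere_start", "centromere_end", "is_sex")
  if (!all(need %in% names(ch)))
    return(paste("chromosome table must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(ch$name)) return("chromosome names must be unique")
  if (any(ch$length <= 0)) return("chromosome lengths must be > 0")
  bad <- !(ch$centromere_start >= 0 &
           ch$centromere_start < ch$centromere_end &
           ch$centromere_end <= ch$length)
  if (any(bad))
    return(paste0("invalid centromere interval on chromosome(s): ",
                  paste(ch$name[bad], collapse = ", ")))
  TRUE
})

#' Construct a GenomeBuild from a chromosome table
#'
#' @param chromosomes data.frame with columns `name`, `length`,
#'   `centromere_start`, `centromere_end`, `is_sex`.
#' @return a [GenomeBuild-class] object.
#' @export
GenomeBuild <- function(chromosomes) {
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$is_sex <- as.logical(chromosomes$is_sex)
  rownames(chromosomes) <- NULL
  new("GenomeBuild", chromosomes = chromosomes)
}

#' @describeIn GenomeBuild chromosome names, in build order.
#' @param x a `GenomeBuild`.
#' @export
chromNames <- function(x) x@chromosomes$name

#' @describeIn GenomeBuild named vector of chromosome lengths (bp).
#' @export
chromLengths <- function(x) {
  stats::setNames(x@chromosomes$length, x@chromosomes$name)
}

#' @describeIn GenomeBuild names of the autosomes only.
#' @export
autosomeNames <- function(x) x@chromosomes$name[!x@chromosomes$is_sex]

#' @describeIn GenomeBuild centromere intervals as a data.frame
#'   (`name`, `centromere_start`, `centromere_end`).
#' @export
centromeres <- function(x) {
  x@chromosomes[, c("name", "centromere_start", "centromere_end")]
}

setMethod("show", "GenomeBuild", function(object) {
  ch <- object@chromosomes
  cat("GenomeBuild:", nrow(ch), "chromosomes (",
      sum(!ch$is_sex), "autosomes ),",
      format(sum(ch$length), big.mark = ","), "bp total\n")
})

#' A small synthetic genome build for examples and tests
#'
#' Ten equal autosomes with a centrally placed centromere. Coordinates are
#' 0-based half-open, like all segment coordinates in the package.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param centromere numeric length-2 vector, centromere interval in bp.
#' @return a [GenomeBuild-class].
#' @export
toyGenomeBuild <- function(n_chrom = 10, chrom_length = 100e6,
                           centromere = c(45e6, 55e6)) {
  GenomeBuild(data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length = chrom_length,
    centromere_start = centromere[1],
    centromere_end = centromere[2],
    is_sex = FALSE))
}

#' The shipped GRCh37 genome build
#'
#' Loads the static GRCh37 chromosome-length/centromere table shipped with
#' the package (`inst/extdata/genome_grch37.tsv`); see that file's header
#' for coordinate provenance.
#'
#' @return a [GenomeBuild-class] with chromosomes 1-22, X, Y.
#' @export
grch37GenomeBuild <- function() {
  loadGenomeBuild(system.file("extdata", "genome_grch37.tsv",
                              package = "osteoevo", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# SegmentProfile
# ---------------------------------------------------------------------------

#' Allele-specific copy-number profile of one sample
#'
#' Ordered, non-overlapping segments with total/major/minor copy number.
#' Coordinates are 0-based half-open (SEG/BED convention). Ploidy is the
#' length-weighted mean total copy number over autosomal segments.
#'
#' @slot sample_id sample label.
#' @slot segments data.frame with columns `chrom`, `start`, `end`,
#'   `total_cn`, `major_cn`, `minor_cn`.
#' @slot ploidy length-weighted mean autosomal total copy number.
#' @seealso [readSegmentTable()], [hrdScores()], [plantScarProfile()]
#' @export
setClass("SegmentProfile",
         representation(sample_id = "character", segments = "data.frame",
                        ploidy = "numeric"))

setValidity("SegmentProfile", function(object) {
  s <- object@segments
  need <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn")
  if (!all(need %in% names(s)))
    return(paste("segment table must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) == 0) return(TRUE)
  if (any(s$start >= s$end)) return("segment start must be < end")
  if (any(s$total_cn < 0)) return("total_cn must be >= 0")
  if (any(s$minor_cn > s$major_cn)) return("minor_cn must be <= major_cn")
  if (any(s$total_cn != s$major_cn + s$minor_cn))
    return("total_cn must equal major_cn + minor_cn")
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, , drop = FALSE]
    if (is.unsorted(x$start, strictly = TRUE) && nrow(x) > 1)
      return(paste("segments not sorted on chromosome", ch))
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      return(paste("overlapping segments on chromosome", ch))
  }
  TRUE
})

#' Construct a SegmentProfile
#'
#' @param sample_id sample label.
#' @param segments segment data.frame (`chrom`, `start`, `end`, `total_cn`,
#'   `major_cn`, `minor_cn`); rows are sorted per chromosome.
#' @param genome a [GenomeBuild-class], used to identify autosomes for the
#'   ploidy computation.
#' @return a [SegmentProfile-class].
#' @export
SegmentProfile <- function(sample_id, segments, genome) {
  segments <- segments[order(match(segments$chrom, chromNames(genome)),
                             segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  auto <- segments[segments$chrom %in% autosomeNames(genome), , drop = FALSE]
  ploidy <- if (nrow(auto) == 0) NA_real_ else {
    w <- auto$end - auto$start
    sum(w * auto$total_cn) / sum(w)
  }
  new("SegmentProfile", sample_id = sample_id, segments = segments,
      ploidy = ploidy)
}

#' @describeIn SegmentProfile the segment data.frame.
#' @param x a `SegmentProfile`.
#' @export
segments <- function(x) x@segments

#' @describeIn SegmentProfile the sample label.
#' @export
sampleId <- function(x) x@sample_id

#' @describeIn SegmentProfile length-weighted mean autosomal total copy
#'   number.
#' @export
ploidy <- function(x) x@ploidy

setMethod("show", "SegmentProfile", function(object) {
  cat("SegmentProfile", object@sample_id, ":", nrow(object@segments),
      "segments, ploidy", round(object@ploidy, 3), "\n")
})

# ---------------------------------------------------------------------------
# HRDResult
# ---------------------------------------------------------------------------

#' Homologous-recombination-deficiency scar result
#'
#' The three genomic-scar components (LOH, TAI, LST), their sum, and the
#' composite positivity call. A sample is positive when the summed score
#' reaches the threshold (default 42) or when a pathogenic BRCA1/BRCA2
#' mutation is present.
#'
#' @slot loh,tai,lst integer component scores.
#' @slot total integer, `loh + tai + lst`.
#' @slot lst_adjusted numeric, ploidy-adjusted LST (reported alongside the
#'   raw count; the composite uses the raw count).
#' @slot positive logical composite call.
#' @slot brca_status `"wildtype"` or `"pathogenic"`.
#' @slot threshold numeric threshold used for the composite call.
#' @seealso [hrdScores()], [hrdClassify()]
#' @export
setClass("HRDResult",
         representation(loh = "integer", tai = "integer", lst = "integer",
                        total = "integer", lst_adjusted = "numeric",
                        positive = "logical", brca_status = "character",
                        threshold = "numeric"))

setValidity("HRDResult", function(object) {
  if (any(c(object@loh, object@tai, object@lst) < 0))
    return("scar components must be >= 0")
  if (object@total != object@loh + object@tai + object@lst)
    return("total must equal loh + tai + lst")
  if (!object@brca_status %in% c("wildtype", "pathogenic"))
    return("brca_status must be 'wildtype' or 'pathogenic'")
  want <- (object@total >= object@threshold) ||
    object@brca_status == "pathogenic"
  if (!identical(object@positive, want))
    return("positive flag inconsistent with total/threshold/brca_status")
  TRUE
})

setMethod("show", "HRDResult", function(object) {
  cat(sprintf("HRDResult: LOH %d + TAI %d + LST %d = %d (threshold %g, BRCA %s) -> %s\n",
              object@loh, object@tai, object@lst, object@total,
              object@threshold, object@brca_status,
              if (object@positive) "POSITIVE" else "negative"))
})

#' @describeIn HRDResult named integer vector of the three components.
#' @param x an `HRDResult`.
#' @export
scarCounts <- function(x) c(loh = x@loh, tai = x@tai, lst = x@lst)

#' @describeIn HRDResult the composite sum.
#' @export
scarTotal <- function(x) x@total

#' @describeIn HRDResult logical positivity call.
#' @export
isHRDPositive <- function(x) x@positive

# ---------------------------------------------------------------------------
# TumorPhylogeny
# ---------------------------------------------------------------------------

#' Maximum-parsimony sample phylogeny
#'
#' A rooted tree over the tumor samples of one patient plus the matched
#' normal (the outgroup at the root), together with the parsimony score,
#' homoplasy index, per-edge variant assignment, trunk designation, and
#' optional bootstrap supports for tumor clades.
#'
#' @slot tree an `ape` `phylo`, rooted at the outgroup.
#' @slot outgroup outgroup (normal sample) label.
#' @slot score total number of character state changes on the tree.
#' @slot homoplasy_index `1 - (number of variants) / score`.
#' @slot edge_variants list: for each edge index (as character), the variant
#'   identifiers assigned to that edge.
#' @slot trunk_edge integer index (into `tree$edge`) of the trunk.
#' @slot homoplastic identifiers of variants whose carrier set matches no
#'   single edge (assigned to all change edges of one minimal labeling).
#' @slot supports named numeric in \[0,1\]: bootstrap support per tumor
#'   clade (names are `+`-joined sorted tumor labels); empty if bootstrap
#'   was not run.
#' @seealso [inferPhylogeny()], [searchTrees()], [assignVariantsToEdges()]
#' @export
setClass("TumorPhylogeny",
         representation(tree = "ANY", outgroup = "character",
                        score = "numeric", homoplasy_index = "numeric",
                        edge_variants = "list", trunk_edge = "integer",
                        homoplastic = "character", supports = "numeric"))

setValidity("TumorPhylogeny", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a 'phylo'")
  if (!object@outgroup %in% object@tree$tip.label)
    return("outgroup must be a tip of the tree")
  if (length(object@supports) &&
      (any(object@supports < 0) || any(object@supports > 1)))
    return("supports must lie in [0, 1]")
  if (object@homoplasy_index < 0 || object@homoplasy_index >= 1)
    return("homoplasy index must lie in [0, 1)")
  TRUE
})

setMethod("show", "TumorPhylogeny", function(object) {
  nv <- length(unique(unlist(object@edge_variants)))
  cat(sprintf("TumorPhylogeny: %d tips (outgroup %s), length %d, HI %.3f, %d variants assigned\n",
              length(object@tree$tip.label), object@outgroup,
              as.integer(object@score), object@homoplasy_index, nv))
})

#' @describeIn TumorPhylogeny the underlying `phylo` tree.
#' @param x a `TumorPhylogeny`.
#' @export
phyloTree <- function(x) x@tree

#' @describeIn TumorPhylogeny per-edge variant assignment (list indexed by
#'   edge number as character).
#' @export
edgeVariants <- function(x) x@edge_variants

#' @describeIn TumorPhylogeny variant identifiers assigned to the trunk.
#' @export
trunkVariants <- function(x) {
  if (is.na(x@trunk_edge)) character(0)
  else x@edge_variants[[as.character(x@trunk_edge)]]
}

#' @describeIn TumorPhylogeny bootstrap supports per tumor clade.
#' @export
cladeSupports <- function(x) x@supports
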