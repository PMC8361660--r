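# Hard quality filtering and in-silico pathogenicity prioritization of
# annotated somatic variants. All inequalities are strict, exactly as the
# thresholds are stated: boundary values fail.

#' Variant filter policy
#'
#' Bundles the hard caller-quality thresholds, the in-silico pathogenicity
#' thresholds, and the curated-pathogenic rescue list. Defaults are the
#' standard GATK-style hard filters (QD > 10, MQ > 40, FS < 30, SOR < 3,
#' MQRankSum > -12.5, ReadPosRankSum > -8) and the usual in-silico panel
#' (SIFT < 0.05, PolyPhen2 > 0.7, MutationTaster > 0.7, GERP++ > 0,
#' CADD > 10, PhyloP > 0).
#'
#' @param qd,mq,fs,sor,mq_rank_sum,read_pos_rank_sum hard-filter thresholds.
#' @param sift,polyphen2,mutation_taster,gerp,cadd,phylop pathogenicity
#'   thresholds.
#' @param keep_truncating_splice keep all protein-truncating and splice-site
#'   variants regardless of scores.
#' @param curated_pathogenic data.frame with columns `gene` and `key`
#'   (a [variantKey()] string): variants rescued by curated evidence.
#' @return a `filter_policy` list.
#' @export
filterPolicy <- function(qd = 10, mq = 40, fs = 30, sor = 3,
                         mq_rank_sum = -12.5, read_pos_rank_sum = -8,
                         sift = 0.05, polyphen2 = 0.7,
                         mutation_taster = 0.7, gerp = 0, cadd = 10,
                         phylop = 0, keep_truncating_splice = TRUE,
                         curated_pathogenic = NULL) {
  pol <- list(qd = qd, mq = mq, fs = fs, sor = sor,
              mq_rank_sum = mq_rank_sum,
              read_pos_rank_sum = read_pos_rank_sum,
              sift = sift, polyphen2 = polyphen2,
              mutation_taster = mutation_taster, gerp = gerp, cadd = cadd,
              phylop = phylop,
              keep_truncating_splice = keep_truncating_splice,
              curated_pathogenic = curated_pathogenic)
  stopifnot(all(is.finite(unlist(pol[1:12]))))
  structure(pol, class = "filter_policy")
}

#' Apply hard caller-quality filters
#'
#' A variant is retained iff every *present* quality metric satisfies its
#' strict inequality; absent metrics never fail a record (rank-sum
#' annotations are undefined for some genotype configurations). Filtering is
#' total and idempotent.
#'
#' @param variants a variant table.
#' @param policy a [filterPolicy()].
#' @return list with `retained` (variant table), `removed` (variant table)
#'   and `reasons` (data.frame `key`, `reasons`; one row per removed
#'   variant, reasons comma-joined metric names).
#' @export
applyHardFilters <- function(variants, policy = filterPolicy()) {
  checks <- list(
    QD = variants$qd > policy$qd,
    MQ = variants$mq > policy$mq,
    FS = variants$fs < policy$fs,
    SOR = variants$sor < policy$sor,
    MQRankSum = variants$mq_rank_sum > policy$mq_rank_sum,
    ReadPosRankSum = variants$read_pos_rank_sum > policy$read_pos_rank_sum)
  fail <- vapply(checks, function(ok) !is.na(ok) & !ok,
                 logical(nrow(variants)))
  if (nrow(variants) == 1) fail <- matrix(fail, nrow = 1,
                                          dimnames = list(NULL, names(checks)))
  removed <- rowSums(fail) > 0
  reasons <- if (!any(removed))
    data.frame(key = character(0), reasons = character(0))
  else data.frame(
    key = variantKey(variants[removed, , drop = FALSE]),
    reasons = apply(fail[removed, , drop = FALSE], 1, function(f)
      paste(names(checks)[f], collapse = ",")),
    row.names = NULL)
  list(retained = variants[!removed, , drop = FALSE],
       removed = variants[removed, , drop = FALSE],
       reasons = reasons)
}

#' Prioritize putatively pathogenic variants
#'
#' A variant is kept iff (a) its effect is truncating or splice (these
#' override failing scores), or (b) it is on the curated pathogenic list,
#' or (c) *all six* in-silico scores are present and pass their strict
#' thresholds. A record missing any score cannot pass the in-silico route.
#'
#' @param variants a variant table.
#' @param policy a [filterPolicy()].
#' @return the prioritized subset of `variants`.
#' @export
prioritizePathogenic <- function(variants, policy = filterPolicy()) {
  if (nrow(variants) == 0) return(variants)
  trunc_ok <- policy$keep_truncating_splice &
    variants$effect %in% c("truncating", "splice")
  cur <- policy$curated_pathogenic
  curated_ok <- if (is.null(cur) || nrow(cur) == 0) rep(FALSE, nrow(variants))
  else paste(variants$gene, variantKey(variants)) %in%
    paste(cur$gene, cur$key)
  pass <- function(x, thr, lower = FALSE) {
    out <- if (lower) x < thr else x > thr
    out & !is.na(out)
  }
  insilico_ok <- pass(variants$sift, policy$sift, lower = TRUE) &
    pass(variants$polyphen2, policy$polyphen2) &
    pass(variants$mutation_taster, policy$mutation_taster) &
    pass(variants$gerp, policy$gerp) &
    pass(variants$cadd, policy$cadd) &
    pass(variants$phylop, policy$phylop)
  variants[trunc_ok | curated_ok | insilico_ok, , drop = FALSE]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Six-class substitution spectrum
#'
#' Counts SNVs into the six pyrimidine-convention substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference variants are
#' reverse-complemented. Non-SNV records are skipped with a notice.
#'
#' @param variants a variant table.
#' @return named integer vector of length 6, summing to the SNV count.
#' @export
spectrum6 <- function(variants) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- stats::setNames(integer(6), classes)
  if (nrow(variants) == 0) return(out)
  snv <- .is_snv(variants)
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) skipped by spectrum6")
  ref <- variants$ref[snv]; alt <- variants$alt[snv]
  purine <- ref %in% c("A", "G")
  ref[purine] <- .complement[ref[purine]]
  alt[purine] <- .complement[alt[purine]]
  tab <- table(factor(paste0(ref, ">", alt), levels = classes))
  out[] <- as.integer(tab)
  out
}
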