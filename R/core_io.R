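# Readers/writers for every external format the pipeline touches.
#
# Conventions (documented in every file header the writers emit):
#   * variant positions: 1-based (VCF convention)
#   * segment coordinates: 0-based half-open (SEG/BED convention)
#   * TSVs: UTF-8, '#'-prefixed column header, '.' for missing values

# Fixed (non-sample) columns of the annotated variant table, in order.
.variant_fixed_cols <- c(
  "chrom", "pos", "ref", "alt", "gene", "effect", "context",
  "sift", "polyphen2", "mutation_taster", "gerp", "cadd", "phylop",
  "qd", "mq", "fs", "sor", "mq_rank_sum", "read_pos_rank_sum", "clonality")

.effect_levels <- c("synonymous", "missense", "truncating", "splice",
                    "noncoding")

#' Sample labels of a variant table
#'
#' Variant tables are data.frames whose fixed annotation columns are followed
#' by one binary presence column per sample; this returns those sample
#' labels.
#'
#' @param variants a variant table as returned by [readVariantTable()].
#' @return character vector of sample labels.
#' @export
variantSamples <- function(variants) {
  setdiff(colnames(variants), .variant_fixed_cols)
}

#' Canonical variant identifier
#'
#' @param variants a variant table.
#' @return character vector `chrom:pos:ref>alt`.
#' @export
variantKey <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, ":", variants$ref, ">",
         variants$alt)
}

.is_snv <- function(variants) {
  nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
}

# -- hashed TSV helpers ------------------------------------------------------

.write_hashed_tsv <- function(df, path, preamble = character(0)) {
  body <- as.data.frame(lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- "."
    out
  }), stringsAsFactors = FALSE, check.names = FALSE)
  lines <- c(paste0("## ", preamble),
             paste0("#", paste(names(df), collapse = "\t")),
             if (nrow(body)) do.call(paste, c(unname(body), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

.read_hashed_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  is_pre <- startsWith(lines, "##")
  lines <- lines[!is_pre]; lineno <- lineno[!is_pre]
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("expected a '#'-prefixed header line in ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, 0L) != length(header))
  if (length(bad))
    stop("malformed row at line ", lineno[-1][bad[1]], " of ", path,
         ": expected ", length(header), " fields")
  df <- as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (!length(rows)) df <- as.data.frame(matrix(character(0), 0,
                                                length(header)))
  names(df) <- header
  df[df == "."] <- NA
  attr(df, "source_lines") <- if (length(rows)) lineno[-1] else integer(0)
  df
}

.num <- function(x) suppressWarnings(as.numeric(x))
.int <- function(x) suppressWarnings(as.integer(x))

# -- genome build ------------------------------------------------------------

#' Load a genome build table
#'
#' Reads a '#'-headed TSV with columns `name`, `length`, `centromere_start`,
#' `centromere_end`, `is_sex` and validates all chromosome invariants.
#' Malformed or invariant-violating rows raise an error naming the line.
#'
#' @param path path to the table.
#' @return a [GenomeBuild-class].
#' @seealso [writeGenomeBuild()], [toyGenomeBuild()], [grch37GenomeBuild()]
#' @export
loadGenomeBuild <- function(path) {
  df <- .read_hashed_tsv(path)
  need <- c("name", "length", "centromere_start", "centromere_end", "is_sex")
  if (!all(need %in% names(df)))
    stop("genome build table must have columns: ",
         paste(need, collapse = ", "))
  lines <- attr(df, "source_lines")
  ch <- data.frame(name = df$name,
                   length = .num(df$length),
                   centromere_start = .num(df$centromere_start),
                   centromere_end = .num(df$centromere_end),
                   is_sex = .int(df$is_sex) != 0L)
  bad <- which(is.na(ch$length) | is.na(ch$centromere_start) |
               is.na(ch$centromere_end) | is.na(ch$is_sex))
  if (length(bad))
    stop("malformed genome build row at line ", lines[bad[1]], " of ", path)
  bad <- which(!(ch$centromere_start >= 0 &
                 ch$centromere_start < ch$centromere_end &
                 ch$centromere_end <= ch$length) | ch$length <= 0)
  if (length(bad))
    stop("out-of-range centromere/length at line ", lines[bad[1]], " of ",
         path, " (chromosome ", ch$name[bad[1]], ")")
  GenomeBuild(ch)
}

#' Write a genome build table
#'
#' @param genome a [GenomeBuild-class].
#' @param path output path.
#' @export
writeGenomeBuild <- function(genome, path) {
  ch <- genome@chromosomes
  ch$is_sex <- as.integer(ch$is_sex)
  # keep bp columns integral in the text representation
  ch$length <- format(ch$length, scientific = FALSE, trim = TRUE)
  ch$centromere_start <- format(ch$centromere_start, scientific = FALSE,
                                trim = TRUE)
  ch$centromere_end <- format(ch$centromere_end, scientific = FALSE,
                              trim = TRUE)
  .write_hashed_tsv(ch, path, preamble = c(
    "genome build table; coordinates 0-based half-open, bp"))
}

# -- variant tables ----------------------------------------------------------

.validate_variants <- function(v, where = "variant table") {
  if (nrow(v) == 0) return(v)
  if (any(is.na(v$pos) | v$pos < 1))
    stop(where, ": positions must be >= 1")
  if (any(v$ref == v$alt)) stop(where, ": ref must differ from alt")
  bad <- which(!v$effect %in% .effect_levels)
  if (length(bad))
    stop(where, ": unknown effect category '", v$effect[bad[1]],
         "' (row ", bad[1], ")")
  samp <- variantSamples(v)
  if (!length(samp)) stop(where, ": no sample presence columns")
  pres <- as.matrix(v[, samp, drop = FALSE])
  if (any(rowSums(pres) == 0))
    stop(where, ": every variant must be present in at least one sample")
  snv <- .is_snv(v)
  ctx <- v$context[snv]
  ok <- is.na(ctx) | substr(ctx, 2, 2) == v$ref[snv]
  if (any(!ok))
    stop(where, ": trinucleotide context middle base must equal ref ",
         "(variant ", variantKey(v[snv, ][!ok, ][1, ]), ")")
  v
}

#' Read a somatic variant table
#'
#' Two dialects are supported. `annotated_tsv` is the package's '#'-headed
#' TSV with the fixed annotation columns (`chrom`, `pos`, `ref`, `alt`,
#' `gene`, `effect`, `context`, six in-silico scores, six caller quality
#' metrics, `clonality`) followed by one binary presence column per sample.
#' `vcf_subset` is a VCF v4.2 file with per-sample `GT` and the same
#' annotations carried in INFO (keys `GENE`, `EFFECT`, `CONTEXT`, `SIFT`,
#' `PP2`, `MT`, `GERP`, `CADD`, `PHYLOP`, `CLONALITY`, `QD`, `MQ`, `FS`,
#' `SOR`, `MQRankSum`, `ReadPosRankSum`); presence is `GT != 0/0`.
#' Absent scores are preserved as `NA`, never imputed.
#'
#' @param path input file.
#' @param dialect `"annotated_tsv"` or `"vcf_subset"`.
#' @return a variant data.frame; see [variantSamples()].
#' @export
readVariantTable <- function(path, dialect = c("annotated_tsv",
                                               "vcf_subset")) {
  dialect <- match.arg(dialect)
  if (dialect == "annotated_tsv") {
    df <- .read_hashed_tsv(path)
    miss <- setdiff(.variant_fixed_cols, names(df))
    if (length(miss))
      stop("annotated variant table lacks column(s): ",
           paste(miss, collapse = ", "))
    samp <- setdiff(names(df), .variant_fixed_cols)
    if (!length(samp)) stop("no sample columns in ", path)
    v <- df[, c(.variant_fixed_cols, samp)]
    v$pos <- .int(v$pos)
    for (col in c("sift", "polyphen2", "mutation_taster", "gerp", "cadd",
                  "phylop", "qd", "mq", "fs", "sor", "mq_rank_sum",
                  "read_pos_rank_sum"))
      v[[col]] <- .num(v[[col]])
    for (col in samp) v[[col]] <- .int(v[[col]])
    pres <- as.matrix(v[, samp, drop = FALSE])
    if (any(is.na(pres)) || !all(pres %in% 0:1))
      stop("inconsistent sample presence columns in ", path)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    info_chr <- function(k) {
      out <- vcfR::extract.info(vcf, element = k)
      if (is.null(out)) rep(NA_character_, nrow(fix)) else out
    }
    info_num <- function(k) .num(info_chr(k))
    v <- data.frame(
      chrom = fix$CHROM, pos = .int(fix$POS), ref = fix$REF, alt = fix$ALT,
      gene = info_chr("GENE"), effect = info_chr("EFFECT"),
      context = info_chr("CONTEXT"),
      sift = info_num("SIFT"), polyphen2 = info_num("PP2"),
      mutation_taster = info_num("MT"), gerp = info_num("GERP"),
      cadd = info_num("CADD"), phylop = info_num("PHYLOP"),
      qd = info_num("QD"), mq = info_num("MQ"), fs = info_num("FS"),
      sor = info_num("SOR"), mq_rank_sum = info_num("MQRankSum"),
      read_pos_rank_sum = info_num("ReadPosRankSum"),
      clonality = info_chr("CLONALITY"),
      stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt) || !ncol(gt)) stop("VCF has no per-sample GT: ", path)
    pres <- ifelse(is.na(gt), 0L,
                   ifelse(gt %in% c("0/0", "0|0", ".", "./."), 0L, 1L))
    v <- cbind(v, as.data.frame(pres, stringsAsFactors = FALSE))
  }
  rownames(v) <- NULL
  .validate_variants(v, where = path)
}

#' Write a somatic variant table
#'
#' Inverse of [readVariantTable()]; both dialects round-trip.
#'
#' @param variants a variant table.
#' @param path output file.
#' @param dialect `"annotated_tsv"` or `"vcf_subset"`.
#' @export
writeVariantTable <- function(variants, path,
                              dialect = c("annotated_tsv", "vcf_subset")) {
  dialect <- match.arg(dialect)
  samp <- variantSamples(variants)
  if (dialect == "annotated_tsv") {
    .write_hashed_tsv(variants[, c(.variant_fixed_cols, samp)], path,
                      preamble = c(
      "annotated somatic variant table; pos 1-based; '.' = missing",
      "fixed columns then one binary presence column per sample"))
    return(invisible(path))
  }
  num_or_dot <- function(x) ifelse(is.na(x), NA_character_,
                                   format(x, scientific = FALSE, trim = TRUE))
  info_keys <- c(GENE = "gene", EFFECT = "effect", CONTEXT = "context",
                 SIFT = "sift", PP2 = "polyphen2", MT = "mutation_taster",
                 GERP = "gerp", CADD = "cadd", PHYLOP = "phylop",
                 QD = "qd", MQ = "mq", FS = "fs", SOR = "sor",
                 MQRankSum = "mq_rank_sum",
                 ReadPosRankSum = "read_pos_rank_sum",
                 CLONALITY = "clonality")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    for (k in names(info_keys)) {
      val <- variants[[info_keys[[k]]]][i]
      if (!is.na(val))
        parts <- c(parts, paste0(k, "=", if (is.numeric(val))
          num_or_dot(val) else val))
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  gt <- sapply(samp, function(s)
    ifelse(variants[[s]] == 1, "0/1", "0/0"))
  if (nrow(variants) == 1) gt <- matrix(gt, nrow = 1,
                                        dimnames = list(NULL, samp))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=osteoevo",
    paste0("##INFO=<ID=", names(info_keys),
           ",Number=1,Type=String,Description=\"", info_keys, "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT",
                sep = "\t")
  if (length(samp))
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, if (nrow(variants)) body), path)
  invisible(path)
}

# -- segment tables ----------------------------------------------------------

#' Read an allele-specific copy-number segment table
#'
#' '#'-headed TSV with columns `sample`, `chrom`, `start`, `end`,
#' `total_cn`, `major_cn`, `minor_cn` (coordinates 0-based half-open).
#' Overlapping segments within a sample+chromosome are rejected with an
#' error naming the offending segments.
#'
#' @param path input file.
#' @param genome a [GenomeBuild-class] (for chromosome order and ploidy).
#' @return named list of [SegmentProfile-class], one per sample.
#' @export
readSegmentTable <- function(path, genome) {
  df <- .read_hashed_tsv(path)
  need <- c("sample", "chrom", "start", "end", "total_cn", "major_cn",
            "minor_cn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("segment table lacks column(s): ", paste(miss, collapse = ", "))
  df$start <- .num(df$start); df$end <- .num(df$end)
  df$total_cn <- .int(df$total_cn); df$major_cn <- .int(df$major_cn)
  df$minor_cn <- .int(df$minor_cn)
  out <- list()
  for (s in unique(df$sample)) {
    seg <- df[df$sample == s, need[-1], drop = FALSE]
    prof <- tryCatch(SegmentProfile(s, seg, genome), error = function(e)
      stop("sample ", s, " in ", path, ": ", conditionMessage(e),
           call. = FALSE))
    out[[s]] <- prof
  }
  out
}

#' Write segment profiles to a single SEG-like table
#'
#' @param profiles a list of [SegmentProfile-class] (or a single one).
#' @param path output file.
#' @export
writeSegmentTable <- function(profiles, path) {
  if (is(profiles, "SegmentProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    cbind(sample = sampleId(p), segments(p))))
  rows$start <- format(rows$start, scientific = FALSE, trim = TRUE)
  rows$end <- format(rows$end, scientific = FALSE, trim = TRUE)
  .write_hashed_tsv(rows, path, preamble = c(
    "allele-specific copy-number segments; coordinates 0-based half-open"))
  invisible(path)
}

# -- trees -------------------------------------------------------------------

#' Write a phylogeny to Newick
#'
#' Branch lengths are the number of variants assigned to each edge; clade
#' bootstrap supports (when present) are serialized as internal node labels
#' with three decimals. Write-read round-trips preserve topology.
#'
#' @param x a [TumorPhylogeny-class] or an `ape` `phylo`.
#' @param path output file.
#' @export
writeTreeNewick <- function(x, path) {
  tree <- if (is(x, "TumorPhylogeny")) x@tree else x
  if (!inherits(tree, "phylo")) stop("x must be a TumorPhylogeny or phylo")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labeled")
  if (is(x, "TumorPhylogeny")) {
    ev <- x@edge_variants
    tree$edge.length <- vapply(seq_len(nrow(tree$edge)), function(i) {
      v <- ev[[as.character(i)]]
      if (is.null(v)) 0 else length(v)
    }, numeric(1))
    if (length(x@supports)) {
      lab <- rep("", tree$Nnode)
      ntip <- length(tree$tip.label)
      tumors <- setdiff(tree$tip.label, x@outgroup)
      for (nd in seq_len(tree$Nnode)) {
        tips <- .node_tip_labels(tree, ntip + nd)
        key <- paste(sort(intersect(tips, tumors)), collapse = "+")
        if (key %in% names(x@supports))
          lab[nd] <- sprintf("%.3f", x@supports[[key]])
      }
      tree$node.label <- lab
    }
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path input file.
#' @return an `ape` `phylo`.
#' @export
readTreeNewick <- function(path) ape::read.tree(path)

# tip labels descending from a node (internal helper)
.node_tip_labels <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  desc <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
    new <- setdiff(kids, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  tree$tip.label[desc[desc <= ntip]]
}
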