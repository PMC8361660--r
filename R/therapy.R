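# Driver-alteration matrix assembly and the genomics-guided CDK/PARP
# therapy decision tree.

.severity <- c(none = 0, missense = 1, truncating = 2, fusion = 2,
               biallelic_deletion = 3, amplification = 3)

#' Build a patient-by-gene alteration matrix
#'
#' Merges prioritized variants with classified copy-number events into one
#' categorical cell per (gene, patient): amplification or biallelic
#' deletion from CNA overlap wins over truncating, which wins over
#' missense. Genes absent from the gene table are skipped for CNA overlap
#' with a notice.
#'
#' @param variants_by_patient named list: per patient, a prioritized
#'   variant table (the `gene` and `effect` columns are used).
#' @param events_by_patient named list: per patient, a CNA event
#'   data.frame from [classifyCNAEvents()].
#' @param gene_table data.frame `gene`, `chrom`, `start`, `end` mapping
#'   genes to build coordinates (0-based half-open).
#' @param genes genes to report (default: rows of `gene_table`).
#' @return character matrix genes x patients with cells in
#'   \{none, amplification, biallelic_deletion, truncating, missense,
#'   fusion\}.
#' @export
buildAlterationMatrix <- function(variants_by_patient, events_by_patient,
                                  gene_table, genes = NULL) {
  if (is.null(genes)) genes <- gene_table$gene
  patients <- union(names(variants_by_patient), names(events_by_patient))
  out <- matrix("none", length(genes), length(patients),
                dimnames = list(genes, patients))
  for (pt in patients) {
    v <- variants_by_patient[[pt]]
    if (!is.null(v) && nrow(v))
      for (i in seq_len(nrow(v))) {
        g <- v$gene[i]
        if (!g %in% genes) next
        cand <- if (v$effect[i] == "truncating") "truncating"
        else if (v$effect[i] == "missense") "missense" else NA
        if (!is.na(cand) &&
            .severity[[cand]] > .severity[[out[g, pt]]])
          out[g, pt] <- cand
      }
    ev <- events_by_patient[[pt]]
    if (!is.null(ev) && nrow(ev))
      for (g in genes) {
        gt <- gene_table[gene_table$gene == g, , drop = FALSE]
        if (nrow(gt) == 0) {
          message("gene ", g, " absent from gene table; CNA overlap skipped")
          next
        }
        hit <- ev[ev$chrom == gt$chrom &
                    ev$start < gt$end & ev$end > gt$start &
                    ev$kind %in% c("amplification", "biallelic_deletion"), ,
                  drop = FALSE]
        if (nrow(hit))
          out[g, pt] <- hit$kind[1]
      }
  }
  out
}

#' Genotype flags for the therapy decision tree
#'
#' @param ccnd3_amp,cdk4_amp,cdk6_amp,ccne1_amp,rb1_lof,cdkn2a_del,brca1_path,brca2_path
#'   binary flags (0/1 or logical).
#' @return named logical vector of the eight marker flags.
#' @export
therapyGenotype <- function(ccnd3_amp = 0, cdk4_amp = 0, cdk6_amp = 0,
                            ccne1_amp = 0, rb1_lof = 0, cdkn2a_del = 0,
                            brca1_path = 0, brca2_path = 0) {
  g <- c(ccnd3_amp = ccnd3_amp, cdk4_amp = cdk4_amp, cdk6_amp = cdk6_amp,
         ccne1_amp = ccne1_amp, rb1_lof = rb1_lof,
         cdkn2a_del = cdkn2a_del, brca1_path = brca1_path,
         brca2_path = brca2_path)
  stopifnot(all(g %in% c(0, 1, TRUE, FALSE)))
  g == 1
}

#' CDK/PARP therapy recommendation
#'
#' Rule-traced eligibility, total over the genotype space:
#' * CDK4/6 inhibition: a CCND3, CDK4 or CDK6 amplification is present,
#'   and neither RB1 loss nor CCNE1 amplification (CCNE1 amplification
#'   confers CDK4/6-inhibitor resistance via the CDK2 route; Rb loss
#'   disconnects the target).
#' * CDK2 inhibition: CCNE1 amplified with wild-type Rb.
#' * PARP inhibition: HRD-positive, via the composite scar score or a
#'   pathogenic BRCA1/BRCA2 mutation.
#' * Otherwise standard of care only.
#'
#' @param genotype named logical flags from [therapyGenotype()].
#' @param hrd an [HRDResult-class] for the patient.
#' @param cdkn2a_widens_cdk46 opt-in: also admit CDK4/6 inhibition on
#'   CDKN2A deletion alone (off by default; amplification is the standard
#'   gate).
#' @param patient patient label carried into the result.
#' @return list with `patient`, `options` (character subset of the four
#'   choices) and `rule_trace` (ordered evaluated conditions).
#' @export
recommendTherapy <- function(genotype, hrd, cdkn2a_widens_cdk46 = FALSE,
                             patient = NA_character_) {
  g <- genotype
  need <- c("ccnd3_amp", "cdk4_amp", "cdk6_amp", "ccne1_amp", "rb1_lof",
            "cdkn2a_del", "brca1_path", "brca2_path")
  stopifnot(all(need %in% names(g)))
  brca <- g[["brca1_path"]] || g[["brca2_path"]]
  amp_gate <- g[["ccnd3_amp"]] || g[["cdk4_amp"]] || g[["cdk6_amp"]] ||
    (cdkn2a_widens_cdk46 && g[["cdkn2a_del"]])
  cdk46 <- amp_gate && !g[["rb1_lof"]] && !g[["ccne1_amp"]]
  cdk2 <- g[["ccne1_amp"]] && !g[["rb1_lof"]]
  parp <- isHRDPositive(hrd) || brca
  trace <- c(
    sprintf("CCND3/CDK4/CDK6 amplification present: %s", amp_gate),
    sprintf("RB1 loss absent: %s", !g[["rb1_lof"]]),
    sprintf("CCNE1 amplification absent: %s", !g[["ccne1_amp"]]),
    sprintf("-> CDK4/6 inhibition: %s", cdk46),
    sprintf("CCNE1 amplified with wild-type Rb: %s", cdk2),
    sprintf("-> CDK2 inhibition: %s", cdk2),
    sprintf("HRD composite positive or BRCA1/2 pathogenic: %s",
            parp || brca),
    sprintf("-> PARP inhibition: %s", parp))
  options <- c(if (cdk46) "CDK4/6 inhibition",
               if (cdk2) "CDK2 inhibition",
               if (parp) "PARP inhibition")
  if (!length(options)) options <- "standard-of-care only"
  list(patient = patient, options = options, rule_trace = trace)
}
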