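# Synthetic multi-sample tumor cohort generator with full ground truth.
# The generator emulates a longitudinal osteosarcoma discovery design:
# per patient a primary plus 1-3 recurrences, a clonal phylogeny whose
# edges carry clock-like (aging-signature) mutations at a fixed
# mutations/month rate plus non-clock signature mutations, allele-specific
# copy-number profiles with planted HRD scars and complex events, and
# driver genotypes obeying configured mutual-exclusivity rules.

#' Cohort simulation configuration
#'
#' Defaults describe a discovery-like cohort: 12 patients with 2-4 samples
#' each, a clock rate of 8 mutations/month, tumor origin 9 months before
#' the primary biopsy, metastatic divergence 3 months after origin,
#' recurrences resected 2-8 months after the primary, an aging-dominated
#' signature mixture, and modest per-patient scar targets.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient integer range (min, max) of samples.
#' @param clock_rate clock mutations per month (> 0).
#' @param origin_months months between tumor origin and primary biopsy
#'   (scalar, or range to vary per patient).
#' @param divergence_months months between origin and metastatic
#'   divergence (scalar or range); must not exceed origin.
#' @param recurrence_months range of recurrence collection months after
#'   the primary biopsy.
#' @param signature_mix named proportions over reference signatures; must
#'   include the clock signature and sum to 1.
#' @param clock_signature name of the clock signature column.
#' @param snv_count_range plausible primary-tumor SNV count range (recorded
#'   with the config; counts follow from the clock model).
#' @param scar_target_max named maxima (loh, tai, lst) for the uniform
#'   per-patient scar target draw.
#' @param driver_freq named marginal alteration frequencies per driver.
#' @param driver_rules list of length-2 character vectors: gene pairs that
#'   must never co-occur.
#' @param branch_rate_sd lognormal sd of per-edge clock-rate multipliers
#'   (0 = strict clock; positive values are a rate-heterogeneity stressor).
#' @param p_complex probability a patient carries a private chromothripsis
#'   and staircase event.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return a validated `cohort_config` list.
#' @export
cohortConfig <- function(n_patients = 12, samples_per_patient = c(2, 4),
                         clock_rate = 8, origin_months = 9,
                         divergence_months = 3,
                         recurrence_months = c(2, 8),
                         signature_mix = c(AC1 = 0.6, AC3 = 0.2,
                                           AC6 = 0.1, AC7 = 0.1),
                         clock_signature = "AC1",
                         snv_count_range = c(6, 144),
                         scar_target_max = c(loh = 3, tai = 2, lst = 5),
                         driver_freq = NULL, driver_rules = NULL,
                         branch_rate_sd = 0, p_complex = 0.3, seed = 1) {
  if (is.null(driver_freq))
    driver_freq <- c(TP53 = 0.50, MDM2 = 0.20, CDKN2A = 0.33, RB1 = 0.25,
                     CCND3 = 0.25, CDK4 = 0.16, CDK6 = 0.08, CCNE1 = 0.25,
                     BRCA1 = 0.05, BRCA2 = 0.15, PALB2 = 0.08)
  if (is.null(driver_rules))
    driver_rules <- list(c("CDK4", "RB1"), c("RB1", "CCND3"),
                         c("CCND3", "CCNE1"), c("CDK4", "CCNE1"))
  rng <- function(x) if (length(x) == 1) c(x, x) else x
  cfg <- list(n_patients = n_patients,
              samples_per_patient = samples_per_patient,
              clock_rate = clock_rate,
              origin_months = rng(origin_months),
              divergence_months = rng(divergence_months),
              recurrence_months = rng(recurrence_months),
              signature_mix = signature_mix,
              clock_signature = clock_signature,
              snv_count_range = snv_count_range,
              scar_target_max = scar_target_max,
              driver_freq = driver_freq, driver_rules = driver_rules,
              branch_rate_sd = branch_rate_sd, p_complex = p_complex,
              seed = seed)
  stopifnot(n_patients >= 1, clock_rate > 0,
            samples_per_patient[1] >= 2, samples_per_patient[2] >= samples_per_patient[1],
            all(cfg$origin_months > 0), all(cfg$divergence_months >= 0),
            abs(sum(signature_mix) - 1) < 1e-9,
            clock_signature %in% names(signature_mix),
            all(snv_count_range >= 0), branch_rate_sd >= 0)
  if (max(cfg$divergence_months) > min(cfg$origin_months))
    stop("infeasible config: divergence after the primary biopsy window")
  structure(cfg, class = "cohort_config")
}

#' Draw mutation channel counts from a signature mixture
#'
#' Multinomial draw of `n` mutations over the 96 channels with
#' probabilities `reference %*% mix`.
#'
#' @param n number of mutations (>= 0).
#' @param mix proportions over the reference signatures (must match the
#'   number of reference columns and sum to 1).
#' @param reference 96 x k signature matrix.
#' @param seed optional integer seed.
#' @return named integer vector over [channels96()] summing to `n`.
#' @export
simulateSignatureMutations <- function(n, mix, reference, seed = NULL) {
  stopifnot(n >= 0)
  if (length(mix) != ncol(reference))
    stop("mix length must equal the number of reference signatures")
  stopifnot(abs(sum(mix) - 1) < 1e-9)
  probs <- as.numeric(reference %*% mix)
  .with_seed(seed, function() {
    out <- if (n == 0) integer(96)
    else as.integer(stats::rmultinom(1, n, probs))
    stats::setNames(out, rownames(reference))
  })
}

# ---------------------------------------------------------------------------
# scar planting
# ---------------------------------------------------------------------------

# Unit geometries (all lengths bp). Buffers of 10 Mb cap the flanks of
# every junction a unit creates, so no unit contributes a large-scale
# transition unless it is an LST chain; terminal imbalanced buffers are
# kept at 10 Mb (< 11 Mb) so they never count as telomeric imbalance.
.BUF <- 10e6      # flank buffer
.LOHLEN <- 18e6   # planted LOH segment (> 15 Mb)
.TAILEN <- 12e6   # planted terminal imbalance (> 11 Mb)
.GAP <- 3e6       # minimum diploid filler between units (survives the
                  # < 3 Mb LST pre-filter)

.loh_unit <- function(chrom, at) {
  data.frame(chrom = chrom,
             start = c(at, at + .BUF, at + .BUF + .LOHLEN),
             end = c(at + .BUF, at + .BUF + .LOHLEN,
                     at + 2 * .BUF + .LOHLEN),
             total_cn = c(3L, 2L, 3L), major_cn = c(2L, 2L, 2L),
             minor_cn = c(1L, 0L, 1L))
}
.loh_unit_len <- 2 * .BUF + .LOHLEN   # 38 Mb

.tai_p_unit <- function(chrom) {
  data.frame(chrom = chrom, start = c(0, .TAILEN),
             end = c(.TAILEN, .TAILEN + .BUF),
             total_cn = c(3L, 4L), major_cn = c(2L, 2L),
             minor_cn = c(1L, 2L))
}
.tai_q_unit <- function(chrom, L) {
  data.frame(chrom = chrom, start = c(L - .TAILEN - .BUF, L - .TAILEN),
             end = c(L - .TAILEN, L),
             total_cn = c(4L, 3L), major_cn = c(2L, 2L),
             minor_cn = c(2L, 1L))
}

.lst_chain <- function(chrom, L, k) {
  m <- k + 1L
  bounds <- round(seq(0, L, length.out = m + 1))
  data.frame(chrom = chrom, start = bounds[-(m + 1)], end = bounds[-1],
             total_cn = rep(c(2L, 4L), length.out = m),
             major_cn = rep(c(1L, 2L), length.out = m),
             minor_cn = rep(c(1L, 2L), length.out = m))
}

#' Construct a profile with exact planted HRD scar counts
#'
#' Builds an allele-specific copy-number profile whose [hrdScores()] equal
#' the requested (LOH, TAI, LST) targets exactly. Events are laid out so
#' that each changes only its own score: LOH segments are flanked by 10 Mb
#' buffers (junction flanks never exceed the LST length cutoff), terminal
#' imbalances are 12 Mb with a balanced 10 Mb buffer, and LST chains are
#' alternating balanced blocks on dedicated chromosomes. The layout is
#' deterministic; unachievable targets on the given build raise an error.
#'
#' @param targets numeric length-3 (loh, tai, lst) or named vector.
#' @param genome a [GenomeBuild-class].
#' @param sample_id label of the returned profile.
#' @return a [SegmentProfile-class] tiling every autosome, with attribute
#'   `used_chroms` naming chromosomes carrying planted events.
#' @export
plantScarProfile <- function(targets, genome, sample_id = "planted") {
  tg <- as.integer(if (!is.null(names(targets)))
    targets[c("loh", "tai", "lst")] else targets)
  stopifnot(length(tg) == 3, all(tg >= 0))
  loh_left <- tg[1]; tai_left <- tg[2]; lst_left <- tg[3]
  autos <- genome@chromosomes[!genome@chromosomes$is_sex, , drop = FALSE]
  plans <- stats::setNames(vector("list", nrow(autos)), autos$name)
  used <- character(0)

  # 1. LST chains on dedicated chromosomes, taken from the end of the build
  lst_chrom <- character(0)
  for (i in rev(seq_len(nrow(autos)))) {
    if (lst_left <= 0) break
    L <- autos$length[i]
    cap <- floor(L / 10.5e6) - 1
    if (cap < 1) next
    k <- min(cap, lst_left)
    plans[[autos$name[i]]] <- .lst_chain(autos$name[i], L, k)
    lst_chrom <- c(lst_chrom, autos$name[i])
    lst_left <- lst_left - k
  }
  if (lst_left > 0)
    stop("scar targets unachievable on this build: LST capacity exhausted")

  # 2. terminal imbalances, two per eligible chromosome
  tai_res <- list()   # per chromosome: c(p_used, q_used)
  for (i in seq_len(nrow(autos))) {
    ch <- autos$name[i]
    if (ch %in% lst_chrom) next
    if (tai_left <= 0) break
    L <- autos$length[i]
    p_ok <- autos$centromere_start[i] >= .TAILEN &&
      L >= 2 * (.TAILEN + .BUF)
    q_ok <- autos$centromere_end[i] <= L - .TAILEN &&
      L >= 2 * (.TAILEN + .BUF)
    use <- c(p = FALSE, q = FALSE)
    if (p_ok && tai_left > 0) { use["p"] <- TRUE; tai_left <- tai_left - 1 }
    if (q_ok && tai_left > 0) { use["q"] <- TRUE; tai_left <- tai_left - 1 }
    if (any(use)) tai_res[[ch]] <- use
  }
  if (tai_left > 0)
    stop("scar targets unachievable on this build: ",
         "not enough eligible chromosome ends for TAI")

  # 3. LOH units packed into the remaining interior space
  for (i in seq_len(nrow(autos))) {
    ch <- autos$name[i]
    if (ch %in% lst_chrom) next
    if (loh_left <= 0) break
    L <- autos$length[i]
    use <- tai_res[[ch]]
    a <- if (!is.null(use) && use["p"]) .TAILEN + .BUF else 0
    b <- if (!is.null(use) && use["q"]) L - .TAILEN - .BUF else L
    cap <- floor((b - a + .GAP) / (.loh_unit_len + .GAP))
    if (cap < 1) next
    n <- min(cap, loh_left)
    units <- do.call(rbind, lapply(seq_len(n) - 1, function(j)
      .loh_unit(ch, a + j * (.loh_unit_len + .GAP))))
    plans[[ch]] <- rbind(plans[[ch]], units)
    loh_left <- loh_left - n
  }
  if (loh_left > 0)
    stop("scar targets unachievable on this build: ",
         "not enough interior space for LOH segments")

  # assemble: planted units plus the TAI units, diploid fill elsewhere
  seg <- list()
  for (i in seq_len(nrow(autos))) {
    ch <- autos$name[i]; L <- autos$length[i]
    rows <- plans[[ch]]
    use <- tai_res[[ch]]
    if (!is.null(use)) {
      if (use["p"]) rows <- rbind(rows, .tai_p_unit(ch))
      if (use["q"]) rows <- rbind(rows, .tai_q_unit(ch, L))
    }
    if (is.null(rows)) {
      seg[[ch]] <- data.frame(chrom = ch, start = 0, end = L,
                              total_cn = 2L, major_cn = 1L, minor_cn = 1L)
      next
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    fill <- list()
    cur <- 0
    for (r in seq_len(nrow(rows))) {
      if (rows$start[r] > cur)
        fill[[length(fill) + 1]] <- data.frame(
          chrom = ch, start = cur, end = rows$start[r], total_cn = 2L,
          major_cn = 1L, minor_cn = 1L)
      cur <- rows$end[r]
    }
    if (cur < L)
      fill[[length(fill) + 1]] <- data.frame(
        chrom = ch, start = cur, end = L, total_cn = 2L, major_cn = 1L,
        minor_cn = 1L)
    out <- rbind(rows, do.call(rbind, fill))
    seg[[ch]] <- out[order(out$start), , drop = FALSE]
    used <- c(used, ch)
  }
  # sex chromosomes: carried as diploid so I/O round-trips keep them
  sex <- genome@chromosomes[genome@chromosomes$is_sex, , drop = FALSE]
  if (nrow(sex))
    for (i in seq_len(nrow(sex)))
      seg[[sex$name[i]]] <- data.frame(
        chrom = sex$name[i], start = 0, end = sex$length[i],
        total_cn = 2L, major_cn = 1L, minor_cn = 1L)
  prof <- SegmentProfile(sample_id, do.call(rbind, seg), genome)
  got <- hrdScores(prof, genome)
  if (!identical(c(got$loh, got$tai, got$lst), tg))
    stop("internal error: planted profile scores (", got$loh, ",",
         got$tai, ",", got$lst, ") != targets (",
         paste(tg, collapse = ","), ")")
  attr(prof, "used_chroms") <- unique(used)
  prof
}

# overlay a private complex event (oscillation or staircase) on a free
# chromosome of a planted profile; geometry chosen so scar scores are
# untouched (all added segments < 3 Mb or with <= 10 Mb junction flanks).
.overlay_complex <- function(prof, genome, chrom, kind) {
  seg <- segments(prof)
  L <- chromLengths(genome)[[chrom]]
  keep <- seg[seg$chrom != chrom, , drop = FALSE]
  if (kind == "chromothripsis") {
    n <- 13                     # 12 switches between two states
    at <- 5e6
    w <- 2e6
    ev <- data.frame(chrom = chrom, start = at + (seq_len(n) - 1) * w,
                     end = at + seq_len(n) * w,
                     total_cn = rep(c(3L, 2L), length.out = n),
                     major_cn = rep(c(2L, 1L), length.out = n),
                     minor_cn = 1L)
  } else {
    ev <- data.frame(chrom = chrom,
                     start = c(L - 8e6, L - 5.5e6, L - 2.8e6),
                     end = c(L - 5.5e6, L - 2.8e6, L),
                     total_cn = c(3L, 4L, 5L), major_cn = c(2L, 2L, 3L),
                     minor_cn = c(1L, 2L, 2L))
  }
  lo <- min(ev$start); hi <- max(ev$end)
  rest <- list()
  if (lo > 0) rest[[1]] <- data.frame(chrom = chrom, start = 0, end = lo,
                                      total_cn = 2L, major_cn = 1L,
                                      minor_cn = 1L)
  if (hi < L) rest[[2]] <- data.frame(chrom = chrom, start = hi, end = L,
                                      total_cn = 2L, major_cn = 1L,
                                      minor_cn = 1L)
  SegmentProfile(sampleId(prof),
                 rbind(keep, ev, do.call(rbind, rest)), genome)
}

# splice a private focal event (5 Mb gain or single-copy loss) into the
# middle of a diploid run, keeping > 10 Mb diploid margins on both sides so
# scar counting is unaffected: leftover pieces keep qualifying as long LST
# flanks where they already did, and the 5 Mb event can never be one.
.splice_private <- function(prof, genome, kind = c("gain", "loss")) {
  kind <- match.arg(kind)
  width <- 5e6; margin <- 10.5e6
  seg <- segments(prof)
  cand <- which(seg$chrom %in% autosomeNames(genome) &
                  seg$total_cn == 2L & seg$major_cn == 1L &
                  (seg$end - seg$start) >= width + 2 * margin + 1e6)
  if (!length(cand)) return(prof)
  i <- .sample1(cand)
  lo <- seg$start[i] + margin
  hi <- seg$end[i] - margin - width
  at <- round(stats::runif(1, lo, hi) / 1e5) * 1e5
  st <- if (kind == "gain") c(3L, 2L, 1L) else c(1L, 1L, 0L)
  left <- seg[i, ]; left$end <- at
  mid <- seg[i, ]; mid$start <- at; mid$end <- at + width
  mid$total_cn <- st[1]; mid$major_cn <- st[2]; mid$minor_cn <- st[3]
  right <- seg[i, ]; right$start <- at + width
  SegmentProfile(sampleId(prof),
                 rbind(seg[-i, ], left, mid, right), genome)
}

# ---------------------------------------------------------------------------
# cohort simulation
# ---------------------------------------------------------------------------

.draw_driver_genotype <- function(freq, rules) {
  cat_for <- function(g, hit) {
    if (!hit) return("none")
    switch(g,
           TP53 = sample(c("truncating", "missense"), 1, prob = c(.6, .4)),
           RB1 = sample(c("biallelic_deletion", "truncating"), 1),
           CDKN2A = "biallelic_deletion",
           PALB2 = "biallelic_deletion",
           BRCA1 = "truncating", BRCA2 = "truncating",
           "amplification")
  }
  for (try in 1:1000) {
    hits <- stats::runif(length(freq)) < freq
    names(hits) <- names(freq)
    ok <- all(vapply(rules, function(r) !(hits[r[1]] && hits[r[2]]),
                     logical(1)))
    if (ok)
      return(vapply(names(freq), function(g) cat_for(g, hits[[g]]),
                    character(1)))
  }
  stop("could not satisfy driver exclusivity rules in 1000 draws")
}

.sample1 <- function(v) if (length(v) == 1) v else sample(v, 1)

.decode_channel <- function(lab) {
  # "A[C>T]G" -> ref, alt, context
  up <- substr(lab, 1, 1); ref <- substr(lab, 3, 3)
  alt <- substr(lab, 5, 5); down <- substr(lab, 7, 7)
  list(ref = ref, alt = alt, context = paste0(up, ref, down))
}

#' Simulate a longitudinal tumor cohort with ground truth
#'
#' Generates, per patient, a clonal phylogeny (primary plus recurrences
#' diverging from a common ancestor), clock-like mutations accumulating at
#' `clock_rate` per month on every edge, non-clock signature mutations
#' spread uniformly over edges with positive duration, allele-specific
#' copy-number profiles with exactly planted scar targets (shared across
#' the patient's samples, emulating truncal rearrangement) plus private
#' focal and complex events, collection dates, and a driver alteration
#' matrix obeying the configured mutual-exclusivity rules. Output is
#' deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @param genome a [GenomeBuild-class] (default: [toyGenomeBuild()]).
#' @param reference signature matrix (default: the shipped table),
#'   restricted to the mixture's signatures.
#' @return list with `variants` (per-patient variant tables), `profiles`
#'   (per-patient named lists of [SegmentProfile-class]), `dates`
#'   (data.frame patient/sample/month), `alterations` (driver matrix),
#'   `ground_truth`, `genome`, `config`.
#' @export
simulateCohort <- function(config = cohortConfig(),
                           genome = toyGenomeBuild(),
                           reference = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(reference)) reference <- referenceSignatures()
  mix <- config$signature_mix
  miss <- setdiff(names(mix), colnames(reference))
  if (length(miss))
    stop("signature(s) absent from reference: ", paste(miss, collapse = ", "))
  reference <- reference[, names(mix), drop = FALSE]
  clock_sig <- config$clock_signature
  w1 <- mix[[clock_sig]]
  .with_seed(config$seed, function() {
    patients <- paste0("P", seq_len(config$n_patients))
    variants <- list(); profiles <- list(); gt <- list()
    dates <- list()
    for (pt in patients) {
      s <- .sample1(seq(config$samples_per_patient[1],
                        config$samples_per_patient[2]))
      t_origin <- stats::runif(1, config$origin_months[1],
                               config$origin_months[2])
      t_div <- stats::runif(1, config$divergence_months[1],
                            config$divergence_months[2])
      samples <- c(paste0(pt, "_P"),
                   if (s > 1) paste0(pt, "_REC", seq_len(s - 1)))
      months <- c(0, if (s > 1)
        sort(stats::runif(s - 1, config$recurrence_months[1],
                          config$recurrence_months[2])))
      collect <- t_origin + months          # time since origin
      # lineage splitting: first split at t_div, later splits uniform
      extra <- if (s > 2)
        sort(stats::runif(s - 2, t_div, t_origin)) else numeric(0)
      split_times <- c(t_div, extra)
      # edges: id, parent, birth (time lineage started), desc (filled later)
      edges <- data.frame(id = 1L, birth = 0, stop = NA_real_,
                          leaf = NA_character_)
      children <- list()                    # id -> child ids
      active <- 1L; next_id <- 2L
      for (ts in split_times) {
        pick <- if (length(active) == 1) active else sample(active, 1)
        edges$stop[pick] <- ts
        kids <- c(next_id, next_id + 1L)
        for (k in kids)
          edges <- rbind(edges, data.frame(id = k, birth = ts,
                                           stop = NA_real_,
                                           leaf = NA_character_))
        children[[pick]] <- kids
        active <- c(setdiff(active, pick), kids)
        next_id <- next_id + 2L
      }
      # assign samples to active lineages (primary first, random order)
      perm <- sample(seq_along(active))
      for (j in seq_along(active)) {
        lin <- active[j]
        edges$leaf[edges$id == lin] <- samples[perm[j]]
        edges$stop[edges$id == lin] <- collect[perm[j]]
      }
      edges$duration <- edges$stop - edges$birth
      # descendant sample sets
      desc <- function(id) {
        kid <- if (id <= length(children)) children[[id]]
        if (is.null(kid)) edges$leaf[edges$id == id]
        else unlist(lapply(kid, desc))
      }
      edges$desc <- vapply(edges$id, function(i)
        paste(sort(desc(i)), collapse = "+"), character(1))
      all_key <- paste(sort(samples), collapse = "+")
      edges$class <- ifelse(edges$desc == all_key, "trunk",
                            ifelse(!is.na(edges$leaf), "leaf", "branch"))
      # mutations per edge
      rate_mult <- if (config$branch_rate_sd > 0)
        exp(stats::rnorm(nrow(edges), -config$branch_rate_sd^2 / 2,
                         config$branch_rate_sd)) else rep(1, nrow(edges))
      clock_n <- stats::rpois(nrow(edges),
                              config$clock_rate * edges$duration * rate_mult)
      total_clock <- sum(clock_n)
      nonclock_total <- if (w1 < 1)
        round(total_clock * (1 - w1) / w1) else 0
      live <- edges$duration > 0
      if (!any(live)) live <- edges$class == "trunk"
      nc_alloc <- if (nonclock_total > 0)
        as.integer(stats::rmultinom(1, nonclock_total,
                                    as.numeric(live) / sum(live)))
      else integer(nrow(edges))
      nc_mix <- mix[setdiff(names(mix), clock_sig)]
      nc_mix <- nc_mix / sum(nc_mix)
      rows <- list()
      for (e in seq_len(nrow(edges))) {
        n_e <- clock_n[e] + nc_alloc[e]
        if (n_e == 0) next
        sigs <- c(rep(clock_sig, clock_n[e]),
                  if (nc_alloc[e] > 0)
                    sample(names(nc_mix), nc_alloc[e], replace = TRUE,
                           prob = nc_mix))
        chan_idx <- vapply(sigs, function(sg)
          sample.int(96, 1, prob = reference[, sg]), integer(1))
        rows[[e]] <- data.frame(edge = edges$id[e], signature = sigs,
                                channel = channels96()[chan_idx])
      }
      mut <- do.call(rbind, rows)
      if (is.null(mut)) mut <- data.frame(edge = integer(0),
                                          signature = character(0),
                                          channel = character(0))
      nmut <- nrow(mut)
      # genomic coordinates: unique positions
      auto <- autosomeNames(genome)
      lens <- chromLengths(genome)[auto]
      repeat {
        chrom <- sample(auto, nmut, replace = TRUE,
                        prob = lens / sum(lens))
        pos <- vapply(chrom, function(ch)
          sample.int(lens[[ch]] - 2L, 1) + 1L, integer(1))
        if (!anyDuplicated(paste(chrom, pos))) break
      }
      dec <- .decode_channel(mut$channel)
      effect <- sample(c("synonymous", "missense", "truncating", "splice"),
                       nmut, replace = TRUE,
                       prob = c(1 / 3.5, 0.6, 0.10, 2.5 / 3.5 - 0.7))
      pathogenic <- effect == "missense" & stats::runif(nmut) < 0.5
      v <- data.frame(
        chrom = chrom, pos = pos, ref = dec$ref, alt = dec$alt,
        gene = paste0("GENE", sample(1:500, nmut, replace = TRUE)),
        effect = effect, context = dec$context,
        sift = ifelse(pathogenic, stats::runif(nmut, 0, 0.049),
                      stats::runif(nmut, 0.06, 1)),
        polyphen2 = ifelse(pathogenic, stats::runif(nmut, 0.71, 1),
                           stats::runif(nmut, 0, 0.69)),
        mutation_taster = ifelse(pathogenic, stats::runif(nmut, 0.71, 1),
                                 stats::runif(nmut, 0, 0.69)),
        gerp = ifelse(pathogenic, stats::runif(nmut, 0.1, 6),
                      stats::runif(nmut, -6, -0.1)),
        cadd = ifelse(pathogenic, stats::runif(nmut, 10.1, 40),
                      stats::runif(nmut, 0, 9.9)),
        phylop = ifelse(pathogenic, stats::runif(nmut, 0.1, 3),
                        stats::runif(nmut, -3, -0.1)),
        qd = stats::runif(nmut, 11, 34), mq = stats::runif(nmut, 41, 60),
        fs = stats::runif(nmut, 0, 29), sor = stats::runif(nmut, 0.2, 2.9),
        mq_rank_sum = stats::runif(nmut, -5, 5),
        read_pos_rank_sum = stats::runif(nmut, -5, 5),
        clonality = "clonal", stringsAsFactors = FALSE)
      for (sm in samples) {
        carried <- vapply(mut$edge, function(eid) {
          d <- strsplit(edges$desc[edges$id == eid], "+", fixed = TRUE)[[1]]
          sm %in% d
        }, logical(1))
        v[[sm]] <- as.integer(carried)
      }
      if (nmut > 0) v <- .validate_variants(v, where = paste("patient", pt))
      # copy-number profiles: shared (truncal) scars + private events
      tgt <- c(loh = .sample1(0:config$scar_target_max[["loh"]]),
               tai = .sample1(0:config$scar_target_max[["tai"]]),
               lst = .sample1(0:config$scar_target_max[["lst"]]))
      base <- plantScarProfile(tgt, genome, sample_id = "base")
      free <- setdiff(autosomeNames(genome), attr(base, "used_chroms"))
      has_complex <- stats::runif(1) < config$p_complex &&
        length(free) >= 2
      prof_list <- list()
      complex_rec <- NULL
      for (sm in samples) {
        p <- SegmentProfile(sm, segments(base), genome)
        if (has_complex && sm == samples[1]) {
          p <- .overlay_complex(p, genome, free[1], "chromothripsis")
          p <- .overlay_complex(p, genome, free[2], "staircase")
          complex_rec <- data.frame(sample = sm,
                                    chrom = free[1:2],
                                    kind = c("chromothripsis",
                                             "staircase_telomeric"))
        }
        # private focal gains/losses, invisible to the scar scores
        for (j in seq_len(.sample1(1:3)))
          p <- .splice_private(p, genome,
                               kind = sample(c("gain", "loss"), 1))
        sc <- hrdScores(p, genome)
        stopifnot(identical(c(sc$loh, sc$tai, sc$lst),
                            as.integer(tgt)))
        prof_list[[sm]] <- p
      }
      # ground-truth exposures per sample
      expos <- sapply(samples, function(sm) {
        pres <- v[[sm]] == 1
        table(factor(mut$signature[pres], levels = names(mix)))
      })
      variant_id <- variantKey(v)
      variants[[pt]] <- v
      profiles[[pt]] <- prof_list
      dates[[pt]] <- data.frame(patient = pt, sample = samples,
                                month = months)
      gt[[pt]] <- list(
        edges = edges[, c("id", "birth", "stop", "duration", "leaf",
                          "desc", "class")],
        assignment = data.frame(variant = variant_id, edge = mut$edge,
                                class = edges$class[match(mut$edge,
                                                          edges$id)],
                                signature = mut$signature,
                                channel = mut$channel),
        exposures = expos,
        clock = list(rate = config$clock_rate, t_origin = t_origin,
                     t_div = t_div),
        scar_targets = tgt,
        complex_events = complex_rec,
        samples = samples)
    }
    # driver genotypes with exclusivity
    alt <- vapply(patients, function(pt)
      .draw_driver_genotype(config$driver_freq, config$driver_rules),
      character(length(config$driver_freq)))
    rownames(alt) <- names(config$driver_freq)
    for (pt in patients) gt[[pt]]$driver_genotype <- alt[, pt]
    list(variants = variants, profiles = profiles,
         dates = do.call(rbind, c(dates, list(make.row.names = FALSE))),
         alterations = alt, ground_truth = gt, genome = genome,
         config = config)
  })
}
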