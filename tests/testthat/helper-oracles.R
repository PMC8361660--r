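# Test helpers: fixture builders and independent brute-force oracles.
# The oracles deliberately share no code with the package internals: plain
# loops over the raw definitions.

# -- fixture builders --------------------------------------------------------

# minimal variant table; presence defaults to a single sample "S1"
make_variants <- function(n = 1, ..., samples = list(S1 = 1)) {
  args <- list(...)
  base <- list(chrom = "chr1", pos = seq_len(n) * 100, ref = "C",
               alt = "T", gene = "GENE1", effect = "missense",
               context = NA_character_, sift = NA_real_,
               polyphen2 = NA_real_, mutation_taster = NA_real_,
               gerp = NA_real_, cadd = NA_real_, phylop = NA_real_,
               qd = 20, mq = 50, fs = 5, sor = 1, mq_rank_sum = 0,
               read_pos_rank_sum = 0, clonality = "clonal")
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  v <- as.data.frame(lapply(base, rep, length.out = n),
                     stringsAsFactors = FALSE)
  for (s in names(samples)) v[[s]] <- rep(samples[[s]], length.out = n)
  v
}

seg_row <- function(chrom, start, end, total, major, minor) {
  data.frame(chrom = chrom, start = start, end = end, total_cn = total,
             major_cn = major, minor_cn = minor)
}

# random valid profile tiling the toy genome
random_profile <- function(genome, max_segments = 25, id = "rnd") {
  autos <- autosomeNames(genome)
  lens <- chromLengths(genome)
  n_chrom <- sample(1:3, 1)
  chroms <- sample(autos, n_chrom)
  rows <- list()
  nseg_left <- max_segments
  for (ch in chroms) {
    k <- sample(1:min(8, nseg_left), 1)
    nseg_left <- nseg_left - k
    bp <- sort(sample(seq(1e6, lens[[ch]] - 1e6, by = 5e5), k - 1))
    bounds <- c(0, bp, lens[[ch]])
    major <- sample(0:3, k, replace = TRUE)
    minor <- vapply(major, function(m) sample(0:m, 1), integer(1))
    rows[[ch]] <- seg_row(ch, bounds[-(k + 1)], bounds[-1],
                          major + minor, major, minor)
  }
  # untouched autosomes stay diploid
  for (ch in setdiff(autos, chroms))
    rows[[ch]] <- seg_row(ch, 0, lens[[ch]], 2L, 1L, 1L)
  SegmentProfile(id, do.call(rbind, rows), genome)
}

# -- brute-force HRD oracle --------------------------------------------------

# direct-definition scan, naive loops, no shared helpers
brute_hrd <- function(profile, genome) {
  seg <- segments(profile)
  cent <- centromeres(genome)
  lens <- chromLengths(genome)
  seg <- seg[seg$chrom %in% autosomeNames(genome), , drop = FALSE]
  seg <- seg[order(match(seg$chrom, chromNames(genome)), seg$start), ]
  merge_naive <- function(s) {
    repeat {
      done <- TRUE
      i <- 1
      while (i < nrow(s)) {
        if (s$chrom[i] == s$chrom[i + 1] &&
            s$total_cn[i] == s$total_cn[i + 1] &&
            s$major_cn[i] == s$major_cn[i + 1] &&
            s$minor_cn[i] == s$minor_cn[i + 1]) {
          s$end[i] <- s$end[i + 1]
          s <- s[-(i + 1), , drop = FALSE]
          done <- FALSE
        } else i <- i + 1
      }
      if (done) return(s)
    }
  }
  m <- merge_naive(seg)
  loh <- 0; tai <- 0
  for (i in seq_len(nrow(m))) {
    len <- m$end[i] - m$start[i]
    L <- lens[[m$chrom[i]]]
    whole <- m$start[i] == 0 && m$end[i] == L
    if (m$minor_cn[i] == 0 && m$total_cn[i] >= 1 && len > 15e6 && !whole)
      loh <- loh + 1
    cs <- cent$centromere_start[cent$name == m$chrom[i]]
    ce <- cent$centromere_end[cent$name == m$chrom[i]]
    p_arm <- m$start[i] == 0 && m$end[i] <= ce
    q_arm <- m$end[i] == L && m$start[i] >= cs
    if (m$major_cn[i] != m$minor_cn[i] && len > 11e6 && !whole &&
        (p_arm || q_arm))
      tai <- tai + 1
  }
  keep <- m[(m$end - m$start) >= 3e6, , drop = FALSE]
  keep <- merge_naive(keep)
  lst <- 0
  if (nrow(keep) > 1)
    for (i in seq_len(nrow(keep) - 1)) {
      if (keep$chrom[i] != keep$chrom[i + 1]) next
      l1 <- keep$end[i] - keep$start[i]
      l2 <- keep$end[i + 1] - keep$start[i + 1]
      changed <- keep$major_cn[i] != keep$major_cn[i + 1] ||
        keep$minor_cn[i] != keep$minor_cn[i + 1]
      if (l1 > 10e6 && l2 > 10e6 && changed) lst <- lst + 1
    }
  c(loh = loh, tai = tai, lst = lst)
}

# -- brute-force parsimony oracle -------------------------------------------

# minimum changes of one binary column by enumerating all internal-node
# state assignments
brute_column_changes <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_states <- x[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    states <- c(tip_states, as.integer(intToBits(mask))[1:nnode])
    ch <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

brute_parsimony <- function(tree, m) {
  sum(vapply(seq_len(ncol(m)), function(j)
    brute_column_changes(tree, m[, j]), numeric(1)))
}

# random binary presence matrix with an all-zero outgroup row
random_matrix <- function(n_tumors, n_variants, outgroup = "NORMAL") {
  repeat {
    m <- matrix(rbinom(n_tumors * n_variants, 1, 0.5), n_tumors,
                dimnames = list(paste0("T", seq_len(n_tumors)),
                                paste0("v", seq_len(n_variants))))
    if (all(colSums(m) > 0)) break
  }
  m <- rbind(m, matrix(0L, 1, ncol(m), dimnames = list(outgroup, NULL)))
  storage.mode(m) <- "integer"
  attr(m, "outgroup") <- outgroup
  m
}

# presence matrix of a perfect phylogeny: chain topology
# ((T1,T2),T3,...) with k private variants per edge
perfect_matrix <- function(n_tumors = 3, per_edge = 5,
                           outgroup = "NORMAL") {
  cols <- list()
  # trunk variants: all tumors
  cols$trunk <- matrix(1L, n_tumors, per_edge)
  # nested clades (T1..Tk) for k = 2..n-1, plus leaf-private columns
  for (k in seq_len(n_tumors)) {
    v <- integer(n_tumors); v[seq_len(k)] <- 1L
    if (k < n_tumors)
      cols[[paste0("c", k)]] <- matrix(v, n_tumors, per_edge)
  }
  for (k in seq_len(n_tumors)) {
    v <- integer(n_tumors); v[k] <- 1L
    cols[[paste0("leaf", k)]] <- matrix(v, n_tumors, per_edge)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("T", seq_len(n_tumors))
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  m <- rbind(m, matrix(0L, 1, ncol(m), dimnames = list(outgroup, NULL)))
  storage.mode(m) <- "integer"
  attr(m, "outgroup") <- outgroup
  m
}
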