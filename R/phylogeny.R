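# Maximum-parsimony sample phylogenies from binary variant presence
# matrices, rooted at the matched normal. Fitch scoring, exhaustive and
# NNI-heuristic search, homoplasy index, column-bootstrap clade supports,
# trunk/branch/leaf variant assignment and ns/s ratios are implemented
# here; phangorn is used only to enumerate unrooted topologies.

# run code under a temporary RNG state
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Build a binary sample-by-variant presence matrix
#'
#' Rows are tumor samples plus one appended all-zero outgroup row (the
#' matched normal); columns are variant identifiers; cells encode presence.
#'
#' @param variants a variant table.
#' @param samples sample labels to include (default: all sample columns).
#' @param outgroup_label label for the appended normal row.
#' @return binary integer matrix with attribute `outgroup`.
#' @export
buildPresenceMatrix <- function(variants, samples = NULL,
                                outgroup_label = "NORMAL") {
  if (is.null(samples)) samples <- variantSamples(variants)
  if (anyDuplicated(samples)) stop("duplicate sample labels")
  if (outgroup_label %in% samples)
    stop("outgroup label collides with a sample label")
  m <- t(as.matrix(variants[, samples, drop = FALSE]))
  colnames(m) <- make.unique(variantKey(variants))
  if (any(colSums(m) == 0))
    stop("variant absent from every included sample: ",
         colnames(m)[colSums(m) == 0][1])
  m <- rbind(m, matrix(0L, 1, ncol(m),
                       dimnames = list(outgroup_label, NULL)))
  storage.mode(m) <- "integer"
  attr(m, "outgroup") <- outgroup_label
  m
}

# -- Fitch machinery ---------------------------------------------------------

# Binary-state Fitch pass over all columns of X01 (leaves x variants,
# rownames = tip labels). Returns total changes and per-column changes.
.fitch <- function(tree, X01) {
  if (!setequal(rownames(X01), tree$tip.label))
    stop("tree leaves must match matrix rows")
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nn <- ntip + po$Nnode
  ncols <- ncol(X01)
  S <- matrix(0L, nn, ncols)
  S[seq_len(ntip), ] <- X01[po$tip.label, , drop = FALSE] + 1L
  seen <- logical(nn)
  changes <- integer(ncols)
  E <- po$edge
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    if (!seen[p]) { S[p, ] <- S[ch, ]; seen[p] <- TRUE }
    else {
      I <- bitwAnd(S[p, ], S[ch, ])
      z <- I == 0L
      changes <- changes + z
      S[p, ] <- I + bitwOr(S[p, ], S[ch, ]) * z
    }
  }
  list(total = sum(changes), per_column = changes)
}

#' Parsimony score of a tree on a presence matrix
#'
#' Sum over variant columns of the minimum number of binary state changes
#' (two-state Fitch pass). Independent of where the tree is rooted.
#'
#' @param tree an `ape` `phylo` whose tips are the matrix rows.
#' @param matrix binary presence matrix (rows = samples incl. outgroup).
#' @return integer total number of state changes.
#' @export
parsimonyScore <- function(tree, matrix) {
  as.integer(.fitch(tree, matrix)$total)
}

# One minimal Fitch labeling for a single column x (named by tip label);
# returns indices of change edges in tree$edge (tree assumed cladewise).
.fitch_change_edges <- function(tree, x) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  S <- integer(nn)
  S[seq_len(ntip)] <- x[tree$tip.label] + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  seen <- logical(nn)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    if (!seen[p]) { S[p] <- S[ch]; seen[p] <- TRUE }
    else {
      I <- bitwAnd(S[p], S[ch])
      S[p] <- if (I == 0L) bitwOr(S[p], S[ch]) else I
    }
  }
  root <- ntip + 1L
  state <- integer(nn)
  state[root] <- if (bitwAnd(S[root], 1L) > 0L) 0L else 1L
  changed <- integer(0)
  E <- tree$edge
  for (k in seq_len(nrow(E))) {        # cladewise: parents before children
    p <- E[k, 1]; ch <- E[k, 2]
    bit <- state[p] + 1L
    if (bitwAnd(S[ch], bit) > 0L) state[ch] <- state[p]
    else {
      state[ch] <- if (S[ch] == 1L) 0L else 1L
      changed <- c(changed, k)
    }
  }
  changed
}

# -- topology enumeration and search ----------------------------------------

.root_at <- function(tree, outgroup) {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::reorder.phylo(tr, "cladewise")
}

# sorted clade-key string set of a rooted tree (tumor bipartitions)
.clade_keys <- function(tree, outgroup) {
  tumors <- setdiff(tree$tip.label, outgroup)
  ntip <- length(tree$tip.label)
  keys <- character(0)
  for (nd in seq_len(tree$Nnode) + ntip) {
    tips <- intersect(.node_tip_labels(tree, nd), tumors)
    if (length(tips)) keys <- c(keys, paste(sort(tips), collapse = "+"))
  }
  keys <- c(keys, tumors)               # singleton clades
  sort(unique(keys))
}

.topology_hash <- function(tree, outgroup) {
  paste(.clade_keys(tree, outgroup), collapse = ";")
}

.all_topologies <- function(labels, outgroup) {
  n <- length(labels)
  if (n == 2)
    return(list(ape::read.tree(text = paste0("(", labels[1], ",",
                                             labels[2], ");"))))
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  lapply(trees, identity)
}

#' Search tree space for maximum-parsimony trees
#'
#' `exhaustive` scores every unrooted topology (feasible for at most ten
#' samples) and returns *all* minimum-length topologies; `heuristic` runs
#' seeded random-start nearest-neighbor-interchange hill climbing and
#' returns the `n_kept` shortest distinct topologies found. All returned
#' trees are rooted at the outgroup.
#'
#' @param matrix binary presence matrix (from [buildPresenceMatrix()] or
#'   hand-built, with an all-zero outgroup row).
#' @param mode `"exhaustive"` or `"heuristic"`.
#' @param n_kept number of trees kept in heuristic mode.
#' @param seed integer seed for heuristic restarts (ignored by exhaustive).
#' @param outgroup outgroup row label (default: the matrix attribute).
#' @param restarts number of random restarts in heuristic mode.
#' @return list with `trees` (list of rooted `phylo`), `score` (best
#'   parsimony length) and `mode`.
#' @export
searchTrees <- function(matrix, mode = c("exhaustive", "heuristic"),
                        n_kept = 100, seed = NULL, outgroup = NULL,
                        restarts = 10) {
  mode <- match.arg(mode)
  if (is.null(outgroup)) outgroup <- attr(matrix, "outgroup")
  if (is.null(outgroup) || !outgroup %in% rownames(matrix))
    stop("outgroup row not found in matrix")
  labels <- rownames(matrix)
  if (mode == "exhaustive") {
    if (nrow(matrix) > 10)
      stop("exhaustive search supports at most 10 samples; use mode = 'heuristic'")
    cand <- .all_topologies(labels, outgroup)
    scores <- vapply(cand, function(tr) .fitch(tr, matrix)$total, numeric(1))
    best <- min(scores)
    trees <- lapply(cand[scores == best], .root_at, outgroup = outgroup)
    return(list(trees = trees, score = as.integer(best), mode = mode))
  }
  .with_seed(seed, function() {
    found <- list(); found_scores <- numeric(0); seen <- character(0)
    register <- function(tr, sc) {
      rt <- .root_at(tr, outgroup)
      h <- .topology_hash(rt, outgroup)
      if (!h %in% seen) {
        seen <<- c(seen, h)
        found[[length(found) + 1L]] <<- rt
        found_scores <<- c(found_scores, sc)
      }
    }
    for (r in seq_len(restarts)) {
      tr <- if (length(labels) <= 3) .all_topologies(labels, outgroup)[[1]]
      else ape::rtopology(length(labels), rooted = FALSE,
                          tip.label = sample(labels))
      sc <- .fitch(tr, matrix)$total
      register(tr, sc)
      repeat {
        if (length(labels) < 4) break
        nbrs <- phangorn::nni(tr)
        nsc <- vapply(nbrs, function(x) .fitch(x, matrix)$total, numeric(1))
        for (i in seq_along(nbrs)) register(nbrs[[i]], nsc[i])
        if (min(nsc) < sc) {
          i <- which.min(nsc); tr <- nbrs[[i]]; sc <- nsc[i]
        } else break
      }
    }
    o <- order(found_scores)
    o <- o[seq_len(min(n_kept, length(o)))]
    list(trees = found[o], score = as.integer(min(found_scores)),
         mode = mode)
  })
}

#' Homoplasy index of a tree on a matrix
#'
#' `HI = 1 - (minimum conceivable changes) / (realized changes)`, with the
#' minimum for binary characters equal to the number of variant columns
#' (the PAUP convention `HI = 1 - CI`). Zero iff the matrix fits the tree
#' with no convergent changes.
#'
#' @param tree rooted or unrooted `phylo` over the matrix rows.
#' @param matrix binary presence matrix.
#' @return numeric in \[0, 1).
#' @export
homoplasyIndex <- function(tree, matrix) {
  if (is.null(dim(matrix)) || ncol(matrix) == 0)
    stop("empty presence matrix")
  1 - ncol(matrix) / .fitch(tree, matrix)$total
}

#' Column-bootstrap clade supports
#'
#' Resamples variant columns with replacement, re-runs the tree search, and
#' reports for each observed tumor clade the fraction of replicates whose
#' shortest trees (strict: all co-optimal trees of the replicate) contain
#' it. Clade identity is defined on tumor-leaf bipartitions; the outgroup
#' is excluded.
#'
#' @param matrix binary presence matrix.
#' @param reps number of bootstrap replicates.
#' @param seed integer seed (resampling is deterministic given it).
#' @param mode search mode passed to [searchTrees()]; `"auto"` picks
#'   exhaustive for at most 8 rows.
#' @param outgroup outgroup label (default: matrix attribute).
#' @return named numeric vector of supports in \[0, 1\]; names are
#'   `+`-joined sorted tumor labels.
#' @export
bootstrapSupport <- function(matrix, reps = 1000, seed = NULL,
                             mode = c("auto", "exhaustive", "heuristic"),
                             outgroup = NULL) {
  stopifnot(reps >= 1)
  mode <- match.arg(mode)
  if (is.null(outgroup)) outgroup <- attr(matrix, "outgroup")
  if (mode == "auto")
    mode <- if (nrow(matrix) <= 8) "exhaustive" else "heuristic"
  labels <- rownames(matrix)
  cand <- if (mode == "exhaustive") .all_topologies(labels, outgroup)
  ref <- searchTrees(matrix, mode = mode, seed = seed, outgroup = outgroup)
  obs <- Reduce(intersect, lapply(ref$trees, .clade_keys,
                                  outgroup = outgroup))
  hits <- stats::setNames(numeric(length(obs)), obs)
  .with_seed(seed, function() {
    for (r in seq_len(reps)) {
      cols <- sample.int(ncol(matrix), replace = TRUE)
      bm <- matrix[, cols, drop = FALSE]
      attr(bm, "outgroup") <- outgroup
      if (mode == "exhaustive") {
        scores <- vapply(cand, function(tr) .fitch(tr, bm)$total,
                         numeric(1))
        best <- lapply(cand[scores == min(scores)], .root_at,
                       outgroup = outgroup)
      } else {
        best <- searchTrees(bm, mode = "heuristic", seed = r,
                            outgroup = outgroup)
        best <- best$trees[vapply(best$trees, function(tr)
          .fitch(tr, bm)$total, numeric(1)) == best$score]
      }
      strict <- Reduce(intersect, lapply(best, .clade_keys,
                                         outgroup = outgroup))
      hits[obs %in% strict] <<- hits[obs %in% strict] + 1
    }
  })
  hits / reps
}

# -- variant assignment and ratios ------------------------------------------

# per-edge descendant tumor-set keys of a rooted tree
.edge_tumor_keys <- function(tree, outgroup) {
  tumors <- setdiff(tree$tip.label, outgroup)
  vapply(seq_len(nrow(tree$edge)), function(k) {
    tips <- .node_tip_labels(tree, tree$edge[k, 2])
    paste(sort(intersect(tips, tumors)), collapse = "+")
  }, character(1))
}

#' Assign variants to tree edges; designate the trunk
#'
#' A non-homoplastic variant is placed on the unique edge subtending
#' exactly its carrier set. A variant whose carrier set matches no edge is
#' flagged homoplastic and assigned to all change edges of one minimal
#' Fitch labeling. The trunk is the edge from the root (normal) side to the
#' most recent common ancestor of all tumor samples; trunk variants are
#' exactly those carried by every tumor sample.
#'
#' @param tree rooted `phylo` (root = normal outgroup); may be a strict
#'   consensus with multifurcations.
#' @param matrix binary presence matrix.
#' @param outgroup outgroup label (default: matrix attribute).
#' @return list with `edge_variants` (list keyed by edge index as
#'   character), `trunk_edge` (integer), `homoplastic` (character).
#' @export
assignVariantsToEdges <- function(tree, matrix, outgroup = NULL) {
  if (is.null(outgroup)) outgroup <- attr(matrix, "outgroup")
  tree <- ape::reorder.phylo(tree, "cladewise")
  tumors <- setdiff(rownames(matrix), outgroup)
  keys <- .edge_tumor_keys(tree, outgroup)
  ev <- stats::setNames(vector("list", nrow(tree$edge)),
                        as.character(seq_len(nrow(tree$edge))))
  homoplastic <- character(0)
  for (j in seq_len(ncol(matrix))) {
    carriers <- tumors[matrix[tumors, j] == 1]
    key <- paste(sort(carriers), collapse = "+")
    hit <- which(keys == key)
    if (length(hit) >= 1) {
      # with consensus trees an edge key can repeat only for the
      # outgroup-side edge; take the tumor-side (last, cladewise) match
      e <- hit[length(hit)]
      ev[[e]] <- c(ev[[e]], colnames(matrix)[j])
    } else {
      homoplastic <- c(homoplastic, colnames(matrix)[j])
      ch <- .fitch_change_edges(tree, matrix[, j])
      for (e in ch) ev[[e]] <- c(ev[[e]], colnames(matrix)[j])
    }
  }
  mrca <- if (length(tumors) == 1) which(tree$tip.label == tumors)
  else ape::getMRCA(tree, tumors)
  trunk <- which(tree$edge[, 2] == mrca)
  if (!length(trunk)) trunk <- NA_integer_
  list(edge_variants = ev, trunk_edge = as.integer(trunk[1]),
       homoplastic = homoplastic, tree = tree)
}

#' Infer a full maximum-parsimony phylogeny
#'
#' Convenience wrapper: searches tree space, takes the strict consensus of
#' all shortest trees, assigns variants to its edges, computes the
#' homoplasy index from the best binary-tree score, and (optionally)
#' bootstrap supports.
#'
#' @param matrix binary presence matrix.
#' @param mode `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param bootstrap_reps bootstrap replicates (0 = skip).
#' @param seed integer seed for heuristic search and bootstrap.
#' @param outgroup outgroup label (default: matrix attribute).
#' @return a [TumorPhylogeny-class].
#' @export
inferPhylogeny <- function(matrix, mode = c("auto", "exhaustive",
                                            "heuristic"),
                           bootstrap_reps = 0, seed = NULL,
                           outgroup = NULL) {
  mode <- match.arg(mode)
  if (is.null(outgroup)) outgroup <- attr(matrix, "outgroup")
  if (mode == "auto")
    mode <- if (nrow(matrix) <= 10) "exhaustive" else "heuristic"
  res <- searchTrees(matrix, mode = mode, seed = seed, outgroup = outgroup)
  cons <- if (length(res$trees) == 1) res$trees[[1]]
  else ape::reorder.phylo(ape::consensus(res$trees, p = 1, rooted = TRUE),
                          "cladewise")
  asg <- assignVariantsToEdges(cons, matrix, outgroup = outgroup)
  hi <- 1 - ncol(matrix) / res$score
  sup <- if (bootstrap_reps > 0)
    bootstrapSupport(matrix, reps = bootstrap_reps, seed = seed,
                     outgroup = outgroup)
  else stats::setNames(numeric(0), character(0))
  new("TumorPhylogeny", tree = asg$tree, outgroup = outgroup,
      score = as.numeric(res$score), homoplasy_index = hi,
      edge_variants = asg$edge_variants, trunk_edge = asg$trunk_edge,
      homoplastic = asg$homoplastic, supports = sup)
}

#' Trunk and branch non-synonymous/synonymous ratios
#'
#' Counts protein-changing (missense, truncating, splice) versus synonymous
#' variants on the trunk and pooled over all non-trunk edges. A zero
#' denominator yields `NA` (undefined), never infinity. Noncoding variants
#' enter neither count.
#'
#' @param phylogeny a [TumorPhylogeny-class], or the list returned by
#'   [assignVariantsToEdges()].
#' @param effects named character vector: effect category per variant
#'   identifier.
#' @return list `T_ns_s`, `B_ns_s`, and `counts` (trunk_ns, trunk_s,
#'   branch_ns, branch_s).
#' @export
nsSRatios <- function(phylogeny, effects) {
  ev <- if (is(phylogeny, "TumorPhylogeny")) phylogeny@edge_variants
  else phylogeny$edge_variants
  trunk <- if (is(phylogeny, "TumorPhylogeny")) phylogeny@trunk_edge
  else phylogeny$trunk_edge
  ns_set <- c("missense", "truncating", "splice")
  tally <- function(ids) {
    eff <- effects[ids]
    c(ns = sum(eff %in% ns_set), s = sum(eff == "synonymous"))
  }
  trunk_ids <- if (!is.na(trunk)) ev[[as.character(trunk)]] else character(0)
  branch_ids <- unlist(ev[setdiff(names(ev), as.character(trunk))])
  tc <- tally(trunk_ids); bc <- tally(branch_ids)
  ratio <- function(x) if (x[["s"]] > 0) x[["ns"]] / x[["s"]] else NA_real_
  list(T_ns_s = ratio(tc), B_ns_s = ratio(bc),
       counts = c(trunk_ns = tc[["ns"]], trunk_s = tc[["s"]],
                  branch_ns = bc[["ns"]], branch_s = bc[["s"]]))
}
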