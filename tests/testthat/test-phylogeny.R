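# presence matrices, Fitch parsimony, tree search, homoplasy, bootstrap,
# edge assignment, ns/s ratios

test_that("presence matrix gains an all-zero outgroup row and validates input", {
  v <- make_variants(5, pos = 1:5,
                     samples = list(A = c(1, 1, 1, 1, 0),
                                    B = c(1, 1, 1, 0, 1)))
  m <- buildPresenceMatrix(v)
  expect_equal(dim(m), c(3, 5))
  expect_equal(unname(m["NORMAL", ]), rep(0L, 5))
  expect_error(buildPresenceMatrix(v, samples = c("A", "A")), "duplicate")
  v0 <- v; v0$A[1] <- 0L; v0$B[1] <- 0L
  expect_error(buildPresenceMatrix(v0), "absent")
})

test_that("Fitch score equals brute-force minimal-change enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    m <- random_matrix(4, 8)
    tr <- ape::rtopology(5, rooted = FALSE, tip.label = rownames(m))
    expect_equal(parsimonyScore(tr, m), brute_parsimony(tr, m))
  }
  # and matches phangorn's independent implementation
  m <- random_matrix(5, 10)
  tr <- ape::rtopology(6, rooted = FALSE, tip.label = rownames(m))
  pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
  expect_equal(parsimonyScore(tr, m),
               as.integer(phangorn::parsimony(tr, pd)))
  # a variant private to one tumor contributes exactly 1 on any tree
  pm <- perfect_matrix(4, per_edge = 1)
  tr <- ape::rtopology(5, rooted = FALSE, tip.label = rownames(pm))
  leaf_col <- pm[, ncol(pm), drop = FALSE]
  expect_equal(parsimonyScore(tr, leaf_col), 1L)
})

test_that("exhaustive search recovers the generating topology of a perfect phylogeny", {
  m <- perfect_matrix(3, per_edge = 5)
  res <- searchTrees(m, mode = "exhaustive")
  expect_equal(res$score, ncol(m))       # no homoplasy
  expect_equal(length(res$trees), 1)     # unique shortest tree
  keys <- osteoevo:::.clade_keys(res$trees[[1]], "NORMAL")
  expect_true("T1+T2" %in% keys)         # the generating clade
  expect_equal(homoplasyIndex(res$trees[[1]], m), 0)
})

test_that("star-like data tie all resolutions at equal length", {
  m <- perfect_matrix(4, per_edge = 1)
  m <- m[, colSums(m[paste0("T", 1:4), ]) %in% c(4, 1), drop = FALSE]
  attr(m, "outgroup") <- "NORMAL"
  res <- searchTrees(m, mode = "exhaustive")
  expect_equal(length(res$trees), 15)    # every 5-taxon topology ties
  expect_error(searchTrees(random_matrix(10, 5), mode = "exhaustive"),
               "heuristic")
})

test_that("heuristic search matches the exhaustive optimum on most instances and never beats it", {
  set.seed(99)
  hit <- 0
  for (i in 1:100) {
    m <- random_matrix(sample(4:6, 1), sample(6, 1) + 4)
    ex <- searchTrees(m, mode = "exhaustive")
    he <- searchTrees(m, mode = "heuristic", seed = i)
    expect_gte(he$score, ex$score)
    hit <- hit + (he$score == ex$score)
  }
  expect_gte(hit, 95)
})

test_that("homoplasy index follows 1 - min/realized with hand-checked cases", {
  # 4 taxa, one clean character + one convergent (forced to change twice)
  m <- cbind(v1 = c(1, 1, 0, 0, 0), v2 = c(1, 0, 1, 0, 0))
  rownames(m) <- c("T1", "T2", "T3", "T4", "NORMAL")
  storage.mode(m) <- "integer"
  attr(m, "outgroup") <- "NORMAL"
  tr <- ape::read.tree(text = "(((T1,T2),(T3,T4)),NORMAL);")
  expect_equal(parsimonyScore(tr, m), 3L)
  expect_equal(homoplasyIndex(tr, m), 1 - 2 / 3)
  # appending a convergent column to a perfect matrix raises HI
  pm <- perfect_matrix(4, per_edge = 2)
  best <- searchTrees(pm, mode = "exhaustive")$trees[[1]]
  expect_equal(homoplasyIndex(best, pm), 0)
  conv <- cbind(pm, vx = c(1L, 0L, 1L, 0L, 0L))
  attr(conv, "outgroup") <- "NORMAL"
  expect_gt(homoplasyIndex(best, conv), 0)
  expect_error(homoplasyIndex(best, pm[, 0]), "empty")
})

test_that("bootstrap supports are high for well-supported clades and low after shuffling", {
  m <- perfect_matrix(3, per_edge = 5)
  sup <- bootstrapSupport(m, reps = 200, seed = 1)
  expect_true(all(sup >= 0.99))
  # single-variant matrix: degenerate support 1.0 for its clade
  m1 <- m[, 11, drop = FALSE]  # a T1+T2 clade variant
  attr(m1, "outgroup") <- "NORMAL"
  sup1 <- bootstrapSupport(m1, reps = 50, seed = 2)
  expect_equal(unname(sup1["T1+T2"]), 1.0)
  # label-shuffled matrices: no nontrivial clade strongly supported
  set.seed(7)
  worst <- 0
  for (s in 1:20) {
    pair_cols <- replicate(24, {
      v <- integer(4); v[sample(4, 2)] <- 1L; v
    })
    triple_cols <- replicate(8, {
      v <- integer(4); v[sample(4, 3)] <- 1L; v
    })
    mr <- t(rbind(t(pair_cols), t(triple_cols)))
    rownames(mr) <- paste0("T", 1:4)
    colnames(mr) <- paste0("v", seq_len(ncol(mr)))
    mr <- rbind(mr, NORMAL = 0L)
    storage.mode(mr) <- "integer"
    attr(mr, "outgroup") <- "NORMAL"
    supr <- bootstrapSupport(mr, reps = 200, seed = s)
    nontriv <- supr[grepl("\\+", names(supr)) &
                      names(supr) != "T1+T2+T3+T4"]
    if (length(nontriv)) worst <- max(worst, nontriv)
  }
  expect_lte(worst, 0.9)
})

test_that("variants land on the edges their carrier sets subtend", {
  m <- perfect_matrix(3, per_edge = 2)
  ph <- inferPhylogeny(m)
  ev <- edgeVariants(ph)
  # trunk carries exactly the all-tumor variants
  expect_setequal(trunkVariants(ph), colnames(m)[1:2])
  # leaf-private variants sit on that leaf's pendant edge
  tr <- phyloTree(ph)
  for (k in 1:3) {
    leaf_cols <- colnames(m)[colSums(m[paste0("T", 1:3), ]) == 1 &
                               m[paste0("T", k), ] == 1]
    edge_of <- vapply(leaf_cols, function(vc)
      which(vapply(ev, function(x) vc %in% x, logical(1)))[[1]],
      numeric(1))
    tip <- which(tr$tip.label == paste0("T", k))
    expect_true(all(tr$edge[edge_of, 2] == tip))
  }
  expect_length(ph@homoplastic, 0)
  # conservation: total assignments = columns (no homoplasy)
  expect_equal(length(unlist(ev)), ncol(m))
})

test_that("simulated cohorts are reassembled exactly from their variants", {
  sim <- simulateCohort(cohortConfig(n_patients = 3, seed = 31))
  for (pt in names(sim$variants)) {
    v <- sim$variants[[pt]]
    gt <- sim$ground_truth[[pt]]
    m <- buildPresenceMatrix(v)
    ph <- inferPhylogeny(m, seed = 1)
    expect_equal(ph@homoplasy_index, 0)
    expect_length(ph@homoplastic, 0)
    # every variant's edge class matches the ground truth
    ev <- edgeVariants(ph)
    tr <- phyloTree(ph)
    ntip <- length(tr$tip.label)
    for (e in names(ev)) {
      if (!length(ev[[e]])) next
      child <- tr$edge[as.integer(e), 2]
      cls <- if (as.integer(e) == ph@trunk_edge) "trunk"
      else if (child <= ntip) "leaf" else "branch"
      truth <- gt$assignment$class[match(ev[[e]], gt$assignment$variant)]
      expect_true(all(truth == cls))
    }
  }
})

test_that("ns/s ratios report counts and undefined denominators honestly", {
  effects <- setNames(c(rep("missense", 10), rep("synonymous", 2)),
                      paste0("v", 1:12))
  fake <- list(edge_variants = list(`1` = paste0("v", 1:12)),
               trunk_edge = 1L)
  r <- nsSRatios(fake, effects)
  expect_equal(r$T_ns_s, 5.0)
  expect_true(is.na(r$B_ns_s))   # no branch synonymous -> undefined

  # pooled cohort ratio close to the planted 2.5:1 within binomial CI
  sim <- simulateCohort(cohortConfig(n_patients = 12, seed = 41))
  ns <- s <- 0
  for (pt in names(sim$variants)) {
    eff <- sim$variants[[pt]]$effect
    ns <- ns + sum(eff %in% c("missense", "truncating", "splice"))
    s <- s + sum(eff == "synonymous")
  }
  p_hat <- ns / (ns + s)
  ci <- p_hat + c(-3, 3) * sqrt(p_hat * (1 - p_hat) / (ns + s))
  expect_true(2.5 / 3.5 > ci[1] && 2.5 / 3.5 < ci[2])
})
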