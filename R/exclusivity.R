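# Mutual-exclusivity testing of driver-gene alterations with a
# margin-constrained background model (the coverage statistic of the
# DISCOVER-style group test), Benjamini-Hochberg adjustment, and cohort
# prevalence arithmetic.

#' Fit the margin-constrained alteration background
#'
#' Models each cell of a binary gene-by-patient alteration matrix as an
#' independent Bernoulli with `p_ij = plogis(a_i + b_j)`, with the gene and
#' patient effects fitted so that every expected row and column sum matches
#' the observed margin (iterative proportional fitting on the logistic
#' parameterization, damped Newton updates, margin tolerance `tol`).
#'
#' @param m binary matrix, genes x patients.
#' @param tol maximum allowed absolute margin error.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the residual margin error.
#' @return matrix of background probabilities `p_ij`, same shape as `m`.
#' @export
fitAlterationBackground <- function(m, tol = 1e-8, max_iter = 5000) {
  m <- (m != 0) * 1L
  G <- nrow(m); N <- ncol(m)
  r <- rowSums(m); s <- colSums(m)
  a <- rep(0, G); b <- rep(0, N)
  clamp <- function(x) pmin(pmax(x, -30), 30)
  deg_row <- r == 0 | r == N           # all-zero or all-one rows
  deg_col <- s == 0 | s == G
  a[r == 0] <- -30; a[r == N] <- 30
  b[s == 0] <- -30; b[s == G] <- 30
  for (iter in seq_len(max_iter)) {
    eta <- outer(a, b, "+")
    P <- stats::plogis(eta)
    # Newton step on gene effects
    num <- r - rowSums(P)
    den <- rowSums(P * (1 - P))
    step <- ifelse(den > 1e-12, num / den, 0)
    a <- clamp(a + pmin(pmax(step, -2), 2))
    a[r == 0] <- -30; a[r == N] <- 30
    eta <- outer(a, b, "+")
    P <- stats::plogis(eta)
    num <- s - colSums(P)
    den <- colSums(P * (1 - P))
    step <- ifelse(den > 1e-12, num / den, 0)
    b <- clamp(b + pmin(pmax(step, -2), 2))
    b[s == 0] <- -30; b[s == G] <- 30
    P <- stats::plogis(outer(a, b, "+"))
    err <- max(abs(rowSums(P) - r)[!deg_row],
               abs(colSums(P) - s)[!deg_col], 0)
    if (err < tol) {
      dimnames(P) <- dimnames(m)
      return(P)
    }
  }
  stop("background fit did not converge: max margin error ",
       signif(err, 4), " after ", max_iter, " iterations")
}

# Poisson-binomial tail P(X >= x) by direct pmf convolution
.poibin_tail_ge <- function(q, x) {
  pmf <- 1
  for (p in q) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  sum(pmf[(x + 1):length(pmf)])
}

#' Group mutual-exclusivity test
#'
#' Tests whether alterations of a gene group cover more patients than
#' expected if genes were independent given the fitted background margins.
#' The statistic is the number of patients altered in at least one group
#' gene; its null tail probability P(coverage >= observed) is computed
#' exactly (Poisson-binomial convolution) for groups of up to three genes,
#' and by seeded Monte Carlo otherwise. A one-gene group carries no
#' exclusivity signal and returns p = 1 by construction.
#'
#' @param m alteration matrix (genes x patients); any non-zero /
#'   non-`"none"` cell counts as altered.
#' @param group character vector of gene names (rows of `m`).
#' @param n_sims Monte Carlo draws when the exact route is not used.
#' @param seed integer seed for Monte Carlo.
#' @param method `"auto"` (exact for <= 3 genes), `"exact"`,
#'   `"montecarlo"`.
#' @return list with `group`, `coverage_observed`, `coverage_expected`,
#'   `p_value`, `method`.
#' @export
exclusivityTest <- function(m, group, n_sims = 10000, seed = NULL,
                            method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  if (!is.matrix(m)) stop("m must be a matrix")
  bin <- if (is.numeric(m) || is.logical(m)) (m != 0) * 1L
  else (m != "none") * 1L
  stopifnot(all(group %in% rownames(bin)))
  P <- fitAlterationBackground(bin)
  sub <- bin[group, , drop = FALSE]
  obs <- sum(colSums(sub) > 0)
  q <- 1 - apply(1 - P[group, , drop = FALSE], 2, prod)
  expected <- sum(q)
  if (length(group) == 1) {
    return(list(group = group, coverage_observed = obs,
                coverage_expected = expected, p_value = 1,
                method = "degenerate"))
  }
  if (method == "auto")
    method <- if (length(group) <= 3) "exact" else "montecarlo"
  p <- if (method == "exact") .poibin_tail_ge(q, obs)
  else .with_seed(seed, function() {
    stopifnot(n_sims >= 1000)
    hits <- 0L
    for (i in seq_len(n_sims))
      hits <- hits + (sum(stats::runif(length(q)) < q) >= obs)
    (hits + 1) / (n_sims + 1)
  })
  list(group = group, coverage_observed = obs,
       coverage_expected = expected, p_value = min(p, 1), method = method)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; monotone, `q >= p`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return numeric q-values.
#' @export
fdrAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Cohort prevalence of alterations in a gene set
#'
#' Counts patients with at least one qualifying alteration in the gene set
#' and reports the percentage the way cohort tables print it: truncated
#' (not rounded) at the requested number of decimals, so 47/78 prints as
#' 60.2 and 58/112 as 51.7.
#'
#' @param m alteration matrix (genes x patients), `"none"` or zero meaning
#'   unaltered.
#' @param gene_set non-empty character vector of genes (rows).
#' @param patients optional character vector: the denominator subset of
#'   patients (default: all columns).
#' @param digits decimals kept in the percentage (default 1).
#' @return list with `count`, `total`, `percent`.
#' @export
cohortPrevalence <- function(m, gene_set, patients = NULL, digits = 1) {
  stopifnot(length(gene_set) >= 1)
  if (is.null(patients)) patients <- colnames(m)
  if (length(patients) == 0) stop("zero patients in denominator")
  miss <- setdiff(gene_set, rownames(m))
  if (length(miss))
    stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  bin <- if (is.numeric(m) || is.logical(m)) (m != 0) else (m != "none")
  sub <- bin[gene_set, patients, drop = FALSE]
  count <- sum(colSums(sub) > 0)
  total <- length(patients)
  pct <- floor(100 * count / total * 10^digits) / 10^digits
  list(count = count, total = total, percent = pct)
}
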