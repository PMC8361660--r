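# 96-channel trinucleotide substitution counting and signature-exposure
# estimation by multinomial-mixture expectation-maximization.

#' The 96 trinucleotide substitution channel labels
#'
#' Pyrimidine convention, standard order: substitution class (C>A, C>G,
#' C>T, T>A, T>C, T>G) outermost, then 5' base, then 3' base.
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
channels96 <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (sub in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
    for (up in bases) for (down in bases)
      out <- c(out, paste0(up, "[", sub, "]", down))
  out
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x)
           paste(rev(x), collapse = ""), character(1)))
}

#' Count a sample's SNVs into the 96 channels
#'
#' Purine-reference SNVs are mapped through the reverse complement.
#' Records without a usable trinucleotide context are skipped with a
#' notice; the returned vector sums to the number of counted SNVs.
#'
#' @param variants a variant table.
#' @param sample sample label; only variants present in this sample are
#'   counted (`NULL` counts every row).
#' @return named integer vector over [channels96()].
#' @export
countChannels96 <- function(variants, sample = NULL) {
  chan <- channels96()
  out <- stats::setNames(integer(96), chan)
  v <- variants[.is_snv(variants), , drop = FALSE]
  if (!is.null(sample)) v <- v[v[[sample]] == 1, , drop = FALSE]
  if (nrow(v) == 0) return(out)
  ctx <- toupper(v$context)
  usable <- !is.na(ctx) & nchar(ctx) == 3 & substr(ctx, 2, 2) == v$ref
  if (any(!usable))
    message(sum(!usable), " SNV(s) without usable context skipped")
  v <- v[usable, , drop = FALSE]; ctx <- ctx[usable]
  alt <- v$alt
  purine <- v$ref %in% c("A", "G")
  ctx[purine] <- .revcomp(ctx[purine])
  alt[purine] <- .complement[alt[purine]]
  lab <- paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">", alt, "]",
                substr(ctx, 3, 3))
  tab <- table(factor(lab, levels = chan))
  out[] <- as.integer(tab)
  out
}

#' Load a 96-channel reference signature matrix
#'
#' Reads a '#'-headed TSV whose first column is the channel label and whose
#' remaining columns are signature probability vectors. With `path = NULL`
#' the shipped synthetic reference (aging/clock AC1, HRD AC3, MMR AC6, UV
#' AC7, and a flat background) is loaded; it is a constructed stand-in with
#' the qualitative channel preferences of those processes, not a database
#' copy — see the file header.
#'
#' @param path path to a signature table, or `NULL` for the shipped one.
#' @return numeric matrix 96 x k, columns summing to 1, rows in
#'   [channels96()] order.
#' @export
referenceSignatures <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signatures_96_synthetic.tsv",
                        package = "osteoevo", mustWork = TRUE)
  df <- .read_hashed_tsv(path)
  chan <- df[[1]]
  m <- as.matrix(as.data.frame(lapply(df[-1], as.numeric)))
  rownames(m) <- chan
  if (!setequal(chan, channels96()))
    stop("signature table channels do not match the 96 standard labels")
  m <- m[channels96(), , drop = FALSE]
  if (any(m < 0)) stop("signature probabilities must be >= 0")
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop("each signature column must sum to 1")
  m
}

#' Fit signature exposures to a 96-channel count vector
#'
#' `em` maximizes the multinomial-mixture likelihood by
#' expectation-maximization from a uniform (deterministic) initialization,
#' iterating until the relative log-likelihood change falls below `tol` or
#' `max_iter` is reached; the log-likelihood is asserted non-decreasing at
#' every step. `nnls` is a least-squares cross-check (non-negative fit of
#' channel frequencies, rescaled to the count total).
#' Exposures are on the count scale and sum to the total SNV count.
#'
#' @param counts named or plain numeric vector of 96 channel counts.
#' @param reference signature matrix from [referenceSignatures()].
#' @param mode `"em"` or `"nnls"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `exposures` (named, count scale), `proportions`,
#'   `log_likelihood`, `iterations`, `mode`, and (EM mode) `ll_trace`, the
#'   per-iteration log-likelihood sequence.
#' @export
fitExposures <- function(counts, reference, mode = c("em", "nnls"),
                         tol = 1e-8, max_iter = 10000) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == nrow(reference), all(counts >= 0),
            ncol(reference) >= 1)
  N <- sum(counts)
  k <- ncol(reference)
  sig_names <- colnames(reference)
  if (N == 0) {
    message("zero total count; exposures are all zero")
    return(list(exposures = stats::setNames(numeric(k), sig_names),
                proportions = stats::setNames(numeric(k), sig_names),
                log_likelihood = 0, iterations = 0L, mode = mode))
  }
  if (mode == "nnls") {
    fit <- pracma::lsqnonneg(reference, as.numeric(counts) / N)
    w <- fit$x
    w <- w / sum(w)
    expo <- w * N
    ll <- .mix_loglik(counts, reference, w)
    return(list(exposures = stats::setNames(expo, sig_names),
                proportions = stats::setNames(w, sig_names),
                log_likelihood = ll, iterations = 1L, mode = mode))
  }
  w <- rep(1 / k, k)
  ll <- .mix_loglik(counts, reference, w)
  ll_trace <- ll
  iter <- 0L
  pos <- counts > 0
  repeat {
    iter <- iter + 1L
    mix <- as.numeric(reference %*% w)
    # responsibilities-weighted exposure update
    resp <- t(reference) * w              # k x 96, row s: w_s * p_cs
    resp <- sweep(resp, 2, mix, "/")
    w_new <- as.numeric(resp[, pos, drop = FALSE] %*% counts[pos]) / N
    ll_new <- .mix_loglik(counts, reference, w_new)
    stopifnot(ll_new >= ll - 1e-9 * abs(ll))   # EM monotonicity
    done <- abs(ll_new - ll) <= tol * abs(ll) || iter >= max_iter
    w <- w_new; ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (done) break
  }
  list(exposures = stats::setNames(w * N, sig_names),
       proportions = stats::setNames(w, sig_names),
       log_likelihood = ll, iterations = iter, mode = mode,
       ll_trace = ll_trace)
}

.mix_loglik <- function(counts, reference, w) {
  mix <- as.numeric(reference %*% w)
  pos <- counts > 0
  sum(counts[pos] * log(mix[pos]))
}
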