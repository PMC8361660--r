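# Molecular-clock back-dating. The model: clock-like (aging-signature)
# clonal mutations accumulate linearly in calendar time at rate r
# (mutations/month), so a count c attributed to the clock corresponds to
# c / r months of elapsed lineage time. The tumor's origin is dated by the
# primary tumor's clonal clock count; metastatic divergence by the
# trunk-shared clock count measured forward from the origin.

#' Estimate the clock mutation rate from sequential samples
#'
#' Least-squares slope of clonal clock-attributed mutation count against
#' collection month. A non-positive slope violates the steady-accumulation
#' assumption and raises an error.
#'
#' @param months numeric collection times (months, any common reference).
#' @param counts clonal clock-attributed mutation counts at those times.
#' @return list with `rate` (mutations/month), `intercept`, `fit` (the
#'   `lm` object).
#' @export
estimateClockRate <- function(months, counts) {
  stopifnot(length(months) == length(counts), length(months) >= 2)
  if (length(unique(months)) < 2)
    stop("need at least two distinct collection months")
  fit <- stats::lm(counts ~ months)
  r <- unname(stats::coef(fit)[2])
  # numerically flat slopes count as violations too
  if (!is.finite(r) || r <= 1e-8 * max(abs(counts), 1))
    stop("clock violation: clock mutation count does not increase with time",
         " (estimated slope ", signif(r, 3), ")")
  list(rate = r, intercept = unname(stats::coef(fit)[1]), fit = fit)
}

#' Back-date tumor origin and metastatic divergence
#'
#' Origin is `primary_count / r` months before the primary biopsy;
#' divergence is `trunk_shared_count / r` months after the origin.
#' Uncertainty intervals come from Poisson-resampling the two counts with a
#' fixed seed.
#'
#' @param primary_count clonal clock-attributed mutations in the primary.
#' @param trunk_shared_count clock-attributed mutations shared by all
#'   samples (the trunk); must not exceed `primary_count`.
#' @param r clock rate (mutations/month), > 0.
#' @param boot number of bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param level interval coverage (default 0.95).
#' @return list with `rate`, `origin_months_before_biopsy`,
#'   `divergence_months_after_origin`, and `intervals` (2 x 2 matrix of
#'   bootstrap quantiles).
#' @export
dateOriginDivergence <- function(primary_count, trunk_shared_count, r,
                                 boot = 200, seed = NULL, level = 0.95) {
  stopifnot(r > 0, primary_count >= 0)
  if (trunk_shared_count > primary_count)
    stop("trunk-shared count cannot exceed the primary count")
  origin <- primary_count / r
  divergence <- trunk_shared_count / r
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  intervals <- .with_seed(seed, function() {
    po <- stats::rpois(boot, primary_count) / r
    pd <- stats::rpois(boot, trunk_shared_count) / r
    rbind(origin = stats::quantile(po, qs),
          divergence = stats::quantile(pd, qs))
  })
  list(rate = r, origin_months_before_biopsy = origin,
       divergence_months_after_origin = divergence,
       intervals = intervals)
}
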