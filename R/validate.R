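#' Coincidence of a selection with independent sites
#'
#' A site counts as coincident when at least one selected pixel centre falls
#' within it (any-overlap rule; site polygons follow pixel edges, so
#' membership is exact).
#'
#' @param selection A `selection_result`, or a 0/1 matrix of selected pixels.
#' @param sites Non-empty list of site polygons, each a data frame with
#'   `row` and `col` columns.
#' @param grid Optional `grid_spec`, required when `selection` is a
#'   `selection_result` (to shape the selection mask).
#' @return List with `n_coincident` and `n_sites`.
#' @export
coincidence <- function(selection, sites, grid = NULL) {
  if (!length(sites)) stop("empty validation site list", call. = FALSE)
  if (inherits(selection, "selection_result")) {
    if (is.null(grid)) stop("grid required to rasterise a selection_result", call. = FALSE)
    mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
    if (nrow(selection$selected))
      mask[cbind(selection$selected$row, selection$selected$col)] <- TRUE
  } else {
    mask <- selection > 0 & !is.na(selection)
  }
  hit <- vapply(sites, function(s)
    any(mask[cbind(s$row, s$col)]), logical(1))
  list(n_coincident = sum(hit), n_sites = length(sites))
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood two-sided p-value: the sum of `Pr(j | n, p0)` over all
#' outcomes `j` no more probable than the observed count. For `p0 = 0.5`
#' this equals the symmetric two-tail sum.
#'
#' @param successes Observed success count (0..n).
#' @param n Number of trials (>= 1).
#' @param p0 Null success proportion.
#' @return The exact two-sided p-value.
#' @export
exact_binomial_test <- function(successes, n, p0 = 0.5) {
  check_counts(successes, n)
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]", call. = FALSE)
  stats::binom.test(successes, n, p = p0)$p.value
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile construction; the lower endpoint is exactly 0 when
#' `successes = 0` and the upper exactly 1 when `successes = n`.
#'
#' @param successes Observed success count (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level.
#' @return Numeric vector `c(low, high)` on the proportion scale.
#' @export
clopper_pearson_ci <- function(successes, n, confidence = 0.95) {
  check_counts(successes, n)
  alpha <- 1 - confidence
  low <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  high <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(low = low, high = high)
}

check_counts <- function(successes, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.numeric(successes) || length(successes) != 1L ||
      successes < 0 || successes > n || successes != round(successes))
    stop("successes must be an integer in 0..n", call. = FALSE)
  invisible(TRUE)
}

#' Validation report for a coincidence count
#'
#' Composes the coincidence rate (the model's true presence rate, or
#' sensitivity), its exact Clopper-Pearson interval and the two-sided exact
#' binomial test against `p0`. Rates and interval bounds are reported in
#' percent.
#'
#' @param n_coincident Number of sites intersected by the selection.
#' @param n_sites Number of validation sites.
#' @param p0 Null proportion for the binomial test.
#' @param confidence Confidence level for the interval.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(n_coincident, n_sites, p0 = 0.5,
                              confidence = 0.95) {
  check_counts(n_coincident, n_sites)
  ci <- clopper_pearson_ci(n_coincident, n_sites, confidence)
  structure(list(n_sites = n_sites, n_coincident = n_coincident,
                 rate = 100 * n_coincident / n_sites,
                 ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
                 p_value = exact_binomial_test(n_coincident, n_sites, p0),
                 null_proportion = p0, confidence = confidence),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d of %d sites coincident: %.0f%% (%.0f%%-%.0f%% CI), exact binomial p = %.4g vs p0 = %g\n",
    x$n_coincident, x$n_sites, x$rate, x$ci_low, x$ci_high, x$p_value,
    x$null_proportion))
  invisible(x)
}

#' Validate a selection against independent sites
#'
#' Runs [coincidence()] and wraps the counts in a [validation_report()].
#'
#' @inheritParams coincidence
#' @inheritParams validation_report
#' @return A `validation_report`.
#' @export
validate_selection <- function(selection, sites, grid = NULL, p0 = 0.5,
                               confidence = 0.95) {
  co <- coincidence(selection, sites, grid)
  validation_report(co$n_coincident, co$n_sites, p0, confidence)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(n_sites = x$n_sites, n_coincident = x$n_coincident,
             rate = x$rate, ci_low = x$ci_low, ci_high = x$ci_high,
             p_value = x$p_value, null_proportion = x$null_proportion)
}
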