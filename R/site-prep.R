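#' @title Presence and pseudo-absence pixel extraction
#' @description Helpers that turn stand polygons plus covariate rasters into
#'   labelled pixel tables at prevalence 0.5, following the stand-composition
#'   rules: oak share >= 60% of the stand qualifies as presence, broadleaved
#'   stands with oak absent or <= 10% supply absence candidates, and stands
#'   in between belong to neither class.
#' @name site_prep
NULL

# data frame of pixel records (region_id, stand_id, row, col, covariates)
# for the pixels of the given stand ids; rows with any NoData covariate are
# dropped and their count attached as attribute "n_dropped_nodata".
pixel_records <- function(stands, stack, stand_ids) {
  keep <- stands$label %in% stand_ids
  cells <- which(keep)
  if (!length(cells)) {
    out <- data.frame(region_id = integer(0), stand_id = integer(0),
                      row = integer(0), col = integer(0))
    for (nm in names(stack$layers)) out[[nm]] <- numeric(0)
    attr(out, "n_dropped_nodata") <- 0L
    return(out)
  }
  n_rows <- stands$grid$n_rows
  rows <- ((cells - 1L) %% n_rows) + 1L
  cols <- ((cells - 1L) %/% n_rows) + 1L
  out <- data.frame(region_id = stack$region_id[cells],
                    stand_id = stands$label[cells],
                    row = rows, col = cols)
  for (nm in names(stack$layers)) out[[nm]] <- stack$layers[[nm]][cells]
  cov <- as.matrix(out[names(stack$layers)])
  bad <- !stats::complete.cases(cov) | apply(!is.finite(cov), 1L, any)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nodata") <- sum(bad)
  out
}

#' Extract presence pixels from oak-dominated stands
#'
#' Returns every pixel whose containing stand has an oak composition at or
#' above `oak_min_pct` (default 60%) and a training role. Pixels carrying any
#' NoData covariate are dropped and counted in the `n_dropped_nodata`
#' attribute.
#'
#' @param stands A `stand_layer` with composition attributes.
#' @param stack The matching `biophysical_stack`.
#' @param oak_min_pct Minimum oak percentage qualifying a stand as presence.
#' @param roles Stand roles eligible for training data.
#' @return Data frame of pixel records with covariate columns.
#' @export
extract_presence_pixels <- function(stands, stack, oak_min_pct = 60,
                                    roles = "training") {
  stopifnot(inherits(stands, "stand_layer"))
  df <- stands$stands
  if (is.null(df$oak_pct)) stop("stands carry no oak composition attribute", call. = FALSE)
  ids <- df$stand_id[df$oak_pct >= oak_min_pct & df$role %in% roles]
  pixel_records(stands, stack, ids)
}

#' Extract pseudo-absence candidate pixels
#'
#' Pixels from broadleaved-type stands whose oak component is absent or at
#' most `oak_max_pct` (default 10%). Stands with oak strictly between
#' `oak_max_pct` and the presence threshold belong to neither class.
#'
#' @inheritParams extract_presence_pixels
#' @param oak_max_pct Maximum oak percentage for an absence stand.
#' @param types Indicative forest types absence may be drawn from.
#' @return Data frame of pixel records with covariate columns.
#' @export
extract_absence_candidates <- function(stands, stack, oak_max_pct = 10,
                                       types = c("broadleaved", "mixed"),
                                       roles = "training") {
  stopifnot(inherits(stands, "stand_layer"))
  df <- stands$stands
  if (is.null(df$oak_pct)) stop("stands carry no oak composition attribute", call. = FALSE)
  ids <- df$stand_id[df$oak_pct <= oak_max_pct & df$type %in% types &
                       df$role %in% roles]
  pixel_records(stands, stack, ids)
}

#' Sample balanced absence replicates
#'
#' Draws `k` pseudo-absence sets of exactly `n_presence` records each from
#' the candidate pool, without replacement within a set and independently
#' across sets (sets may overlap), keeping prevalence at 0.5 against the
#' presence data.
#'
#' @param candidates Data frame of absence candidate pixel records.
#' @param n_presence Number of presence records to match.
#' @param k Number of replicates (the analysis design uses 15).
#' @param seed Integer seed; fixed seeds reproduce replicate membership.
#' @return List of `k` data frames.
#' @export
sample_absence_replicates <- function(candidates, n_presence, k = 15, seed = 1L) {
  n_cand <- nrow(candidates)
  if (n_cand < n_presence)
    stop(sprintf(
      "absence candidate pool (%d pixels) is smaller than the presence set (%d); short by %d",
      n_cand, n_presence, n_presence - n_cand), call. = FALSE)
  set.seed(as.integer(seed))
  lapply(seq_len(k), function(i) {
    out <- candidates[sample.int(n_cand, n_presence), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Bundle a region's presence data and absence replicates
#'
#' @param region_id Region identifier.
#' @param presence Presence pixel records.
#' @param absence_replicates List of absence pixel record sets, each the same
#'   size as `presence`.
#' @param variable_names Covariate columns used for modelling.
#' @return An object of class `presence_absence_set`.
#' @export
presence_absence_set <- function(region_id, presence, absence_replicates,
                                 variable_names) {
  sizes <- vapply(absence_replicates, nrow, integer(1))
  if (any(sizes != nrow(presence)))
    stop("every absence replicate must match the presence count", call. = FALSE)
  missing_vars <- setdiff(variable_names, names(presence))
  if (length(missing_vars))
    stop("unknown variables: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  structure(list(region_id = region_id, presence = presence,
                 absence_replicates = absence_replicates,
                 variable_names = variable_names),
            class = "presence_absence_set")
}

#' @export
print.presence_absence_set <- function(x, ...) {
  cat(sprintf("<presence_absence_set> region %s: %d presence pixels, %d absence replicates\n",
              x$region_id, nrow(x$presence), length(x$absence_replicates)))
  invisible(x)
}

# VIFs of the columns of x by the regression definition 1/(1 - R^2).
vif_values <- function(x) {
  p <- ncol(x)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(x)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    out[j] <- 1 / max(1 - r2, 1e-12)
  }
  stats::setNames(out, colnames(x))
}

#' Screen covariates for collinearity
#'
#' Iteratively removes, from each offending correlated pair or high-VIF
#' group, the variable contributing least explained variance to the
#' presence/absence response, until all pairwise |r| <= `r_threshold` and
#' all VIF <= `vif_threshold`. Constant columns are flagged and removed
#' first with a warning.
#'
#' @param x Numeric covariate matrix (records x variables).
#' @param response Binary response (0/1) aligned with the rows of `x`,
#'   used to decide which of two collinear variables to keep.
#' @param variable_names Optional variable names (defaults to column names).
#' @param r_threshold Maximum tolerated absolute pairwise correlation.
#' @param vif_threshold Maximum tolerated variance inflation factor.
#' @return An object of class `collinearity_report`: list with
#'   `pairwise_correlations`, `vif_values` (both on the retained set),
#'   `removed`, `retained` and the thresholds used.
#' @export
screen_collinearity <- function(x, response, variable_names = colnames(x),
                                r_threshold = 0.7, vif_threshold = 10) {
  x <- as.matrix(x)
  colnames(x) <- variable_names
  if (ncol(x) < 2L) stop("need at least 2 variables", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 records", call. = FALSE)
  removed <- character(0)

  const <- apply(x, 2L, function(v) stats::sd(v) == 0 || anyNA(v))
  if (any(const)) {
    warning("removing constant column(s): ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    removed <- colnames(x)[const]
    x <- x[, !const, drop = FALSE]
  }

  relevance <- function(v) {
    r <- suppressWarnings(stats::cor(v, response))
    if (is.na(r)) 0 else r^2
  }
  repeat {
    if (ncol(x) < 2L) break
    cm <- stats::cor(x)
    vifs <- vif_values(x)
    offdiag <- abs(cm) > r_threshold & row(cm) != col(cm)
    offenders <- colnames(x)[apply(offdiag, 1L, any) | vifs > vif_threshold]
    if (!length(offenders)) break
    rel <- vapply(offenders, function(nm) relevance(x[, nm]), numeric(1))
    drop_var <- offenders[which.min(rel)]
    removed <- c(removed, drop_var)
    x <- x[, setdiff(colnames(x), drop_var), drop = FALSE]
  }
  structure(list(pairwise_correlations = if (ncol(x) > 1) stats::cor(x) else NULL,
                 vif_values = vif_values(x),
                 removed = removed, retained = colnames(x),
                 r_threshold = r_threshold, vif_threshold = vif_threshold),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("<collinearity_report>\n")
  cat("  removed: ", if (length(x$removed)) paste(x$removed, collapse = ", ") else "-", "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
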