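#' Mask a probability raster to broadleaved woodland
#'
#' Pixels whose containing stand's indicative forest type is not in
#' `categories` are set to zero and marked ineligible; pixels inside keep
#' their value. Pixels without a probability value (outside the region or
#' NoData) are also ineligible.
#'
#' @param prob A `probability_raster` (or bare matrix on the same grid).
#' @param polygons A `stand_layer` co-registered with the raster.
#' @param categories Indicative types counted as broadleaved woodland.
#' @return An object of class `masked_raster`: list with `values` (matrix,
#'   zero outside the mask) and `eligible` (logical matrix).
#' @export
mask_to_broadleaf <- function(prob, polygons,
                              categories = c("broadleaved", "mixed")) {
  values <- if (inherits(prob, "probability_raster")) prob$values else prob
  stopifnot(inherits(polygons, "stand_layer"))
  grid <- polygons$grid
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("probability raster and polygons are not co-registered", call. = FALSE)
  type_of <- polygons$stands$type[match(as.integer(polygons$label),
                                        polygons$stands$stand_id)]
  in_mask <- matrix(type_of %in% categories, grid$n_rows, grid$n_cols)
  eligible <- in_mask & !is.na(values)
  out <- values
  out[!eligible] <- 0
  structure(list(values = out, eligible = eligible, grid = grid),
            class = "masked_raster")
}

#' Rank eligible pixels by probability
#'
#' Eligible pixels sorted from highest to lowest probability; ties broken by
#' (row, col) ascending so the ordering is deterministic.
#'
#' @param masked A `masked_raster` from [mask_to_broadleaf()], or a list
#'   with `values` and `eligible` matrices.
#' @return Data frame with columns `row`, `col`, `prob`, `cell`, in rank
#'   order.
#' @export
rank_pixels <- function(masked) {
  cells <- which(masked$eligible)
  if (!length(cells)) stop("no eligible pixels to rank", call. = FALSE)
  n_rows <- nrow(masked$values)
  out <- data.frame(row = ((cells - 1L) %% n_rows) + 1L,
                    col = ((cells - 1L) %/% n_rows) + 1L,
                    prob = masked$values[cells], cell = cells)
  out <- out[order(-out$prob, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_selection_result <- function(ranked_sel, target_area, pixel_area, method,
                                 per_class_quota = NULL, per_class_achieved = NULL,
                                 shortfalls = NULL, area_shortfall = 0) {
  structure(list(selected = ranked_sel, method = method,
                 target_area = target_area,
                 achieved_area = nrow(ranked_sel) * pixel_area,
                 pixel_area = pixel_area,
                 area_shortfall = area_shortfall,
                 per_class_quota = per_class_quota,
                 per_class_achieved = per_class_achieved,
                 shortfalls = shortfalls,
                 min_selected_probability =
                   if (nrow(ranked_sel)) min(ranked_sel$prob) else NA_real_),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result:%s> %d pixels (%.2f ha of %.2f ha target), min prob %s\n",
              x$method, nrow(x$selected), x$achieved_area, x$target_area,
              format(x$min_selected_probability, digits = 3)))
  invisible(x)
}

#' Area-constrained pixel selection
#'
#' Accumulates ranked pixels from the top until the published regional
#' stocked-oak area would be exceeded: selects the first `n` pixels where
#' `n = max(k : k * pixel_area <= target_area)` (`"not_exceed"`), or the
#' nearest pixel count (`"round_nearest"`). If the eligible pool is smaller
#' than the target, everything is selected and the shortfall recorded.
#'
#' @param ranked Ranked pixel data frame from [rank_pixels()].
#' @param target_area Regional area target in hectares (>= 0).
#' @param pixel_area Pixel area in hectares (0.25 for 50 m pixels).
#' @param mode Rounding rule for converting area to a pixel count.
#' @return A `selection_result`.
#' @export
area_filter <- function(ranked, target_area, pixel_area = 0.25,
                        mode = c("not_exceed", "round_nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_area) || target_area < 0)
    stop("target_area must be >= 0", call. = FALSE)
  n_target <- if (mode == "not_exceed") floor(target_area / pixel_area + 1e-9)
              else round(target_area / pixel_area)
  n <- min(n_target, nrow(ranked))
  shortfall <- max(0, target_area - nrow(ranked) * pixel_area)
  new_selection_result(ranked[seq_len(n), , drop = FALSE], target_area,
                       pixel_area, "area",
                       area_shortfall = if (n < n_target) shortfall else 0)
}

#' Build a 10 m elevation-class histogram
#'
#' Classes are half-open intervals `[10k, 10k + 10)` keyed by their lower
#' bound (the 0-9, 10-19, ... convention).
#'
#' @param elevations Numeric elevations in metres.
#' @param class_width Class width in metres.
#' @return Named integer vector: lower bound -> count.
#' @export
elevation_histogram <- function(elevations, class_width = 10) {
  cls <- floor(elevations / class_width) * class_width
  tab <- table(cls)
  stats::setNames(as.integer(tab), names(tab))
}

#' Rescale an elevation histogram to a new total
#'
#' Largest-remainder rounding so the scaled counts sum exactly to
#' `new_total`, preserving class proportions. Used to inflate a survey
#' sample histogram to a regional pixel target.
#'
#' @param counts Named non-negative counts (lower bound -> count).
#' @param new_total Desired total count.
#' @return Named integer vector with `sum == new_total`.
#' @export
scale_histogram <- function(counts, new_total) {
  if (any(counts < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0 || new_total == 0)
    return(stats::setNames(integer(length(counts)), names(counts)))
  raw <- counts * new_total / total
  base <- floor(raw)
  rem <- new_total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Area-plus-elevation constrained pixel selection
#'
#' Bins ranked pixels into half-open 10 m elevation classes by the DEM value
#' at the pixel centre, then, within each class, takes the highest-ranked
#' pixels until the class quota is met. Classes with too few eligible pixels
#' take all available and record the deficit; quotas are never reallocated
#' across classes.
#'
#' @param ranked Ranked pixel data frame from [rank_pixels()].
#' @param dem Elevation matrix co-registered with the ranking.
#' @param quota Named quota counts (class lower bound -> count), e.g. a
#'   scaled [elevation_histogram()].
#' @param class_width Elevation class width in metres.
#' @param pixel_area Pixel area in hectares.
#' @return A `selection_result` with per-class bookkeeping.
#' @export
elevation_filter <- function(ranked, dem, quota, class_width = 10,
                             pixel_area = 0.25) {
  quota <- stats::setNames(as.integer(quota), names(quota))
  if (any(is.na(quota)) || any(quota < 0))
    stop("quota counts must be non-negative", call. = FALSE)
  lower <- as.numeric(names(quota))
  if (any(is.na(lower)) || any(abs(lower / class_width - round(lower / class_width)) > 1e-9))
    stop("quota class lower bounds must be multiples of the class width", call. = FALSE)
  elev <- dem[ranked$cell]
  cls <- floor(elev / class_width) * class_width
  take <- logical(nrow(ranked))
  achieved <- stats::setNames(integer(length(quota)), names(quota))
  for (k in names(quota)) {
    in_class <- which(cls == as.numeric(k))   # already in rank order
    n_take <- min(quota[[k]], length(in_class))
    if (n_take > 0) take[in_class[seq_len(n_take)]] <- TRUE
    achieved[[k]] <- n_take
  }
  shortfalls <- quota - achieved
  shortfalls <- shortfalls[shortfalls > 0]
  sel <- ranked[take, , drop = FALSE]
  rownames(sel) <- NULL
  new_selection_result(sel, sum(quota) * pixel_area, pixel_area, "elevation",
                       per_class_quota = quota, per_class_achieved = achieved,
                       shortfalls = shortfalls)
}

#' Force training pixels to probability one
#'
#' Diagnostic for whether known training oak stands would be missed by the
#' ranking: sets the probability of every training pixel to 1 and reports
#' the signed mean difference `mean(1 - original)` over those pixels. A
#' small mean difference means the training stands already sat among the
#' highest probabilities.
#'
#' @param prob A `probability_raster` or bare matrix.
#' @param training_pixels Data frame with `row` and `col` columns (may be
#'   empty).
#' @return List with `adjusted` (matrix) and `mean_difference`.
#' @export
manual_adjust_check <- function(prob, training_pixels) {
  values <- if (inherits(prob, "probability_raster")) prob$values else prob
  if (is.null(training_pixels) || !nrow(training_pixels))
    return(list(adjusted = values, mean_difference = 0))
  if (any(training_pixels$row < 1 | training_pixels$row > nrow(values) |
          training_pixels$col < 1 | training_pixels$col > ncol(values)))
    stop("training pixel off the raster grid", call. = FALSE)
  cells <- cbind(training_pixels$row, training_pixels$col)
  orig <- values[cells]
  if (anyNA(orig)) stop("training pixel has no probability value", call. = FALSE)
  adjusted <- values
  adjusted[cells] <- 1
  list(adjusted = adjusted, mean_difference = mean(1 - orig))
}

#' Two-sample Kolmogorov-Smirnov comparison of selections
#'
#' Compares the probability-value distributions of two pixel selections:
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param values_a,values_b Non-empty numeric samples (e.g. selected pixel
#'   probabilities).
#' @return List with `D` and `p`.
#' @export
compare_selections_ks <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both samples must be non-empty", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(ks$statistic), p = ks$p.value)
}
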