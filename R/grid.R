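#' Define a raster grid
#'
#' All rasters in oakmap are plain numeric matrices laid over a common grid.
#' Row 1 is the northern edge; pixel centres sit at half-pixel offsets from
#' `origin` (the upper-left corner, in map units).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param pixel_size Pixel edge length in metres. The default 50 m gives the
#'   0.25 ha pixels used throughout the analysis.
#' @param origin Numeric length-2, map coordinates of the upper-left corner.
#' @param region_count Number of administrative regions the landscape is
#'   divided into (contiguous vertical bands).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, pixel_size = 50, origin = c(0, 0),
                      region_count = 3) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  if (region_count < 1L || region_count > n_cols)
    stop("region_count must be between 1 and n_cols", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
         origin = as.numeric(origin), region_count = as.integer(region_count)),
    class = "grid_spec")
}

#' Pixel area in hectares for a grid
#' @param grid A `grid_spec`.
#' @return Area of one pixel in ha (0.25 for 50 m pixels).
#' @export
pixel_area_ha <- function(grid) grid$pixel_size^2 / 1e4

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels of %g m (%.2f ha each), %d region(s)\n",
              x$n_rows, x$n_cols, x$pixel_size, pixel_area_ha(x), x$region_count))
  invisible(x)
}

# 1-D convolution with edge replication; k must be an odd-length kernel.
conv1 <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  idx <- pmin(pmax(seq.int(1L - r, n + r), 1L), n)
  xp <- x[idx]
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out)[(r + 1L):(r + n)]
}

# Separable Gaussian smoothing of a matrix, edge-replicated.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2L, conv1, k = k)
  t(apply(t(m), 2L, conv1, k = k))
}

# Standardised (mean 0, sd 1) spatially autocorrelated Gaussian field.
# White noise is generated with a margin of 3*sigma on every side and the
# smoothed interior cropped out, so the field is stationary up to the edges.
# Consumes the current RNG stream; callers are responsible for seeding.
random_field <- function(grid, sigma) {
  r <- if (sigma > 0) max(1L, as.integer(ceiling(3 * sigma))) else 0L
  nr <- grid$n_rows + 2L * r
  nc <- grid$n_cols + 2L * r
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- gaussian_smooth(z, sigma)
  z <- z[(r + 1L):(r + grid$n_rows), (r + 1L):(r + grid$n_cols), drop = FALSE]
  s <- stats::sd(z)
  if (is.na(s) || s == 0) return(z * 0)
  (z - mean(z)) / s
}

# Region membership raster: contiguous vertical bands 1..region_count.
region_bands <- function(grid) {
  band_width <- ceiling(grid$n_cols / grid$region_count)
  col_region <- pmin(grid$region_count, (seq_len(grid$n_cols) - 1L) %/% band_width + 1L)
  matrix(rep(col_region, each = grid$n_rows), grid$n_rows, grid$n_cols)
}

#' Write a raster matrix as an Esri ASCII grid
#'
#' A plain-text raster interchange format readable by standard GIS software.
#'
#' @param m Numeric matrix (row 1 = north).
#' @param grid A `grid_spec`.
#' @param path Output file path.
#' @param nodata Value written for `NA` cells.
#' @export
write_ascii_grid <- function(m, grid, path, nodata = -9999) {
  if (!is.matrix(m)) m <- matrix(m, grid$n_rows, grid$n_cols)
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %g", grid$origin[1]),
    sprintf("yllcorner %g", grid$origin[2] - grid$n_rows * grid$pixel_size),
    sprintf("cellsize %g", grid$pixel_size),
    sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid written by [write_ascii_grid()]
#' @param path File path.
#' @return A list with `values` (matrix, `NA` for NODATA) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(ln, " ")[[1]][2])
  }
  n_cols <- val("ncols"); n_rows <- val("nrows")
  cell <- val("cellsize"); nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- t(vapply(body, function(x) as.numeric(x), numeric(n_cols)))
  m[m == nodata] <- NA_real_
  g <- grid_spec(n_rows, n_cols, pixel_size = cell,
                 origin = c(val("xllcorner"), val("yllcorner") + n_rows * cell),
                 region_count = 1)
  list(values = m, grid = g)
}
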