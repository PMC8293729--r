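#' Generate a synthetic biophysical covariate stack
#'
#' Builds the co-registered 50 m raster layers the oak analysis consumes:
#' a digital elevation model (DEM) as a smooth, spatially autocorrelated
#' field, climate layers tied to elevation by fixed lapse coefficients plus
#' autocorrelated noise, and ordinal soil layers cut from thresholded
#' autocorrelated fields.
#'
#' Layer semantics (British forest site classification conventions):
#' \describe{
#'   \item{AT}{accumulated temperature, degree-days above 5 C; decreases
#'     with elevation (lapse 1.8 dd per metre).}
#'   \item{CMD}{climatic moisture deficit, mm; decreases with elevation
#'     (0.45 mm per metre), floored at 0.}
#'   \item{DAMS}{wind-exposure score; increases with elevation
#'     (0.018 units per metre).}
#'   \item{TWI}{topographic wetness index, unitless smooth field.}
#'   \item{DEM}{elevation in metres, >= 0.}
#'   \item{SMR, SNR}{ordinal soil moisture / nutrient regime classes
#'     (integers 1-8 and 1-6).}
#' }
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed; identical seeds reproduce the stack exactly.
#' @param roughness Non-negative scalar scaling all sources of spatial
#'   variation. `roughness = 0` yields a flat landscape (constant layers).
#' @return An object of class `biophysical_stack`: list with `grid`,
#'   `layers` (named list of matrices), `region_id` (integer matrix) and
#'   `params` (the lapse coefficients used, needed to evaluate covariates at
#'   displaced elevations).
#' @export
generate_biophysical <- function(grid, seed = 1L, roughness = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(roughness) || length(roughness) != 1L || roughness < 0)
    stop("roughness must be a non-negative scalar", call. = FALSE)
  params <- list(
    dem_base = 250, dem_amp = 160, at0 = 1850, at_lapse = 1.8,
    cmd0 = 190, cmd_lapse = 0.45, dams0 = 7, dams_gain = 0.018,
    twi0 = 6, sigma_dem = 8, sigma_noise = 5)

  set.seed(as.integer(seed))
  fld <- function(sigma) roughness * random_field(grid, sigma)
  # pmax() drops dim attributes when the first argument is scalar
  as_layer <- function(v) matrix(v, grid$n_rows, grid$n_cols)

  dem  <- as_layer(pmax(0, params$dem_base + params$dem_amp * fld(params$sigma_dem)))
  at   <- as_layer(params$at0 - params$at_lapse * dem + 60 * fld(params$sigma_noise))
  cmd  <- as_layer(pmax(0, params$cmd0 - params$cmd_lapse * dem + 30 * fld(params$sigma_noise)))
  dams <- as_layer(pmax(0, params$dams0 + params$dams_gain * dem + 1.5 * fld(params$sigma_noise)))
  twi  <- as_layer(pmax(0, params$twi0 + 2 * fld(params$sigma_noise)))

  # ordinal soils: fixed normal-quantile breaks so classes are near-uniform
  cut_ordinal <- function(z, n_class) {
    breaks <- c(-Inf, stats::qnorm(seq_len(n_class - 1L) / n_class), Inf)
    matrix(as.integer(cut(z, breaks)), nrow(z), ncol(z))
  }
  smr <- cut_ordinal(fld(6), 8L)
  snr <- cut_ordinal(fld(6), 6L)

  structure(
    list(grid = grid,
         layers = list(AT = at, CMD = cmd, DAMS = dams, TWI = twi, DEM = dem,
                       SMR = smr, SNR = snr),
         region_id = region_bands(grid),
         params = params),
    class = "biophysical_stack")
}

#' @export
print.biophysical_stack <- function(x, ...) {
  cat(sprintf("<biophysical_stack> %d x %d, layers: %s\n",
              x$grid$n_rows, x$grid$n_cols, paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# Serpentine (boustrophedon) orderings of the pixels of one region band.
# The region is cut into horizontal bands `band_height` pixels high; within
# a band, columns are traversed alternately downward and upward so that
# consecutive pixels are always 4-adjacent. Stands are carved from
# contiguous runs within one band, so a 120-pixel stand is a compact
# ~10 x 12 pixel block, never a kilometres-long strip.
# Returns a list of integer cell-index vectors, one per band.
serpentine_bands <- function(grid, region_id, region, band_height = 10L) {
  cols <- which(region_id[1, ] == region)
  if (!length(cols)) return(list())
  n_rows <- grid$n_rows
  bands <- split(seq_len(n_rows), (seq_len(n_rows) - 1L) %/% band_height)
  lapply(bands, function(rows) {
    downward <- TRUE
    out <- vector("list", length(cols))
    for (i in seq_along(cols)) {
      r <- if (downward) rows else rev(rows)
      out[[i]] <- (cols[i] - 1L) * n_rows + r
      downward <- !downward
    }
    unlist(out)
  })
}

# Draw contiguous run lengths in [min_px, max_px] that exactly partition
# n_total pixels; the final run is adjusted within bounds where possible.
chunk_sizes <- function(n_total, min_px, max_px) {
  sizes <- integer(0)
  remaining <- n_total
  while (remaining > 0L) {
    if (remaining <= max_px) {
      # single final stand; may be under-sized if the region itself is small
      sizes <- c(sizes, remaining)
      break
    }
    s <- sample.int(max_px - min_px + 1L, 1L) + min_px - 1L
    if (remaining - s < min_px) s <- remaining - min_px
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  sizes
}

#' Tessellate the landscape into forest stands
#'
#' Partitions every pixel into contiguous stands of approximately 5-30 ha,
#' mirroring subcompartment polygons of a public forest estate map. Each
#' stand receives a region id, an indicative forest type and
#' species-composition percentages summing to 100. Stand boundaries follow
#' pixel edges, so the label raster is an exact polygon representation.
#'
#' @param stack A `biophysical_stack`.
#' @param seed Integer seed.
#' @param min_area,max_area Stand area bounds in hectares (0 < min <= max).
#' @param type_probs Named probabilities for the indicative types
#'   `broadleaved`, `conifer`, `mixed`, `other`.
#' @return An object of class `stand_layer`: list with `grid`, `label`
#'   (integer matrix of stand ids) and `stands` (data frame of attributes:
#'   region_id, type, n_pixels, area_ha, composition percentages, role).
#' @export
generate_stands <- function(stack, seed = 1L, min_area = 5, max_area = 30,
                            type_probs = c(broadleaved = 0.45, conifer = 0.30,
                                           mixed = 0.20, other = 0.05)) {
  stopifnot(inherits(stack, "biophysical_stack"))
  grid <- stack$grid
  pa <- pixel_area_ha(grid)
  if (!(min_area > 0 && min_area <= max_area))
    stop("need 0 < min_area <= max_area", call. = FALSE)
  if (max_area < pa)
    stop("max_area is smaller than one pixel", call. = FALSE)
  min_px <- max(1L, as.integer(ceiling(min_area / pa)))
  max_px <- max(min_px, as.integer(floor(max_area / pa)))

  set.seed(as.integer(seed))
  label <- matrix(NA_integer_, grid$n_rows, grid$n_cols)
  stand_region <- integer(0)
  next_id <- 1L
  for (r in seq_len(grid$region_count)) {
    for (cells in serpentine_bands(grid, stack$region_id, r)) {
      sizes <- chunk_sizes(length(cells), min_px, max_px)
      ids <- rep.int(seq.int(next_id, next_id + length(sizes) - 1L), sizes)
      label[cells] <- ids
      stand_region <- c(stand_region, rep.int(r, length(sizes)))
      next_id <- next_id + length(sizes)
    }
  }
  n_stand <- next_id - 1L
  n_px <- tabulate(label, nbins = n_stand)

  type <- sample(names(type_probs), n_stand, replace = TRUE, prob = type_probs)
  comp <- t(vapply(type, draw_composition, numeric(4)))
  stands <- data.frame(
    stand_id = seq_len(n_stand), region_id = stand_region, type = type,
    n_pixels = n_px, area_ha = n_px * pa,
    oak_pct = comp[, 1], other_broadleaf_pct = comp[, 2],
    conifer_pct = comp[, 3], nonwood_pct = comp[, 4],
    role = "training", row.names = NULL, stringsAsFactors = FALSE)
  structure(list(grid = grid, label = label, stands = stands),
            class = "stand_layer")
}

# Provisional composition by indicative type; oak shares are overwritten by
# generate_truth_and_inventory() once occupancy is assigned.
draw_composition <- function(type) {
  out <- c(oak = 0, other_broadleaf = 0, conifer = 0, nonwood = 0)
  if (type == "broadleaved") {
    u <- stats::runif(1)
    out["oak"] <- if (u < 0.25) sample(60:90, 1) else if (u < 0.70) 0 else sample(1:40, 1)
    out["other_broadleaf"] <- 100 - out["oak"]
  } else if (type == "conifer") {
    out["conifer"] <- sample(85:100, 1)
    out["other_broadleaf"] <- 100 - out["conifer"]
  } else if (type == "mixed") {
    out["oak"] <- sample(0:30, 1)
    out["conifer"] <- sample(30:60, 1)
    out["other_broadleaf"] <- 100 - out["oak"] - out["conifer"]
  } else {
    out["nonwood"] <- 100
  }
  out
}

#' @export
print.stand_layer <- function(x, ...) {
  cat(sprintf("<stand_layer> %d stands over %d x %d grid\n",
              nrow(x$stands), x$grid$n_rows, x$grid$n_cols))
  print(table(x$stands$type))
  invisible(x)
}

#' Define the true oak niche and its management distortion
#'
#' The logistic suitability function that generates occupancy in synthetic
#' landscapes. The linear predictor is built from standardised covariates
#' (fixed centres/scales, documented in the methods vignette) and includes a
#' quadratic accumulated-temperature term, giving oak an intermediate
#' elevation optimum, which an additive elevation offset can displace.
#'
#' @param niche_coefficients Named weights on standardised covariates. The
#'   name `AT2` is the coefficient on the squared standardised AT term.
#' @param intercept Intercept of the logit.
#' @param management_bias Elevation offset in metres applied (through the
#'   deterministic covariate lapses) when converting suitability into an
#'   occupancy score; positive values displace occupied stands towards sites
#'   whose climate resembles higher ground.
#' @param occupancy_area_fraction Fraction of the total landscape area
#'   occupied by oak stands.
#' @param occupancy_noise_sd Standard deviation of stand-level logit noise
#'   added to the occupancy score only: unmeasured land-use history. With
#'   `management_bias = 0` and `occupancy_noise_sd = 0`, occupied stands are
#'   exactly the top-suitability stands.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(niche_coefficients = c(AT = 2.2, AT2 = -2.8, CMD = -1.5,
                                               DAMS = -2.0, TWI = 1.0,
                                               SMR = -0.5, SNR = 1.2),
                        intercept = 1.0,
                        management_bias = 150,
                        occupancy_area_fraction = 0.12,
                        occupancy_noise_sd = 1.0) {
  if (occupancy_area_fraction < 0 || occupancy_area_fraction > 1)
    stop("occupancy_area_fraction must be in [0, 1]", call. = FALSE)
  if (occupancy_noise_sd < 0)
    stop("occupancy_noise_sd must be >= 0", call. = FALSE)
  structure(list(niche_coefficients = niche_coefficients, intercept = intercept,
                 management_bias = management_bias,
                 occupancy_area_fraction = occupancy_area_fraction,
                 occupancy_noise_sd = occupancy_noise_sd),
            class = "truth_model")
}

# Fixed standardisation constants for the niche logit.
niche_centres <- c(AT = 1400, CMD = 100, DAMS = 12, TWI = 6, SMR = 4.5, SNR = 3.5)
niche_scales  <- c(AT = 300,  CMD = 60,  DAMS = 4,  TWI = 2, SMR = 2,   SNR = 1.5)

#' Pixel-level suitability surface of a truth model
#'
#' @param stack A `biophysical_stack`.
#' @param truth A `truth_model`.
#' @param elevation_offset Evaluate the elevation-driven covariates (AT, CMD,
#'   DAMS) as if every pixel sat `elevation_offset` metres higher, using the
#'   stack's deterministic lapse coefficients. 0 gives true suitability.
#' @return Matrix of probabilities in `[0, 1]`.
#' @export
suitability_surface <- function(stack, truth, elevation_offset = 0) {
  L <- stack$layers
  p <- stack$params
  at   <- L$AT   - p$at_lapse   * elevation_offset
  cmd  <- L$CMD  - p$cmd_lapse  * elevation_offset
  dams <- L$DAMS + p$dams_gain  * elevation_offset
  z <- function(v, nm) (v - niche_centres[[nm]]) / niche_scales[[nm]]
  b <- truth$niche_coefficients
  coef_of <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  eta <- truth$intercept +
    coef_of("AT")   * z(at, "AT") +
    coef_of("AT2")  * z(at, "AT")^2 +
    coef_of("CMD")  * z(cmd, "CMD") +
    coef_of("DAMS") * z(dams, "DAMS") +
    coef_of("TWI")  * z(L$TWI, "TWI") +
    coef_of("SMR")  * z(L$SMR, "SMR") +
    coef_of("SNR")  * z(L$SNR, "SNR")
  stats::plogis(eta)
}

#' Assign oak occupancy and derive inventory-style products
#'
#' Stand-level occupancy: eligible stands (indicative type broadleaved or
#' mixed) are ranked by an occupancy score -- the suitability logit evaluated
#' at elevations displaced by `truth$management_bias`, plus stand-level noise
#' -- and occupied from the top until the target area
#' (`occupancy_area_fraction` of the landscape) would be exceeded. Occupied
#' stands get an oak canopy share of 60-95%; unoccupied broadleaved stands
#' get 0, a small (<=10%) or an intermediate share.
#'
#' Inventory products mirror a national forest inventory: per-region stocked
#' oak area targets (occupied pixels x pixel area, optionally noised), a 10 m
#' elevation-class histogram built from a small area sample of occupied
#' stands, and validation sites -- occupied stands withheld from training.
#'
#' @param stands A `stand_layer` (modified copy returned).
#' @param stack The matching `biophysical_stack`.
#' @param truth A `truth_model`.
#' @param seed Integer seed.
#' @param validation_fraction Fraction of occupied stands withheld as
#'   independent validation sites.
#' @param sample_fraction Fraction of occupied stand area sampled for the
#'   elevation histogram (the national survey samples 0.6%).
#' @param area_noise_sd Relative sd of multiplicative noise on the published
#'   area targets (0 = exact).
#' @param site_footprint_px Pixels per validation-site footprint: each
#'   withheld stand is represented by this many pixels around its centroid
#'   (4 pixels = the 1 ha survey-plot convention).
#' @param estate_skew Strength of the suitability skew in choosing which
#'   occupied stands form the training estate (0 = random withholding;
#'   larger values make training stands increasingly suitability-typical
#'   and the withheld validation population increasingly atypical).
#' @return A list with `stands` (updated `stand_layer` with oak shares and
#'   roles), `occupancy` (0/1 matrix), `suitability` and `occupancy_score`
#'   matrices, `inventory` (list: `regional_area_targets` data frame,
#'   `elevation_histograms` data frame with columns region, elev_class_lower,
#'   count in pixels, `sample_fraction`, `sampled_stand_ids`), and
#'   `validation_sites` (list of data frames with columns row, col plus a
#'   region attribute).
#' @export
generate_truth_and_inventory <- function(stands, stack, truth, seed = 1L,
                                         validation_fraction = 0.25,
                                         sample_fraction = 0.006,
                                         area_noise_sd = 0,
                                         site_footprint_px = 4L,
                                         estate_skew = 1) {
  stopifnot(inherits(stands, "stand_layer"), inherits(stack, "biophysical_stack"),
            inherits(truth, "truth_model"))
  grid <- stands$grid
  pa <- pixel_area_ha(grid)
  df <- stands$stands
  set.seed(as.integer(seed))

  suit <- suitability_surface(stack, truth, elevation_offset = 0)
  suit_biased <- suitability_surface(stack, truth,
                                     elevation_offset = truth$management_bias)
  mean_by_stand <- function(m) {
    as.numeric(tapply(as.numeric(m), as.numeric(stands$label), mean))[df$stand_id]
  }
  df$suitability <- mean_by_stand(suit)
  score_logit <- stats::qlogis(pmin(pmax(mean_by_stand(suit_biased), 1e-12), 1 - 1e-12))
  df$occupancy_score <- score_logit +
    stats::rnorm(nrow(df), 0, truth$occupancy_noise_sd)

  eligible <- df$type %in% c("broadleaved", "mixed")
  target_area <- truth$occupancy_area_fraction * grid$n_rows * grid$n_cols * pa
  if (target_area > sum(df$area_ha[eligible]))
    stop("occupancy_area_fraction exceeds the available broadleaved area",
         call. = FALSE)
  ord <- order(-df$occupancy_score, df$stand_id)
  ord <- ord[eligible[ord]]
  cum <- cumsum(df$area_ha[ord])
  occupied_ids <- df$stand_id[ord[cum <= target_area + 1e-9]]
  df$occupied <- df$stand_id %in% occupied_ids

  # rewrite oak composition consistently with occupancy
  n_occ <- sum(df$occupied)
  df$oak_pct[df$occupied] <- sample(60:95, n_occ, replace = TRUE)
  unocc_elig <- which(eligible & !df$occupied)
  u <- stats::runif(length(unocc_elig))
  df$oak_pct[unocc_elig] <- ifelse(u < 0.60, 0,
                            ifelse(u < 0.85, sample(1:10, length(unocc_elig), TRUE),
                                   sample(11:59, length(unocc_elig), TRUE)))
  broad <- df$type %in% c("broadleaved", "mixed")
  df$other_broadleaf_pct[broad] <- pmax(0, 100 - df$oak_pct[broad] - df$conifer_pct[broad])

  occupancy <- matrix(0L, grid$n_rows, grid$n_cols)
  occupancy[stands$label %in% occupied_ids] <- 1L

  # Withhold validation sites. Training stands emulate a managed public
  # estate whose oak sits on climatically typical (high-suitability) sites:
  # withholding is weighted towards occupied stands atypical of the pure
  # niche, so the withheld population mirrors the private/ancient oak the
  # survey sees but the training map does not. With management_bias = 0 and
  # no occupancy noise all occupied stands are top-suitability and the skew
  # is immaterial.
  df$role <- "training"
  occ_idx <- which(df$occupied)
  n_val <- round(validation_fraction * n_occ)
  val_ids <- integer(0)
  if (n_val > 0) {
    z <- scale(stats::qlogis(pmin(pmax(df$suitability[occ_idx], 1e-12), 1 - 1e-12)))
    if (anyNA(z)) z <- matrix(0, length(occ_idx))
    w <- exp(-estate_skew * as.numeric(z))
    val_ids <- df$stand_id[sample(occ_idx, n_val, prob = w)]
  }
  df$role[df$stand_id %in% val_ids] <- "validation"

  # each withheld stand contributes a small survey-plot footprint (the
  # site_footprint_px pixels nearest the stand centroid; 4 px = 1 ha)
  validation_sites <- lapply(val_ids, function(id) {
    cells <- which(stands$label == id, arr.ind = TRUE)
    ctr <- colMeans(cells)
    d <- (cells[, 1] - ctr[1])^2 + (cells[, 2] - ctr[2])^2
    keep <- order(d)[seq_len(min(site_footprint_px, nrow(cells)))]
    site <- data.frame(row = cells[keep, 1], col = cells[keep, 2])
    attr(site, "region_id") <- df$region_id[df$stand_id == id]
    attr(site, "stand_id") <- id
    site
  })

  # published regional area targets
  regions <- sort(unique(df$region_id))
  occ_px_region <- vapply(regions, function(r)
    sum(df$n_pixels[df$occupied & df$region_id == r]), numeric(1))
  area_target <- occ_px_region * pa
  if (area_noise_sd > 0)
    area_target <- pmax(0, area_target * (1 + stats::rnorm(length(regions), 0, area_noise_sd)))
  regional_area_targets <- data.frame(region = regions, area_ha = area_target)

  # Elevation histogram from a survey-plot sample of occupied stands, per
  # region: plot locations are pixels drawn without replacement from all
  # occupied stands (public and withheld alike, as a national survey samples
  # every ownership) until sample_fraction of the occupied area is covered.
  dem <- stack$layers$DEM
  occ_cells_all <- which(occupancy == 1L)
  hist_rows <- list()
  sampled_plots <- integer(0)
  for (r in regions) {
    cells_r <- occ_cells_all[stack$region_id[occ_cells_all] == r]
    if (!length(cells_r)) next
    n_plots <- max(1L, round(sample_fraction * length(cells_r)))
    plots <- sample(cells_r, n_plots)
    sampled_plots <- c(sampled_plots, plots)
    cls <- floor(dem[plots] / 10) * 10
    tab <- table(cls)
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      region = r, elev_class_lower = as.numeric(names(tab)),
      count = as.integer(tab))
  }
  elevation_histograms <- do.call(rbind, hist_rows)

  stands$stands <- df
  list(stands = stands, occupancy = occupancy, suitability = suit,
       occupancy_score = df$occupancy_score,
       inventory = list(regional_area_targets = regional_area_targets,
                        elevation_histograms = elevation_histograms,
                        sample_fraction = sample_fraction,
                        sampled_plot_cells = sampled_plots),
       validation_sites = validation_sites,
       occupied_stand_ids = occupied_ids)
}
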