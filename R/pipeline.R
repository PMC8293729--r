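#' Pipeline configuration
#'
#' One list holding every tunable of the end-to-end analysis, with the study
#' defaults. Any field can be overridden through `...`.
#'
#' Landscape: a 200 x 200 grid of 50 m pixels (10,000 ha) in 3 regions, oak
#' occupying 12% of the landscape under a niche with an intermediate-
#' elevation optimum displaced 150 m by management history. Modelling: 15
#' absence replicates x 30 repeats of 50/50 stratified cross-validation over
#' four learners, TSS-weighted. Filtering: regional stocked-area targets and
#' 10 m elevation-class quotas scaled from a stand sample. Validation: exact
#' binomial statistics against withheld oak stands.
#'
#' @param ... Named overrides of any default field.
#' @return A list of class `oak_config`.
#' @export
oak_config <- function(...) {
  cfg <- list(
    seed = 42L,
    # landscape
    n_rows = 200L, n_cols = 200L, pixel_size = 50, region_count = 3L,
    roughness = 1, min_area = 5, max_area = 30,
    truth = truth_model(),
    validation_fraction = 0.25, sample_fraction = 0.1, area_noise_sd = 0,
    # site data preparation
    oak_min_pct = 60, oak_max_pct = 10, presence_fraction = 0.5,
    k_replicates = 15L, r_threshold = 0.7, vif_threshold = 10,
    # ensemble
    algorithms = NULL,        # NULL = sdm_algorithms() defaults
    n_repeats = 30L, split = 0.5, min_converged_fraction = 0.5,
    ensemble_mode = "per_run",
    # filtering
    broadleaf_categories = c("broadleaved", "mixed"),
    adjust_before_filter = FALSE, class_width = 10,
    # validation
    p0 = 0.5, confidence = 0.95)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  class(cfg) <- "oak_config"
  cfg
}

#' Simulate the synthetic landscape and its inventory products
#'
#' @param config An [oak_config()].
#' @return List with `grid`, `stack`, `stands`, `truth` (the generator
#'   output: occupancy, suitability, inventory, validation sites).
#' @export
stage_simulate <- function(config = oak_config()) {
  grid <- grid_spec(config$n_rows, config$n_cols, config$pixel_size,
                    region_count = config$region_count)
  stack <- generate_biophysical(grid, seed = config$seed,
                                roughness = config$roughness)
  stands <- generate_stands(stack, seed = config$seed + 1L,
                            min_area = config$min_area,
                            max_area = config$max_area)
  truth <- generate_truth_and_inventory(
    stands, stack, config$truth, seed = config$seed + 2L,
    validation_fraction = config$validation_fraction,
    sample_fraction = config$sample_fraction,
    area_noise_sd = config$area_noise_sd)
  list(grid = grid, stack = stack, stands = truth$stands, truth = truth)
}

#' Prepare balanced presence/absence tables per region
#'
#' Extracts presence pixels (oak >= 60% training stands), optionally
#' subsamples them by `presence_fraction`, draws the balanced absence
#' replicates, and screens covariates for collinearity per region.
#'
#' @param sim Output of [stage_simulate()].
#' @param config An [oak_config()].
#' @return List with per-region `presence_absence_set`s (`pa_sets`),
#'   collinearity reports and NoData bookkeeping.
#' @export
stage_prepare <- function(sim, config = oak_config()) {
  stands <- sim$stands
  stack <- sim$stack
  presence_all <- extract_presence_pixels(stands, stack, config$oak_min_pct)
  absence_all <- extract_absence_candidates(stands, stack, config$oak_max_pct,
                                            types = config$broadleaf_categories)
  candidates <- names(stack$layers)
  regions <- sort(unique(stands$stands$region_id))
  pa_sets <- list(); screens <- list()
  for (r in regions) {
    pres <- presence_all[presence_all$region_id == r, , drop = FALSE]
    abse <- absence_all[absence_all$region_id == r, , drop = FALSE]
    if (!nrow(pres)) next
    if (config$presence_fraction < 1) {
      set.seed(config$seed + 100L + r)
      keep <- sample.int(nrow(pres), max(4L, floor(nrow(pres) * config$presence_fraction)))
      pres <- pres[keep, , drop = FALSE]
    }
    reps <- sample_absence_replicates(abse, nrow(pres), k = config$k_replicates,
                                      seed = config$seed + 200L + r)
    screen_x <- rbind(pres[candidates], reps[[1]][candidates])
    screen_y <- rep(c(1L, 0L), times = c(nrow(pres), nrow(reps[[1]])))
    screens[[as.character(r)]] <- screen_collinearity(
      as.matrix(screen_x), screen_y, candidates,
      r_threshold = config$r_threshold, vif_threshold = config$vif_threshold)
    pa_sets[[as.character(r)]] <- presence_absence_set(
      r, pres, reps, screens[[as.character(r)]]$retained)
  }
  if (!length(pa_sets)) stop("no region yielded presence data", call. = FALSE)
  list(pa_sets = pa_sets, collinearity = screens,
       n_presence_dropped = attr(presence_all, "n_dropped_nodata"),
       n_absence_dropped = attr(absence_all, "n_dropped_nodata"))
}

# covariate matrix + cell indices of all eligible (broadleaved-category,
# complete-covariate) pixels of one region
eligible_newdata <- function(sim, region, categories) {
  stands <- sim$stands; stack <- sim$stack
  type_of <- stands$stands$type[match(as.integer(stands$label),
                                      stands$stands$stand_id)]
  in_cat <- matrix(type_of %in% categories,
                   stands$grid$n_rows, stands$grid$n_cols)
  cells <- which(in_cat & stack$region_id == region)
  x <- vapply(stack$layers, function(m) m[cells], numeric(length(cells)))
  ok <- stats::complete.cases(x) & apply(is.finite(x), 1L, all)
  list(cells = cells[ok], x = x[ok, , drop = FALSE])
}

#' Fit the per-region ensembles and assemble probability rasters
#'
#' @param prep Output of [stage_prepare()].
#' @param sim Output of [stage_simulate()].
#' @param config An [oak_config()].
#' @return List with the combined evaluation `ledger`, per-region
#'   `cv_result`s, the algorithm stability report and per-region
#'   `probability_raster`s.
#' @export
stage_fit <- function(prep, sim, config = oak_config()) {
  algorithms <- config$algorithms %||% sdm_algorithms()
  cvs <- list(); rasters <- list(); newdatas <- list()
  for (r in names(prep$pa_sets)) {
    nd <- eligible_newdata(sim, as.integer(r), config$broadleaf_categories)
    cvs[[r]] <- cross_validate_region(
      prep$pa_sets[[r]], algorithms, n_repeats = config$n_repeats,
      split = config$split, seed = config$seed + 300L + as.integer(r),
      newdata = nd$x)
    newdatas[[r]] <- nd
  }
  ledger <- do.call(rbind, lapply(cvs, `[[`, "ledger"))
  rownames(ledger) <- NULL
  stability <- exclude_unstable_algorithms(ledger, config$min_converged_fraction)
  for (r in names(cvs)) {
    rasters[[r]] <- ensemble_predict(
      sim$stack, cvs[[r]], newdatas[[r]]$cells,
      retained = stability$retained[[r]], mode = config$ensemble_mode)
  }
  list(ledger = ledger, cv = cvs, stability = stability, rasters = rasters)
}

#' Mask, rank and filter the probability rasters
#'
#' Runs the post-processing per region: broadleaved masking, ranking, the
#' area-only filter against the regional stocked-area target, the
#' area-plus-elevation filter against the 10 m class quota (the survey
#' sample histogram scaled to the regional pixel target), the manual
#' training-pixel adjustment diagnostic, and the Kolmogorov-Smirnov
#' comparison of the two selections' probability distributions.
#'
#' @param fit Output of [stage_fit()].
#' @param prep Output of [stage_prepare()].
#' @param sim Output of [stage_simulate()].
#' @param config An [oak_config()].
#' @return List with per-region selections, the pooled KS comparison and
#'   the mean manual-adjustment difference.
#' @export
stage_filter <- function(fit, prep, sim, config = oak_config()) {
  pa <- pixel_area_ha(sim$grid)
  targets <- sim$truth$inventory$regional_area_targets
  hists <- sim$truth$inventory$elevation_histograms
  area_sel <- list(); elev_sel <- list(); adjust_diffs <- numeric(0)
  for (r in names(fit$rasters)) {
    ri <- as.integer(r)
    train_px <- prep$pa_sets[[r]]$presence[, c("row", "col")]
    adj <- manual_adjust_check(fit$rasters[[r]], train_px)
    adjust_diffs[r] <- adj$mean_difference
    prob <- if (config$adjust_before_filter) adj$adjusted else fit$rasters[[r]]
    masked <- mask_to_broadleaf(prob, sim$stands, config$broadleaf_categories)
    ranked <- rank_pixels(masked)
    target <- targets$area_ha[targets$region == ri]
    if (!length(target)) next
    area_sel[[r]] <- area_filter(ranked, target, pixel_area = pa)
    h <- hists[hists$region == ri, , drop = FALSE]
    if (nrow(h)) {
      counts <- stats::setNames(h$count, h$elev_class_lower)
      quota <- scale_histogram(counts, floor(target / pa + 1e-9))
      elev_sel[[r]] <- elevation_filter(ranked, sim$stack$layers$DEM, quota,
                                        class_width = config$class_width,
                                        pixel_area = pa)
    }
  }
  ks <- compare_selections_ks(
    unlist(lapply(area_sel, function(s) s$selected$prob)),
    unlist(lapply(elev_sel, function(s) s$selected$prob)))
  list(area_selections = area_sel, elevation_selections = elev_sel,
       ks = ks, mean_adjustment = mean(adjust_diffs),
       adjustment_by_region = adjust_diffs)
}

# union of per-region selection results as one landscape 0/1 matrix
selection_mask <- function(selections, grid) {
  mask <- matrix(0L, grid$n_rows, grid$n_cols)
  for (s in selections)
    if (nrow(s$selected)) mask[cbind(s$selected$row, s$selected$col)] <- 1L
  mask
}

#' Validate the filtered predictions against withheld sites
#'
#' @param filt Output of [stage_filter()].
#' @param sim Output of [stage_simulate()].
#' @param config An [oak_config()].
#' @return List with `area` and `elevation` [validation_report()]s.
#' @export
stage_validate <- function(filt, sim, config = oak_config()) {
  sites <- sim$truth$validation_sites
  if (!length(sites)) stop("simulation produced no validation sites", call. = FALSE)
  area_mask <- selection_mask(filt$area_selections, sim$grid)
  elev_mask <- selection_mask(filt$elevation_selections, sim$grid)
  list(area = validate_selection(area_mask, sites, p0 = config$p0,
                                 confidence = config$confidence),
       elevation = validate_selection(elev_mask, sites, p0 = config$p0,
                                      confidence = config$confidence))
}

#' Run the whole oak-mapping pipeline
#'
#' Chains simulate, prepare, fit, filter and validate with a single seeded
#' configuration; re-running with the same config reproduces every output.
#'
#' @param config An [oak_config()].
#' @param quiet Suppress progress messages.
#' @return List with all stage outputs (`sim`, `prep`, `fit`, `filt`,
#'   `val`) and the `config`.
#' @export
run_oak_pipeline <- function(config = oak_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("simulate: ", config$n_rows, " x ", config$n_cols, " landscape, seed ",
      config$seed)
  sim <- stage_simulate(config)
  say("prepare: presence/absence tables for ",
      length(unique(sim$stands$stands$region_id)), " regions")
  prep <- stage_prepare(sim, config)
  say("fit: ", length(prep$pa_sets), " regional ensembles (",
      config$k_replicates, " replicates x ", config$n_repeats, " repeats)")
  fit <- stage_fit(prep, sim, config)
  say("filter: area and elevation constraints")
  filt <- stage_filter(fit, prep, sim, config)
  say("validate: ", length(sim$truth$validation_sites), " withheld sites")
  val <- stage_validate(filt, sim, config)
  list(sim = sim, prep = prep, fit = fit, filt = filt, val = val,
       config = config)
}

#' Write the main pipeline artifacts as plain-text files
#'
#' Evaluation ledger and collinearity reports as CSV, selection and
#' validation reports as JSON, inventory products as CSV, and the combined
#' probability raster as an Esri ASCII grid.
#'
#' @param result Output of [run_oak_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$fit$ledger, file.path(dir, "evaluation_ledger.csv"),
                   row.names = FALSE)
  utils::write.csv(result$sim$truth$inventory$regional_area_targets,
                   file.path(dir, "regional_area_targets.csv"), row.names = FALSE)
  utils::write.csv(result$sim$truth$inventory$elevation_histograms,
                   file.path(dir, "elevation_histograms.csv"), row.names = FALSE)
  prob <- matrix(NA_real_, result$sim$grid$n_rows, result$sim$grid$n_cols)
  for (r in result$fit$rasters) prob[!is.na(r$values)] <- r$values[!is.na(r$values)]
  write_ascii_grid(prob, result$sim$grid, file.path(dir, "oak_probability.asc"))
  sel_summary <- function(s) list(
    method = s$method, target_area = s$target_area,
    achieved_area = s$achieved_area,
    min_selected_probability = s$min_selected_probability,
    shortfalls = as.list(s$shortfalls))
  report <- list(
    area_selections = lapply(result$filt$area_selections, sel_summary),
    elevation_selections = lapply(result$filt$elevation_selections, sel_summary),
    ks = result$filt$ks,
    mean_adjustment = result$filt$mean_adjustment,
    validation = list(area = as.data.frame(result$val$area),
                      elevation = as.data.frame(result$val$elevation)))
  jsonlite::write_json(report, file.path(dir, "selection_validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
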