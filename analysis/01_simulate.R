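# Stage 1: generate the synthetic landscape and its inventory products.
#
# Produces a 10,000 ha landscape of 0.25 ha pixels in 3 regions: elevation-
# linked climate covariates, a 5-30 ha stand tessellation with species
# compositions, oak occupancy displaced 150 m in elevation by management
# history, published-style regional area targets, a survey-plot elevation
# histogram, and 1 ha validation sites withheld from training.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

sim <- cached("sim", stage_simulate(cfg))

df <- sim$stands$stands
message(sprintf("landscape: %d x %d px, %d stands (%.0f-%.0f ha)",
                cfg$n_rows, cfg$n_cols, nrow(df), min(df$area_ha), max(df$area_ha)))
message(sprintf("oak-occupied stands: %d (%.0f ha, %.1f%% of landscape)",
                sum(df$occupied), sum(df$area_ha[df$occupied]),
                100 * sum(df$area_ha[df$occupied]) / sum(df$area_ha)))
message(sprintf("validation sites withheld: %d", length(sim$truth$validation_sites)))

utils::write.csv(df, file.path(res_dir, "stands.csv"), row.names = FALSE)
utils::write.csv(sim$truth$inventory$regional_area_targets,
                 file.path(res_dir, "regional_area_targets.csv"), row.names = FALSE)
utils::write.csv(sim$truth$inventory$elevation_histograms,
                 file.path(res_dir, "elevation_histograms.csv"), row.names = FALSE)
write_ascii_grid(sim$stack$layers$DEM, sim$grid, file.path(res_dir, "dem.asc"))
write_ascii_grid(sim$truth$occupancy, sim$grid, file.path(res_dir, "oak_occupancy.asc"))
message("wrote stands.csv, regional_area_targets.csv, elevation_histograms.csv, dem.asc, oak_occupancy.asc")
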