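# Stage 4: mask, rank and filter the probability raster.
#
# Per region: mask to broadleaved stands, rank pixels by probability, then
# (i) accumulate ranked pixels up to the published regional oak area and
# (ii) fill 10 m elevation-class quotas (the survey histogram scaled to the
# regional pixel target) with the top-ranked pixels of each class. Also
# computes the manual training-pixel adjustment diagnostic and the KS
# comparison of the two selections.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

sim <- cached("sim", stage_simulate(cfg))
prep <- cached("prep", stage_prepare(sim, cfg))
fit <- cached("fit", stage_fit(prep, sim, cfg))
filt <- cached("filt", stage_filter(fit, prep, sim, cfg))

for (kind in c("area_selections", "elevation_selections")) {
  for (r in names(filt[[kind]])) {
    s <- filt[[kind]][[r]]
    message(sprintf("%-10s region %s: %5d px (%.0f of %.0f ha), min prob %.3f",
                    s$method, r, nrow(s$selected), s$achieved_area,
                    s$target_area, s$min_selected_probability))
  }
}
message(sprintf("KS comparison of the two selections: D = %.3f, p = %.3g",
                filt$ks$D, filt$ks$p))
message(sprintf("mean manual adjustment (1 - prob at training oak): %.4f",
                filt$mean_adjustment))

mask_a <- oakmap:::selection_mask(filt$area_selections, sim$grid)
mask_e <- oakmap:::selection_mask(filt$elevation_selections, sim$grid)
write_ascii_grid(mask_a, sim$grid, file.path(res_dir, "selected_area_filter.asc"))
write_ascii_grid(mask_e, sim$grid, file.path(res_dir, "selected_elevation_filter.asc"))

per_class <- do.call(rbind, lapply(names(filt$elevation_selections), function(r) {
  s <- filt$elevation_selections[[r]]
  data.frame(region = r, elev_class_lower = as.numeric(names(s$per_class_quota)),
             quota = as.integer(s$per_class_quota),
             achieved = as.integer(s$per_class_achieved))
}))
utils::write.csv(per_class, file.path(res_dir, "elevation_quota_fill.csv"),
                 row.names = FALSE)
message("wrote selection rasters and elevation_quota_fill.csv")
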