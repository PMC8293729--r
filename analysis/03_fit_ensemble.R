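# Stage 3: the four-learner ensemble, cross-validated and TSS-weighted.
#
# Per region: 15 absence replicates x 30 repeats of stratified 50/50
# cross-validation for GLM, GBM, RF and ANN (1,800 evaluations per region);
# converged runs contribute their prediction surface with weight max(TSS, 0)
# to a single oak probability raster per region.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

sim <- cached("sim", stage_simulate(cfg))
prep <- cached("prep", stage_prepare(sim, cfg))
fit <- cached("fit", stage_fit(prep, sim, cfg))

led <- fit$ledger
utils::write.csv(led, file.path(res_dir, "evaluation_ledger.csv"), row.names = FALSE)

med <- stats::aggregate(tss ~ region + algorithm, led[led$converged, ], stats::median)
names(med)[3] <- "median_tss"
utils::write.csv(med, file.path(res_dir, "tss_by_region.csv"), row.names = FALSE)
message("median TSS by algorithm:")
print(stats::aggregate(tss ~ algorithm, led[led$converged, ], stats::median))
message(sprintf("evaluations: %d total, %.0f%% converged",
                nrow(led), 100 * mean(led$converged)))
drops <- fit$stability$report[!fit$stability$report$retained, ]
message(if (nrow(drops)) paste("dropped:", paste(drops$algorithm, "in region",
                                                 drops$region, collapse = "; "))
        else "all algorithms retained in every region")

prob <- matrix(NA_real_, sim$grid$n_rows, sim$grid$n_cols)
for (r in fit$rasters) prob[!is.na(r$values)] <- r$values[!is.na(r$values)]
write_ascii_grid(prob, sim$grid, file.path(res_dir, "oak_probability.asc"))
message("wrote evaluation_ledger.csv, tss_by_region.csv, oak_probability.asc")
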