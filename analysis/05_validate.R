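# Stage 5: coincidence validation against the withheld sites, plus the
# exact binomial statistics for the published coincidence counts.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

sim <- cached("sim", stage_simulate(cfg))
prep <- cached("prep", stage_prepare(sim, cfg))
fit <- cached("fit", stage_fit(prep, sim, cfg))
filt <- cached("filt", stage_filter(fit, prep, sim, cfg))
val <- stage_validate(filt, sim, cfg)

message("synthetic landscape, area-only filter:")
print(val$area)
message("synthetic landscape, area + elevation filter:")
print(val$elevation)

# the published coincidence counts as inputs to the same statistics
message("published counts, area-only filter (35 of 64):")
print(validation_report(35, 64))
message("published counts, area + elevation filter (53 of 64):")
print(validation_report(53, 64))

out <- rbind(cbind(selection = "synthetic_area", as.data.frame(val$area)),
             cbind(selection = "synthetic_elevation", as.data.frame(val$elevation)),
             cbind(selection = "published_area", as.data.frame(validation_report(35, 64))),
             cbind(selection = "published_elevation", as.data.frame(validation_report(53, 64))))
utils::write.csv(out, file.path(res_dir, "validation.csv"), row.names = FALSE)
jsonlite::write_json(out, file.path(res_dir, "validation.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote validation.csv / validation.json")
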