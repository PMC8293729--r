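# Shared configuration for the analysis scripts: the study conditions.
# Each numbered script can be run on its own; completed stages are cached
# under results/cache/ and reused.

library(oakmap)

cfg <- oak_config(seed = 42L)   # 200 x 200 landscape, 3 regions, 15 x 30 CV
res_dir <- "results"
cache_dir <- file.path(res_dir, "cache")
dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)

cached <- function(name, expr) {
  path <- file.path(cache_dir, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- expr
  saveRDS(value, path)
  value
}
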