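#!/usr/bin/env Rscript
# Step 3 — habitat covariates and the correlation screen.
#
# Engineers the raster variables the models use (distance to natural
# vegetation, moving-window densities, terrain ruggedness, patch contiguity)
# plus the landscape's continuous fields, then screens all pairs for
# |r| >= 0.7; flagged pairs may not enter the same maximum-entropy model.

library(conshab)

out <- "results/03_covariates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_run_config("results/01_sim/run_config.yaml")
landscape <- make_landscape(cfg$sim)   # deterministic from the config
stack <- correlation_screen(build_covariates(landscape))

for (nm in names(stack$rasters))
  write_ascii_grid(stack$rasters[[nm]],
                   file.path(out, paste0(nm, ".asc")))
write_correlation_csv(stack, file.path(out, "correlation.csv"))

message(sprintf("covariates: %s", paste(names(stack$rasters),
                                        collapse = ", ")))
if (nrow(stack$flagged_pairs)) {
  message("flagged correlated pairs (|r| >= 0.7):")
  print(stack$flagged_pairs)
} else message("no covariate pair exceeded |r| = 0.7")
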