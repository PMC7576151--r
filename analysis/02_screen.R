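#!/usr/bin/env Rscript
# Step 2 — telemetry screening and temporal subsampling.
#
# Applies the fix-level rules (capture/mortality records, GPS fix status,
# DOP > 7), then the animal-level rules (age >= 4, >= 30 locations within
# some 12-month window, >= 3 distinct months), and finally thins GPS tracks
# to one location per 5 h. The rejection log records one reason per removal.

library(conshab)

out <- "results/02_screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fixes <- read_fixes_csv("results/01_sim/fixes_raw.csv")
cfg <- read_run_config("results/01_sim/run_config.yaml")

scr <- screen_fixes(fixes, cfg$screening)
sub <- subsample_fixes(scr$kept, cfg$screening$subsample_hours)

write_fixes_csv(sub, file.path(out, "fixes_screened.csv"))
write.csv(scr$log, file.path(out, "rejection_log.csv"), row.names = FALSE)

message(sprintf("screening: kept %d of %d fixes (%.1f%%)",
                scr$n_out, scr$n_in, 100 * scr$n_out / scr$n_in))
print(table(stage = scr$log$stage, reason = scr$log$reason))
message(sprintf("after 5-h subsampling: %d locations from %d animals",
                nrow(sub), length(unique(sub$animal_id))))
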