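#!/usr/bin/env Rscript
# Stage 6 — area accounting: maintained/lost/gained areas between periods
# under both denominator conventions, climate refuges (cells suitable in
# every period) and protected-area coverage. Reads the stage-4 run
# directory and collates one change table in the three-panel layout.

source(file.path("analysis", "00_common.R"))

vs_present <- read.csv(file.path(RUN_DIR, "change_present_vs_future.csv"))
successive <- read.csv(file.path(RUN_DIR, "change_successive.csv"))
succ_mdd <- read.csv(file.path(RUN_DIR, "change_successive_mdd.csv"))
vs_present$panel <- "present_vs_future"
successive$panel <- "successive"
succ_mdd$panel <- "successive_mdd_adjusted"
combined <- rbind(vs_present, successive, succ_mdd)
write.csv(combined, file.path(RESULTS, "change_table.csv"), row.names = FALSE)

summary <- jsonlite::read_json(file.path(RUN_DIR, "summary.json"),
                               simplifyVector = TRUE)
protection <- read.csv(file.path(RUN_DIR, "protection.csv"))

cat("Change accounting (maintained%/lost% vs period 1; gained% per panel convention):\n")
print(combined[, c("panel", "comparison", "maintained_pct", "lost_pct",
                   "gained_pct")], row.names = FALSE, digits = 4)
cat(sprintf("\nClimate refuge (suitable in all periods): %.0f km2 (%.1f%% of the present range).\n",
            summary$refuge_area_km2,
            100 * summary$refuge_area_km2 / summary$suitable_area_km2$present))
cat("Protected-area coverage of the suitable range by period:\n")
print(protection[protection$region == "overall",
                 c("period", "suitable_km2", "protected_km2",
                   "percent_protected")], row.names = FALSE, digits = 4)
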