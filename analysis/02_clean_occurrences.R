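#!/usr/bin/env Rscript
# Stage 2 — occurrence cleaning: drop records beyond the buffered range
# polygon, thin to one record per grid cell, then build the modeling point
# design (hull-radius background sample, congener-derived absences).

source(file.path("analysis", "00_common.R"))

filtered <- range_filter(dataset$occurrences, dataset$range_polygon,
                         config$range_buffer_km)
cleaned <- thin_one_per_cell(filtered, dataset$spec)
radius <- hull_background_radius(cleaned)
background <- sample_background(
  cleaned, background_spec(radius, config$background_multiplier),
  dataset$spec, seed = SEED + 1)
absences <- congener_absences(dataset$congener, dataset$range_polygon,
                              config$congener_exclusion_km)

write_occurrences(cleaned, file.path(RESULTS, "occurrences_clean.csv"))
write_occurrences(background, file.path(RESULTS, "background.csv"))
write_occurrences(absences, file.path(RESULTS, "absences.csv"))

cat(sprintf(paste0(
  "Cleaning kept %d of %d records (%d removed by the %g-km range buffer,\n",
  "%d collapsed by one-per-cell thinning).\n",
  "Accessible-area radius from the presence hull: %.0f km.\n",
  "Background sample: %d points (%dx presences); congener absences kept: %d.\n"),
  nrow(cleaned), nrow(dataset$occurrences),
  nrow(dataset$occurrences) - nrow(filtered),
  config$range_buffer_km, nrow(filtered) - nrow(cleaned), radius,
  nrow(background), config$background_multiplier, nrow(absences)))
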