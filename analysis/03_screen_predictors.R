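#!/usr/bin/env Rscript
# Stage 3 — collinearity screening of the candidate bioclimatic layers on
# the background environment: greedy VIF filter (threshold 9), then the
# pairwise Pearson filter (|r| < 0.6).

source(file.path("analysis", "00_common.R"))

cleaned <- thin_one_per_cell(
  range_filter(dataset$occurrences, dataset$range_polygon,
               config$range_buffer_km), dataset$spec)
background <- sample_background(
  cleaned, background_spec(hull_background_radius(cleaned),
                           config$background_multiplier),
  dataset$spec, seed = SEED + 1)

table_bg <- extract_predictors(dataset$present, background)
vifs_before <- vapply(names(table_bg), function(v) vif(table_bg, v),
                      numeric(1))
after_vif <- stepwise_vif_filter(table_bg, config$vif_threshold)
selected <- correlation_filter(table_bg[after_vif], config$cor_threshold)

report <- data.frame(variable = names(table_bg),
                     vif = round(vifs_before, 2),
                     passed_vif = names(table_bg) %in% after_vif,
                     selected = names(table_bg) %in% selected)
write.csv(report, file.path(RESULTS, "predictor_screening.csv"),
          row.names = FALSE)

cat(sprintf(paste0(
  "Screened %d candidate layers on %d background points.\n",
  "VIF filter (threshold %g) kept %d; correlation filter (|r| < %g) kept %d:\n",
  "  %s\n"),
  ncol(table_bg), nrow(background), config$vif_threshold, length(after_vif),
  config$cor_threshold, length(selected), paste(selected, collapse = ", ")))
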