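# Shared setup for the numbered analysis scripts: one root seed, the
# study-default configuration, and the synthetic dataset all stages share.
# Dataset generation is deterministic and cheap, so every script rebuilds it
# rather than passing binary state around.

library(carayaclim)

SEED <- 42
RESULTS <- file.path("results", "analysis")
RUN_DIR <- file.path(RESULTS, "run")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

config <- default_config()
config$seed <- SEED

dataset <- make_demo_dataset(SEED, n_rows = 100, n_cols = 100)
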