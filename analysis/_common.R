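# Shared configuration for the numbered analysis scripts. Each script is a
# thin driver over the package functions; all computation lives in R/.

library(readiff)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# Study conditions: 60 high-density cases (40 cancer-free, 20 cancer), a
# 20-reader panel, moderate texture-to-error coupling.
study_config <- synthetic_config(
  n_normal = 40, n_cancer = 20, n_readers = 20,
  error_link_slope = 2, seed = 20230601
)

# Reduced tuning grid used throughout the desk-scale analyses (the full
# published-style grid is hyper_grid() with defaults).
reduced_grid <- hyper_grid(n_trees = 100, max_sample_fraction = 1,
                           max_depth = 5, n_selected_features = c(16, 203))

res_path <- function(...) file.path(RESULTS_DIR, ...)
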