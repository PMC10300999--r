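#!/usr/bin/env Rscript
# Nested cross-validated random-forest view models for the false-positive
# basis, on both intensity tracks, with max-probability fusion to case level.

source("analysis/_common.R")

labels_df <- read.csv(res_path("labels_FP.csv"))
labels_df <- labels_df[labels_df$tertile != "median", ]
labels <- setNames(factor(labels_df$tertile, levels = c("easy", "difficult")),
                   labels_df$case_id)

for (track in c("normalized", "raw")) {
  feats <- lapply(setNames(nm = view_tags()), function(v) {
    df <- read.csv(res_path(sprintf("features_%s_%s.csv", track, v)),
                   check.names = FALSE)
    as.matrix(data.frame(df[-1], row.names = df$case_id, check.names = FALSE))
  })
  cv <- nested_cv(feats, labels, grid = reduced_grid,
                  seed = readiff:::substream_seed(study_config$seed,
                                                 paste0("train_", track)))
  write.csv(cv$predictions, res_path(sprintf("predictions_FP_%s.csv", track)),
            row.names = FALSE)
  write.csv(cv$chosen, res_path(sprintf("chosen_FP_%s.csv", track)),
            row.names = FALSE)
  a <- auc(cv$predictions$fused, cv$predictions$label == "difficult")
  cat(sprintf("%-10s track: pooled LOO AUC %.3f over %d cases\n",
              track, a, nrow(cv$predictions)))
}
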