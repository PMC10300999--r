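#!/usr/bin/env Rscript
# Evaluate the fused FP-basis predictions: AUC with stratified-bootstrap CI,
# operating metrics, and DeLong's paired test for the effect of feature
# normalization.

source("analysis/_common.R")

tracks <- list()
for (track in c("normalized", "raw")) {
  p <- read.csv(res_path(sprintf("predictions_FP_%s.csv", track)))
  tracks[[track]] <- p[order(p$case_id), ]
}
stopifnot(identical(tracks$normalized$case_id, tracks$raw$case_id))
y <- tracks$normalized$label == "difficult"

metrics <- list()
for (track in names(tracks)) {
  sc <- tracks[[track]]$fused
  r <- roc_result(sc, y, threshold = 0.5, n_boot = 2000,
                  seed = readiff:::substream_seed(study_config$seed,
                                                 paste0("eval_", track)))
  metrics[[track]] <- list(auc = r$auc, ci = unname(r$ci),
                           sensitivity = r$sensitivity,
                           specificity = r$specificity,
                           accuracy = r$accuracy,
                           n_pos = r$n_pos, n_neg = r$n_neg)
  cat(sprintf("%-10s AUC %.3f (%.3f-%.3f)  sens %.2f spec %.2f acc %.2f\n",
              track, r$auc, r$ci["low"], r$ci["high"],
              r$sensitivity, r$specificity, r$accuracy))
}

dl <- delong_test(tracks$normalized$fused, tracks$raw$fused, y)
cat(sprintf("normalization effect (DeLong): dAUC %.3f, z %.2f, p %.3f\n",
            dl$estimate, dl$statistic, dl$p_value))
metrics$normalization_effect <- list(delta_auc = dl$estimate,
                                     z = dl$statistic, p_value = dl$p_value)

jsonlite::write_json(metrics, res_path("metrics_FP.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", res_path("metrics_FP.json"), "\n")
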