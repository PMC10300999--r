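#!/usr/bin/env Rscript
# Preprocess every view of the FP-labelled cases (segmentation, pectoral
# removal, ROI delineation) and extract the 203-feature bank for both the
# z-scored and the raw intensity track of the central-square ROI.

source("analysis/_common.R")

labels <- read.csv(res_path("labels_FP.csv"))
keep <- labels$case_id[labels$tertile != "median"]

cohort <- generate_cohort(study_config)  # deterministic: same seed as 01
cohort$cases <- cohort$cases[
  vapply(cohort$cases, `[[`, "", "case_id") %in% keep]

for (track in c("normalized", "raw")) {
  feats <- cohort_features(cohort, roi_kind = "square",
                           normalized = track == "normalized")
  for (v in names(feats)) {
    df <- data.frame(case_id = rownames(feats[[v]]), feats[[v]],
                     check.names = FALSE)
    write.csv(df, res_path(sprintf("features_%s_%s.csv", track, v)),
              row.names = FALSE)
  }
  cat(sprintf("%-10s track: %d cases x %d features x %d views\n",
              track, nrow(feats[[1]]), ncol(feats[[1]]), length(feats)))
}
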