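#!/usr/bin/env Rscript
# Turn the reader responses into per-case error proportions and
# easy/median/difficult tertile labels for each error basis.

source("analysis/_common.R")

truth <- read.csv(res_path("truth.csv"))
lesions <- read.csv(res_path("lesions.csv"))
responses <- read.csv(res_path("responses.csv"))

all_labels <- list()
for (basis in c("FP", "FN", "location")) {
  su <- summarize_errors(responses, truth, basis, lesions = lesions,
                         radius = study_config$loc_radius)
  lab <- tertile_split(su)
  out <- merge(su, lab, by = c("case_id", "basis"))
  write.csv(out, res_path(sprintf("labels_%s.csv", basis)), row.names = FALSE)
  all_labels[[basis]] <- out
  cat(sprintf("%-8s n=%2d  proportions %.2f-%.2f  tertiles %s\n",
              basis, nrow(out), min(out$proportion), max(out$proportion),
              paste(table(out$tertile), collapse = "/")))
}

# recovery sanity: under positive coupling, 'difficult' cases should carry
# higher latent difficulty than 'easy' ones
fp <- merge(all_labels$FP, truth, by = "case_id")
cat(sprintf("FP basis: mean d_c difficult = %.2f vs easy = %.2f\n",
            mean(fp$latent_difficulty[fp$tertile == "difficult"]),
            mean(fp$latent_difficulty[fp$tertile == "easy"])))
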