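#!/usr/bin/env Rscript
# Simulate the synthetic screening cohort and its reader panel, and write the
# tables every later stage consumes. A small 12-case demo cohort is also
# exported with its 16-bit PNG views for visual inspection.

source("analysis/_common.R")

cohort <- generate_cohort(study_config)
responses <- simulate_reader_panel(cohort$cases, cohort$truth, study_config)

write.csv(cohort$truth, res_path("truth.csv"), row.names = FALSE)
write.csv(cohort$lesions, res_path("lesions.csv"), row.names = FALSE)
write.csv(responses, res_path("responses.csv"), row.names = FALSE)

cat(sprintf("cohort: %d cases (%d cancer), %d readers, %d responses\n",
            nrow(cohort$truth), sum(cohort$truth$cancer),
            study_config$n_readers, nrow(responses)))
cat(sprintf("latent difficulty range: [%.2f, %.2f]\n",
            min(cohort$truth$latent_difficulty),
            max(cohort$truth$latent_difficulty)))

demo_cfg <- synthetic_config(n_normal = 8, n_cancer = 4, n_readers = 6,
                             seed = 4107)
demo <- generate_cohort(demo_cfg)
demo_resp <- simulate_reader_panel(demo$cases, demo$truth, demo_cfg)
man <- write_cohort(demo, demo_resp, res_path("cohort_demo"))
cat(sprintf("demo cohort written: %d views under %s (config %s)\n",
            man$n_views, res_path("cohort_demo"), man$config_hash))
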