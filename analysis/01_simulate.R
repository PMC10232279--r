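#!/usr/bin/env Rscript
# Stage 1 — simulate the study population and reader study.
#
# Generates an ECG-parameter population with five planted reduced-LVEF
# phenotypes (prevalence calibrated to ~9%), splits it by patient into
# train/test, and simulates the seven-reader before/after interpretation
# study at the printed operating points.  Writes all stage inputs for the
# later scripts under results/.

library(ecgxai)

seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

gen_cfg <- generator_config(n_patients = 5000, seed = seed)
phen <- default_phenotypes()
sim <- simulate_population(gen_cfg, phen)

cat(sprintf("simulated %d ECGs from %d patients; prevalence %.1f%%, paced %d\n",
            length(sim$dataset), length(unique(sim$dataset$patient_id)),
            prevalence(sim$dataset), sum(sim$dataset$paced)))

sp <- split_by_patient(sim$dataset, test_fraction = 0.3, seed = seed + 1L)
cat(sprintf("patient-grouped split: %d train / %d test records (%.1f%% train)\n",
            length(sp$train), length(sp$test),
            100 * length(sp$train) / length(sim$dataset)))

write_ecg_dataset(sp$train, "results/data/train.csv")
write_ecg_dataset(sp$test, "results/data/test.csv")
utils::write.csv(sim$truth, "results/data/phenotype_truth.csv",
                 row.names = FALSE)

rs <- simulate_reader_study(reader_study_config(seed = seed + 11L))
utils::write.csv(rs$data, "results/data/reader_study.csv", row.names = FALSE)
cat("reader study: 7 readers x 100 ECGs written\n")

saveRDS(list(gen_cfg = gen_cfg, phen = phen, seed = seed),
        "results/data/config.rds")
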