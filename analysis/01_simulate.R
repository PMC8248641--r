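#!/usr/bin/env Rscript
# Generate the synthetic survey used by the downstream analysis steps:
# a food catalog with CFG/BNS-tagged foods, ~4000 participants in two age
# strata with calibrated bootstrap replicate weights, and one 24-hr recall
# per participant. Writes the four input CSVs under results/sim/.

library(grainscore)

cfg <- sim_config(seed = 20150L)
dir <- "results/sim"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

catalog <- generate_catalog(cfg)
sv <- generate_survey(cfg, catalog)

write_catalog(catalog, file.path(dir, "catalog.csv"))
write_recalls(sv$recalls, file.path(dir, "recalls.csv"))
write_participants(sv$participants, file.path(dir, "participants.csv"))
write_dv(default_dv_table(), file.path(dir, "dv.csv"))

cat(sprintf("catalog: %d foods in %d categories\n",
            nrow(catalog), length(unique(catalog$cfg_group))))
cat(sprintf("participants: %d (children %d, adults %d), %d replicate weights\n",
            nrow(sv$participants), cfg$n_children, cfg$n_adults, cfg$n_replicates))
cat(sprintf("recall records: %d\n", nrow(sv$recalls)))
cat(sprintf("zero-WG fraction: child %.2f, adult %.2f\n",
            mean(sv$truth$wg_grams[sv$truth$stratum == "child"] == 0),
            mean(sv$truth$wg_grams[sv$truth$stratum == "adult"] == 0)))
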