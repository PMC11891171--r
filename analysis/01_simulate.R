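#!/usr/bin/env Rscript
# Step 1 — simulate the study conditions.
#
# Emits a FAERS-like quarterly stream of 50,000 reports (4 quarters from
# 2013 Q3) in which ten PTs carry a true reporting-rate ratio of 5 for the
# target drug and everything else is null, plus the PT->SOC dictionary and
# the ground-truth sidecar. Downstream steps treat these files exactly as
# they would a real quarterly download.

suppressMessages({
  library(faersignal)
  library(data.table)
})

data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

sig_pts <- c("Nausea", "Vomiting", "Insomnia", "Irritability", "Anger",
             "Pruritus", "Hyperhidrosis", "Weight increased",
             "Serotonin syndrome", "Tinnitus")
cfg <- synthetic_config(
  n_reports = 50000, seed = 20130703,
  signal_spec = setNames(rep(5, length(sig_pts)), sig_pts),
  base_rate = setNames(rep(5e-3, length(sig_pts)), sig_pts))

gen <- generate_faers(cfg, data_dir)
dict <- make_dictionary(cfg, file.path(data_dir, "dictionary.tsv"))
cat(sprintf("dictionary: %d PTs across %d SOCs\n",
            nrow(dict), uniqueN(dict$soc_code)))

lin <- gen$ground_truth$lineage
cat(sprintf("wrote %d quarterly files to %s\n", length(gen$files), data_dir))
cat(sprintf("cases: %d, report versions: %d (duplicated cases: %d)\n",
            uniqueN(lin$caseid), nrow(lin),
            lin[, .N, by = caseid][N > 1, .N]))
cat(sprintf("exposed cases (target drug as primary suspect): %d\n",
            gen$ground_truth$exposed[exposed == TRUE, .N]))
cat(sprintf("seeded signal PTs (rho = 5): %s\n",
            paste(sig_pts, collapse = ", ")))
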