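#!/usr/bin/env Rscript
# Step 2 — ingest, deduplicate, assemble the cohort.
#
# Reads the quarterly stream from step 1, quarantines malformed rows,
# reduces case versions by the FDA rule (latest FDA_DT, ties to the
# highest PRIMARYID), matches the target drug by normalized containment on
# drugname/prod_ai with the primary-suspect role, and strips
# indication-like PTs from the cohort's reaction lists.

suppressMessages({
  library(faersignal)
  library(data.table)
})

data_dir <- "results/data"
out_dir <- "results"

ing <- read_faers_quarters(data_dir)
fwrite(ing$rejects, file.path(out_dir, "rejects.tsv"), sep = "\t")

coh <- build_cohort(ing$tables, cohort_config())
fwrite(coh$demo, file.path(out_dir, "cohort_reports.tsv"), sep = "\t")
counts <- data.table(stage = names(coh$log), n = unlist(coh$log))
fwrite(counts, file.path(out_dir, "stage_counts.tsv"), sep = "\t")

print(coh)
cat(sprintf("rejected rows quarantined: %d\n", nrow(ing$rejects)))

# sanity against ground truth, when the sidecar is present
gt_path <- file.path(data_dir, "ground_truth.json")
if (file.exists(gt_path)) {
  gt <- read_ground_truth(gt_path)
  truth <- gt$lineage[survivor == TRUE, primaryid]
  cat(sprintf("dedup survivors matching ground truth: %d / %d\n",
              length(intersect(coh$survivors, truth)), length(truth)))
}
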