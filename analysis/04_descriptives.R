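#!/usr/bin/env Rscript
# Step 4 — descriptive summaries of the cohort.
#
# Demographic breakdowns (sex, age, weight, reporter, country, outcome)
# with percentages against the full cohort, the annual report
# distribution, and the time-to-onset analysis (median/IQR, share within
# 30 days, histogram).

suppressMessages({
  library(faersignal)
  library(data.table)
})

data_dir <- "results/data"
out_dir <- "results"

coh <- build_cohort(read_faers_quarters(data_dir)$tables, cohort_config())

demog <- summarize_demographics(coh)
demog_long <- rbindlist(lapply(
  c("sex", "age", "weight", "reporter", "country", "outcome"),
  function(blk) data.table(breakdown = blk, demog[[blk]])))
fwrite(demog_long, file.path(out_dir, "demographics.tsv"), sep = "\t")
print(demog)

annual <- annual_distribution(coh)
fwrite(annual, file.path(out_dir, "annual_counts.tsv"), sep = "\t")
cat("reports by receipt year:\n")
print(annual)

tto <- time_to_onset(coh)
fwrite(data.table(statistic = c("n_evaluable", "n_excluded", "median_days",
                                "q1", "q3", "frac_within_30d"),
                  value = c(tto$n_evaluable, tto$n_excluded, tto$median_days,
                            tto$q1, tto$q3, tto$frac_within_30d)),
       file.path(out_dir, "tto_summary.tsv"), sep = "\t")
fwrite(tto$histogram, file.path(out_dir, "tto_histogram.tsv"), sep = "\t")
print(tto)
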