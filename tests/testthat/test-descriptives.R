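test_that("the percentage routine reproduces report-style rounding", {
  expect_equal(pct_of(6875, 11298), 60.9)
  expect_equal(pct_of(2937, 11298), 26.0)
  expect_equal(pct_of(1868, 11298), 16.5)
  expect_equal(pct_of(0, 0), 0)
  expect_equal(round_half_up(2.125, 2), 2.13)  # base round() would give 2.12
})

test_that("every breakdown partitions the cohort and percentages use the full denominator", {
  gen <- gen_tmp(tiny_config(seed = 6, n_reports = 2500))
  coh <- build_cohort(read_faers_quarters(gen$dir)$tables)
  s <- summarize_demographics(coh)
  for (blk in c("sex", "age", "weight", "reporter", "country", "outcome")) {
    expect_equal(sum(s[[blk]]$n), s$n_reports, info = blk)
    expect_equal(s[[blk]]$pct, pct_of(s[[blk]]$n, s$n_reports), info = blk)
    # within rounding of 100%
    expect_lt(abs(sum(s[[blk]]$pct) - 100), 0.1 * nrow(s[[blk]]))
  }
})

test_that("an empty cohort summarizes to all-zero counts and percentages", {
  demo <- full_demo(character(), character(), character())
  s <- summarize_demographics(demo)
  expect_equal(s$n_reports, 0L)
  expect_true(all(s$sex$n == 0L))
  expect_true(all(s$sex$pct == 0))
})

test_that("age and weight bin boundaries follow the documented policy", {
  demo <- full_demo(as.character(1:6), as.character(1:6), "20230101",
                    age_yr = c(17.9, 18, 64.9, 65, 85, NA),
                    wt_kg = c(49.9, 50, 100, 100.1, NA, NA))
  s <- summarize_demographics(demo)
  expect_equal(s$age[category == "<18", n], 1L)
  expect_equal(s$age[category == "18-64.9", n], 2L)
  expect_equal(s$age[category == "65-85", n], 1L)   # [65, 85): 85 is above
  expect_equal(s$age[category == ">85", n], 1L)
  expect_equal(s$weight[category == "<50 kg", n], 1L)
  expect_equal(s$weight[category == "50-100 kg", n], 2L)
  expect_equal(s$weight[category == ">100 kg", n], 1L)
})

test_that("multi-outcome reports count once, under the most serious code", {
  demo <- full_demo("11", "1", "20230101")
  outc <- data.table(primaryid = c("11", "11"), outc_cod = c("HO", "DE"))
  s <- summarize_demographics(demo, outcomes = outc)
  expect_equal(s$outcome[category == "Death", n], 1L)
  expect_equal(sum(s$outcome$n), 1L)
})

test_that("annual distribution matches ground-truth survivor receipt years", {
  cfg <- tiny_config(seed = 8, n_reports = 3000)
  cfg$n_quarters <- 6L  # spans 2013 Q3 - 2014 Q4
  gen <- gen_tmp(cfg)
  demo <- read_faers_quarters(gen$dir)$tables$DEMO
  surv <- deduplicate(demo)
  ann <- annual_distribution(demo[primaryid %in% surv])
  gt_years <- gen$ground_truth$lineage[survivor == TRUE,
                                       as.integer(substr(fda_dt, 1, 4))]
  expected <- as.data.table(table(gt_years))
  expect_equal(ann$year, sort(unique(gt_years)))
  expect_equal(ann$n, expected$N)
  expect_equal(sum(ann$n), length(surv))
})

test_that("time to onset: single-report arithmetic and exclusion of negatives", {
  demo <- full_demo(c("11", "21"), c("1", "2"), "20230301",
                    event_dt = c("20230108", "20221220"))
  drug <- rbind(drug_row("11"), drug_row("21"))
  ther <- data.table(primaryid = c("11", "21"), dsg_drug_seq = 1L,
                     start_dt = c("20230101", "20230101"))
  reac <- rbind(reac_row("11", "Nausea"), reac_row("21", "Nausea"))
  coh <- build_cohort(mini_tables(demo, drug, reac, ther = ther))
  tto <- time_to_onset(coh)
  expect_equal(tto$n_evaluable, 1L)     # event before start is excluded
  expect_equal(tto$n_excluded, 1L)
  expect_equal(tto$median_days, 7)
  expect_equal(tto$n_evaluable + tto$n_excluded, nrow(coh$demo))
})

test_that("the generator's log-normal onset profile is recovered at scale", {
  cfg <- synthetic_config(n_reports = 10000, n_quarters = 2,
                          exposed_fraction = 0.5, missing_date_frac = 0,
                          duplicate_fraction = 0, seed = 10)
  gen <- gen_tmp(cfg)
  coh <- build_cohort(read_faers_quarters(gen$dir)$tables)
  tto <- time_to_onset(coh)
  expect_gt(tto$n_evaluable, 3000)
  expect_true(abs(tto$median_days - 7) <= 1)
  expect_equal(tto$n_evaluable + tto$n_excluded, nrow(coh$demo))
  expect_equal(sum(tto$histogram$n), tto$n_evaluable)
})
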