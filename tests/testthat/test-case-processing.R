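test_that("the later receipt date survives; ties fall to the higher primaryid", {
  s <- deduplicate(demo_rows(c("1", "2"), "X", c("20230101", "20230301")))
  expect_equal(as.character(s), "2")
  s <- deduplicate(demo_rows(c("5", "9"), "X", c("20230301", "20230301")))
  expect_equal(as.character(s), "9")
  # numeric comparison when ids parse: "10" beats "9"
  s <- deduplicate(demo_rows(c("9", "10"), "X", c("20230301", "20230301")))
  expect_equal(as.character(s), "10")
  # lexicographic fallback when an id does not parse
  s <- deduplicate(demo_rows(c("A9", "A10"), "X", c("20230301", "20230301")))
  expect_equal(as.character(s), "A9")
})

test_that("all-distinct caseids pass through dedup unchanged", {
  d <- demo_rows(as.character(101:110), as.character(1:10), "20230101")
  expect_setequal(as.character(deduplicate(d)), d$primaryid)
})

test_that("partial receipt dates defer to fully dated siblings, else use period-end", {
  # sibling with a full date: partial version is dropped from ordering
  s <- deduplicate(demo_rows(c("1", "2"), "X", c("20231230", "2023")))
  expect_equal(as.character(s), "1")
  excl <- attr(s, "excluded")
  expect_equal(excl$primaryid, "2")
  # no full date anywhere: period-end completion orders YYYY (Dec 31)
  # above YYYYMM (Jun 30)
  s <- deduplicate(demo_rows(c("1", "2"), "X", c("202306", "2023")))
  expect_equal(as.character(s), "2")
  # missing fda_dt is excluded and logged
  s <- deduplicate(demo_rows(c("1", "2"), "X", c("20230101", "")))
  expect_equal(as.character(s), "1")
  expect_match(attr(s, "excluded")$reason, "missing")
})

test_that("dedup is idempotent and matches generator ground truth", {
  for (seed in 1:3) {
    gen <- gen_tmp(tiny_config(seed = seed))
    demo <- read_faers_quarters(gen$dir)$tables$DEMO
    s1 <- deduplicate(demo)
    expect_setequal(as.character(s1),
                    gen$ground_truth$lineage[survivor == TRUE, primaryid])
    s2 <- deduplicate(demo[primaryid %in% s1])
    expect_setequal(as.character(s2), as.character(s1))
  }
})

test_that("target matching is normalized containment plus the role filter", {
  cfg <- cohort_config()
  expect_true(match_target(drug_row("1", drugname = "TRINTELLIX"), cfg))
  expect_false(match_target(
    drug_row("1", role_cod = "SS", drugname = "x", prod_ai = "vortioxetine"), cfg))
  expect_true(match_target(
    drug_row("1", drugname = "vortioxetine hydrobromide"), cfg))
  expect_true(match_target(
    drug_row("1", drugname = "  Vortioxetine   HYDROBROMIDE 10MG "), cfg))
  expect_false(match_target(drug_row("1", drugname = "SERTRALINE"), cfg))
  expect_error(match_target(drug_row("1")[0], cfg), "no drug rows")
})

test_that("indication PTs are stripped from reaction lists with counts reconciling", {
  cfg <- cohort_config(indication_exclusion_pts = "depression")
  reac <- rbind(reac_row("1", "Nausea"), reac_row("1", "Depression"),
                reac_row("2", "Depression"))
  out <- exclude_indications(reac, cfg)
  expect_equal(out$pt, "Nausea")
  expect_equal(attr(out, "removed")$n_removed, 2L)
  expect_equal(nrow(out) + sum(attr(out, "removed")$n_removed), nrow(reac))
  # empty exclusion list is the identity
  out2 <- exclude_indications(reac, cohort_config(indication_exclusion_pts = character()))
  expect_equal(nrow(out2), 3L)
})

test_that("a report whose only PT is excluded stays in demographics, not events", {
  demo <- full_demo(c("11", "21", "31"), c("1", "2", "3"),
                    rep("20230101", 3))
  drug <- rbind(drug_row("11"), drug_row("21"),
                drug_row("31", drugname = "OTHER"))
  reac <- rbind(reac_row("11", "Nausea"), reac_row("21", "Depression"),
                reac_row("31", "Nausea"))
  coh <- build_cohort(mini_tables(demo, drug, reac), cohort_config())
  expect_equal(coh$log$cohort_reports, 2L)
  expect_equal(coh$log$cohort_reports_with_events, 1L)
  expect_equal(nrow(coh$demo), 2L)           # report 21 kept for demographics
  expect_equal(unique(coh$reactions$primaryid), "11")
})

test_that("cohort size is monotone non-increasing through the filters", {
  gen <- gen_tmp(tiny_config(seed = 9, n_reports = 2000))
  coh <- build_cohort(read_faers_quarters(gen$dir)$tables)
  l <- coh$log
  expect_true(l$demo_rows >= l$deduplicated)
  expect_true(l$deduplicated >= l$cohort_reports)
  expect_true(l$cohort_reports >= l$cohort_reports_with_events)
})

test_that("cohort membership agrees with generator exposure ground truth", {
  gen <- gen_tmp(tiny_config(seed = 4, n_reports = 2000))
  ing <- read_faers_quarters(gen$dir)
  coh <- build_cohort(ing$tables)
  gt <- gen$ground_truth
  surv <- gt$lineage[survivor == TRUE]
  expected <- surv[gt$exposed[exposed == TRUE], on = "caseid", nomatch = NULL]
  expect_setequal(coh$demo$primaryid, expected$primaryid)
})
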