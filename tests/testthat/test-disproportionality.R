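test_that("independence tables give the null value of every statistic exactly", {
  # a/N == (a+b)(a+c)/N^2 holds for (1,9,9,81)
  t <- c(1, 9, 9, 81)
  expect_identical(ror(t)$ror, 1)
  expect_lt(ror(t)$ror_ci_low, 1)
  expect_gt(ror(t)$ror_ci_high, 1)
  expect_identical(prr_chi2(t)$prr, 1)
  expect_identical(prr_chi2(t)$chi2, 0)
  expect_identical(bcpnn_ic(t)$ic, 0)
  expect_identical(mgps_ebgm(t)$ebgm, 1)
})

test_that("hand-arithmetic oracle values are reproduced", {
  # ROR for (20,10,10,20): 4 with SE sqrt(0.3) on the log scale
  r <- ror(c(20, 10, 10, 20))
  expect_equal(r$ror, 4)
  expect_equal(r$ror_ci_low, 4 * exp(-1.96 * sqrt(0.3)), tolerance = 1e-12)
  expect_equal(r$ror_ci_low, 1.36725, tolerance = 1e-4)
  expect_equal(r$ror_ci_high, 11.70227, tolerance = 1e-4)

  # (20,80,10,890): PRR = 20*900/(10*100), chi2 = 17000^2*1000/(100*900*30*970)
  p <- prr_chi2(c(20, 80, 10, 890))
  expect_equal(p$prr, 18)
  expect_equal(p$chi2, 110.34746, tolerance = 1e-4)

  e <- mgps_ebgm(c(20, 80, 10, 890))
  expect_equal(e$ebgm, 20000 / 3000, tolerance = 1e-12)
  i <- bcpnn_ic(c(20, 80, 10, 890))
  expect_equal(i$ic, 2.73697, tolerance = 1e-4)
})

test_that("chi-squared matches an independent Pearson implementation on random tables", {
  tabs <- random_tables(200, seed = 7)
  ours <- prr_chi2(tabs)$chi2
  oracle <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(as.numeric(tabs[i, c(a, b, c, d)]), 2, byrow = TRUE)
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
  }, numeric(1))
  expect_lt(max(abs(ours - oracle) / pmax(oracle, 1e-300)), 1e-9)
})

test_that("IC equals log2(EBGM) identically", {
  tabs <- random_tables(100, seed = 2)
  expect_equal(bcpnn_ic(tabs)$ic, log2(mgps_ebgm(tabs)$ebgm),
               tolerance = 1e-12)
})

test_that("all four point estimates increase strictly in a with margins fixed", {
  # N = 2000, a+b = 100, a+c = 60; vary a
  a <- 1:59
  tabs <- data.table(a = a, b = 100 - a, c = 60 - a, d = 2000 - 160 + a)
  est <- cbind(ror(tabs)$ror, prr_chi2(tabs)$prr,
               bcpnn_ic(tabs)$ic, mgps_ebgm(tabs)$ebgm)
  for (j in 1:4) expect_true(all(diff(est[, j]) > 0))
})

test_that("ROR approximates PRR for rare events", {
  set.seed(3)
  tabs <- data.table(a = sample(3:30, 50, TRUE), b = sample(2000:6000, 50, TRUE),
                     c = sample(30:300, 50, TRUE), d = sample(50000:150000, 50, TRUE))
  r <- ror(tabs)$ror
  p <- prr_chi2(tabs)$prr
  expect_lt(max(abs(r - p) / p), 0.05)
})

test_that("zero cells leave statistics undefined unless Haldane-corrected", {
  t0 <- c(0, 10, 5, 100)
  expect_true(is.na(ror(t0)$ror))
  expect_true(is.na(bcpnn_ic(t0)$ic))
  expect_true(is.na(mgps_ebgm(t0)$ebgm))
  expect_true(is.finite(ror(t0, zero_correction = "haldane")$ror))
  expect_true(is.finite(bcpnn_ic(t0, zero_correction = "haldane")$ic))
  # prr defined when only b = 0
  expect_equal(prr_chi2(c(5, 0, 5, 100))$prr, 5 * 105 / (5 * 5))
})

test_that("fixed-offset IC mode subtracts a constant kappa", {
  t <- c(20, 80, 10, 890)
  i <- bcpnn_ic(t, variance = "fixed", kappa = 1.66)
  expect_equal(i$ic025, i$ic - 1.66)
})

test_that("signal flags implement the four criteria and their conjunction", {
  mk <- function(n, ror_ci_low = 1.2, prr = 2.5, chi2 = 10, ic025 = 0.3,
                 ebgm05 = 2.1) {
    data.table(n = n, ror_ci_low = ror_ci_low, prr = prr, chi2 = chi2,
               ic025 = ic025, ebgm05 = ebgm05)
  }
  f <- flag_signals(mk(5))
  expect_true(f$consensus)
  f <- flag_signals(mk(5, ebgm05 = 1.5))
  expect_false(f$mgps_pos)
  expect_false(f$consensus)
  expect_true(f$ror_pos && f$prr_pos && f$bcpnn_pos)
  # huge ROR cannot rescue n < 3
  f <- flag_signals(mk(2, ror_ci_low = 50))
  expect_false(f$ror_pos)
  # undefined statistics fail their flags
  f <- flag_signals(mk(5, ror_ci_low = NA_real_, ic025 = NA_real_))
  expect_false(f$ror_pos)
  expect_false(f$bcpnn_pos)
})

test_that("contingency tables are exact on a fully enumerable universe", {
  # two deduplicated reports, one in the cohort with a single PT
  demo <- full_demo(c("11", "21"), c("1", "2"), c("20230101", "20230102"))
  drug <- rbind(drug_row("11"), drug_row("21", drugname = "OTHER DRUG"))
  reac <- rbind(reac_row("11", "Nausea"), reac_row("21", "Headache"))
  coh <- build_cohort(mini_tables(demo, drug, reac), cohort_config())
  dict <- make_dictionary(synthetic_config(n_reports = 0, pt_vocabulary = data.table(
    pt = c("Nausea", "Headache"),
    soc = c("Gastrointestinal disorders", "Nervous system disorders"))))
  tab <- build_tables(coh, dict, level = "PT")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$a, 1L)
  expect_equal(tab$b, 0L)
  expect_equal(tab$c, 0L)
  expect_equal(tab$d, 1L)
  expect_equal(tab[, a + b + c + d], 2L)
})

test_that("a report's PTs sharing a SOC contribute once to that SOC's a", {
  demo <- full_demo(c("11", "21"), c("1", "2"), c("20230101", "20230102"))
  drug <- rbind(drug_row("11"), drug_row("21", drugname = "OTHER DRUG"))
  reac <- rbind(reac_row("11", "Nausea"), reac_row("11", "Vomiting"),
                reac_row("21", "Nausea"))
  coh <- build_cohort(mini_tables(demo, drug, reac), cohort_config())
  dict <- make_dictionary(synthetic_config(n_reports = 0, pt_vocabulary = data.table(
    pt = c("Nausea", "Vomiting"),
    soc = rep("Gastrointestinal disorders", 2))))
  tab <- build_tables(coh, dict, level = "SOC")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$a, 1L)
  expect_equal(tab$c, 1L)
})

test_that("with all rates null, EBGM stays near 1 across a synthetic run", {
  cfg <- tiny_config(seed = 5, n_reports = 8000)
  gen <- gen_tmp(cfg)
  ing <- read_faers_quarters(gen$dir)
  coh <- build_cohort(ing$tables)
  dict <- make_dictionary(cfg)
  tab <- build_tables(coh, dict, level = "PT")
  sig <- compute_signals(tab)
  ok <- sig[!is.na(ebgm) & n >= 3]
  # |log EBGM| within 3 delta-method SEs of 0 for nearly all null PTs
  z <- abs(log(ok$ebgm)) / sqrt(1 / ok$a + 1 / ok$b + 1 / ok$c + 1 / ok$d)
  expect_gt(mean(z < 3), 0.95)
})

test_that("formatted signal tables round half-up to two decimals", {
  stats <- compute_signals(data.table(
    level = "PT", event_name = "x", event_code = "1", a = 20, b = 80,
    c = 10, d = 890, n = 20))
  out <- format_signal_table(stats)
  expect_match(out$prr_chi2, "^18.00 \\(110.35\\)$")
  expect_match(out$ebgm_ebgm05, "^6.67 \\(")
})
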