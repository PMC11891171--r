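write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a header-only file yields empty records and empty rejects", {
  path <- write_lines_tmp("primaryid$caseid$fda_dt$sex")
  out <- read_faers_table(path, "DEMO")
  expect_equal(nrow(out$records), 0L)
  expect_equal(nrow(out$rejects), 0L)
})

test_that("unknown sex codes map to missing without rejecting the row", {
  path <- write_lines_tmp(c("primaryid$caseid$fda_dt$sex",
                            "101$1$20230105$U",
                            "102$2$20230106$F"))
  out <- read_faers_table(path, "DEMO")
  expect_equal(nrow(out$records), 2L)
  expect_equal(nrow(out$rejects), 0L)
  expect_true(is.na(out$records$sex[1]))
  expect_equal(out$records$sex[2], "F")
})

test_that("wrong field counts and invalid values are quarantined, with conservation", {
  path <- write_lines_tmp(c("primaryid$caseid$fda_dt",
                            "101$1$20230105",
                            "102$2",                 # short row
                            "103$3$20231345",        # impossible date
                            "104$4$20230110$extra")) # long row
  out <- read_faers_table(path, "DEMO")
  expect_equal(nrow(out$records), 1L)
  expect_equal(nrow(out$rejects), 3L)
  expect_equal(nrow(out$records) + nrow(out$rejects), 4L)
  expect_setequal(out$rejects$line, c(3L, 4L, 5L))
  expect_match(out$rejects[line == 4L, reason], "calendar")
})

test_that("column order comes from the header, not position", {
  path <- write_lines_tmp(c("sex$fda_dt$caseid$primaryid",
                            "F$20230105$1$101"))
  out <- read_faers_table(path, "DEMO")
  expect_equal(out$records$primaryid, "101")
  expect_equal(out$records$caseid, "1")
  expect_equal(out$records$sex, "F")
})

test_that("missing mandatory columns and unknown table kinds error", {
  path <- write_lines_tmp(c("primaryid$fda_dt", "101$20230105"))
  expect_error(read_faers_table(path, "DEMO"), "caseid")
  expect_error(read_faers_table(path, "NOPE"), "unknown table_kind")
})

test_that("age-unit codes normalize to years; unknown units go missing", {
  path <- write_lines_tmp(c("primaryid$caseid$fda_dt$age$age_cod",
                            "101$1$20230105$45$YR",
                            "102$2$20230105$4.5$DEC",
                            "103$3$20230105$18$MON",
                            "104$4$20230105$45$XX"))
  out <- read_faers_table(path, "DEMO")
  expect_equal(out$records$age_yr, c(45, 45, 1.5, NA))
})

test_that("DRUG rows with role codes outside PS/SS/C/I are rejected", {
  path <- write_lines_tmp(c("primaryid$drug_seq$role_cod$drugname",
                            "101$1$PS$VORTIOXETINE",
                            "102$1$XX$SOMETHING"))
  out <- read_faers_table(path, "DRUG")
  expect_equal(nrow(out$records), 1L)
  expect_match(out$rejects$reason, "role code")
})

test_that("read-write-read round-trips generated data exactly", {
  gen <- gen_tmp(tiny_config(seed = 3, n_reports = 400))
  for (kind in c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")) {
    src <- list.files(gen$dir, pattern = paste0("^", kind, ".*txt$"),
                      full.names = TRUE)[1]
    first <- read_faers_table(src, kind)
    tmp <- withr::local_tempfile(fileext = ".txt")
    write_faers_table(first$records, tmp, kind)
    second <- read_faers_table(tmp, kind)
    expect_equal(second$records, first$records, ignore_attr = TRUE)
    expect_equal(nrow(second$rejects), 0L)
  }
})

test_that("latin-1 encoded files fall back without loss", {
  path <- withr::local_tempfile(fileext = ".txt")
  con <- file(path, open = "wb")
  writeLines(c("primaryid$caseid$fda_dt$reporter_country",
               "101$1$20230105$C\xf4te d'Ivoire"), con, useBytes = TRUE)
  close(con)
  out <- read_faers_table(path, "DEMO")
  expect_equal(nrow(out$records), 1L)
  expect_match(out$records$reporter_country, "^C.te d'Ivoire$")
})

test_that("concatenating quarters preserves rows and provenance", {
  q1 <- write_lines_tmp(c("primaryid$caseid$fda_dt",
                          paste0(100 + 1:10, "$", 1:10, "$20230105")))
  q2 <- write_lines_tmp(c("primaryid$caseid$fda_dt",
                          paste0(200 + 1:20, "$", 10 + 1:20, "$20230405")))
  parsed <- list(read_faers_table(q1, "DEMO"), read_faers_table(q2, "DEMO"))
  out <- concat_quarters(parsed, c("23Q1", "23Q2"))
  expect_equal(nrow(out$tables$DEMO), 30L)
  expect_equal(out$tables$DEMO[, .N, by = quarter]$N, c(10L, 20L))
})

test_that("a caseid recurring across quarters is kept twice before dedup", {
  q1 <- write_lines_tmp(c("primaryid$caseid$fda_dt", "1011$7$20230105"))
  q2 <- write_lines_tmp(c("primaryid$caseid$fda_dt", "1012$7$20230405"))
  parsed <- list(read_faers_table(q1, "DEMO"), read_faers_table(q2, "DEMO"))
  out <- concat_quarters(parsed, c("23Q1", "23Q2"))
  expect_equal(nrow(out$tables$DEMO), 2L)
  expect_equal(unique(out$tables$DEMO$caseid), "7")
})

test_that("inconsistent headers across quarters for one table error out", {
  q1 <- write_lines_tmp(c("primaryid$caseid$fda_dt", "1011$7$20230105"))
  q2 <- write_lines_tmp(c("primaryid$caseid$fda_dt$sex", "1012$8$20230405$F"))
  parsed <- list(read_faers_table(q1, "DEMO"), read_faers_table(q2, "DEMO"))
  expect_error(concat_quarters(parsed, c("23Q1", "23Q2")), "inconsistent headers")
})
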