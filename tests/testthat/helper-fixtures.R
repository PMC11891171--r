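library(data.table)

# Small generator config for fast tests.
tiny_config <- function(seed = 1L, n_reports = 800L, ...) {
  synthetic_config(n_reports = n_reports, n_quarters = 2L, seed = seed,
                   duplicate_fraction = 0.10, tie_fraction = 0.3, ...)
}

gen_tmp <- function(config) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  generate_faers(config, dir)
}

# Hand-built DEMO records for dedup tests.
demo_rows <- function(primaryid, caseid, fda_dt) {
  data.table(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt))
}

# Minimal table set for one-report-at-a-time cohort tests.
mini_tables <- function(demo, drug, reac, ther = NULL, outc = NULL) {
  out <- list(DEMO = demo, DRUG = drug, REAC = reac)
  if (!is.null(ther)) out$THER <- ther
  if (!is.null(outc)) out$OUTC <- outc
  out
}

full_demo <- function(primaryid, caseid, fda_dt, event_dt = "",
                      sex = NA_character_, age_yr = NA_real_,
                      wt_kg = NA_real_, occp_cod = NA_character_,
                      country = NA_character_) {
  data.table(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt),
             event_dt = as.character(event_dt),
             sex = sex, age_yr = age_yr, wt_kg = wt_kg,
             occp_cod = occp_cod, reporter_country = country)
}

drug_row <- function(primaryid, drug_seq = 1L, role_cod = "PS",
                     drugname = "VORTIOXETINE", prod_ai = "") {
  data.table(primaryid = as.character(primaryid), drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname, prod_ai = prod_ai)
}

reac_row <- function(primaryid, pt) {
  data.table(primaryid = as.character(primaryid), pt = pt,
             pt_norm = tolower(pt))
}

# Random strictly-positive 2x2 tables for property checks.
random_tables <- function(n, seed = 1, max_cell = 500L) {
  set.seed(seed)
  data.table(a = sample.int(max_cell, n, TRUE),
             b = sample.int(max_cell, n, TRUE),
             c = sample.int(max_cell, n, TRUE),
             d = sample.int(max_cell, n, TRUE))
}
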