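#' Demographic and clinical summary of a cohort
#'
#' Reproduces the layout of the standard report-characteristics table:
#' sex, age bins, weight bins, reporter occupation, top reporting
#' countries, and outcomes. Every breakdown partitions the cohort (each
#' report lands in exactly one bin, missing included), counts sum to the
#' cohort size, and percentages are computed against the full cohort size
#' with [pct_of()] (1 decimal, half-up).
#'
#' Bin boundaries: age <18, [18, 65), [65, 85), >= 85 years (age-unit codes
#' normalized to years upstream); weight <50, [50, 100], >100 kg. A report
#' with several outcome codes is counted once under its most serious
#' outcome (death > life-threatening > hospitalization > disability >
#' congenital anomaly > required intervention > other); reports with no
#' outcome row are "missing".
#'
#' @param cohort a \code{faers_cohort} from [build_cohort()], or a
#'   data.table of DEMO records (then \code{outcomes} may be supplied
#'   separately).
#' @param outcomes optional OUTC data.table when \code{cohort} is a plain
#'   DEMO table.
#' @param top_countries how many countries to list individually (default
#'   3); the rest are pooled as "Other".
#' @return list of class \code{demographics_summary}: data.tables
#'   \code{sex}, \code{age}, \code{weight}, \code{reporter},
#'   \code{country}, \code{outcome}, each with \code{category}, \code{n},
#'   \code{pct}; plus \code{n_reports}.
#' @export
summarize_demographics <- function(cohort, outcomes = NULL,
                                   top_countries = 3L) {
  if (inherits(cohort, "faers_cohort")) {
    demo <- cohort$demo
    outcomes <- cohort$outcomes
  } else {
    demo <- as.data.table(cohort)
  }
  n_total <- nrow(demo)
  brk <- function(categories, values) {
    counts <- as.integer(table(factor(values, levels = categories)))
    data.table(category = categories, n = counts,
               pct = pct_of(counts, n_total))
  }

  sex_cat <- fifelse(is.na(demo$sex), "Missing",
              fifelse(demo$sex == "F", "Female", "Male"))
  sex <- brk(c("Female", "Male", "Missing"), sex_cat)

  age <- demo$age_yr
  age_cat <- fifelse(is.na(age), "Missing",
              fifelse(age < 18, "<18",
               fifelse(age < 65, "18-64.9",
                fifelse(age < 85, "65-85", ">85"))))
  age_tab <- brk(c("<18", "18-64.9", "65-85", ">85", "Missing"), age_cat)

  wt <- demo$wt_kg
  wt_cat <- fifelse(is.na(wt), "Missing",
             fifelse(wt < 50, "<50 kg",
              fifelse(wt <= 100, "50-100 kg", ">100 kg")))
  wt_tab <- brk(c("<50 kg", "50-100 kg", ">100 kg", "Missing"), wt_cat)

  occ_labels <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                  HP = "Health Professional", OT = "Other health-professional")
  occ_cat <- occ_labels[demo$occp_cod]
  occ_cat[is.na(occ_cat)] <- "Missing"
  reporter <- brk(c("Consumer", "Physician", "Health Professional",
                    "Pharmacist", "Other health-professional", "Missing"),
                  unname(occ_cat))

  ctry <- demo$reporter_country
  ctry[is.na(ctry)] <- "Missing"
  top <- demo[!is.na(reporter_country), .N, by = reporter_country][
    order(-N, reporter_country)]
  top_names <- head(top$reporter_country, top_countries)
  ctry_cat <- fifelse(ctry %in% c(top_names, "Missing"), ctry, "Other")
  country <- brk(c(top_names, "Other", "Missing"), ctry_cat)

  out_sev <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
  out_labels <- c(DE = "Death", LT = "Life-Threatening",
                  HO = "Hospitalization - Initial or Prolonged",
                  DS = "Disability", CA = "Congenital Anomaly",
                  RI = "Required Intervention",
                  OT = "Other Serious (Important Medical Event)")
  if (!is.null(outcomes) && nrow(outcomes)) {
    oc <- as.data.table(outcomes)[primaryid %in% demo$primaryid]
    oc[, rank := match(outc_cod, out_sev)]
    worst <- oc[, .(outc_cod = outc_cod[which.min(rank)]), by = primaryid]
    out_cat <- out_labels[worst$outc_cod[match(demo$primaryid, worst$primaryid)]]
  } else {
    out_cat <- rep(NA_character_, n_total)
  }
  out_cat[is.na(out_cat)] <- "Missing"
  outcome <- brk(c(unname(out_labels), "Missing"), unname(out_cat))

  structure(list(n_reports = n_total, sex = sex, age = age_tab,
                 weight = wt_tab, reporter = reporter, country = country,
                 outcome = outcome),
            class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d reports\n", x$n_reports))
  for (blk in c("sex", "age", "weight", "reporter", "country", "outcome")) {
    cat("--", blk, "--\n")
    print(x[[blk]], row.names = FALSE)
  }
  invisible(x)
}

#' Annual distribution of reports
#'
#' Counts deduplicated reports by receipt year (the year component of
#' \code{fda_dt}). Reports whose receipt date yields no year are counted
#' in the \code{"unparseable"} attribute; the yearly counts sum to the
#' cohort size minus those.
#'
#' @param cohort a \code{faers_cohort} or a DEMO data.table.
#' @return data.table with \code{year} (integer, ascending) and \code{n}.
#' @export
annual_distribution <- function(cohort) {
  demo <- if (inherits(cohort, "faers_cohort")) cohort$demo else as.data.table(cohort)
  yr <- suppressWarnings(as.integer(substr(trimws(demo$fda_dt), 1, 4)))
  ok <- !is.na(yr) & grepl("^[0-9]{4}", trimws(demo$fda_dt))
  out <- data.table(year = yr[ok])[, .(n = .N), by = year][order(year)]
  setattr(out, "unparseable", sum(!ok))
  out[]
}

#' Time-to-onset analysis
#'
#' Time to onset (TTO) is the event date minus the earliest therapy start
#' date of the report's target-drug rows, in days. Reports with a missing
#' or partial date on either side, no matched therapy row, or a negative
#' difference (event before therapy start — an inaccurate report) are
#' excluded and counted; evaluable + excluded equals the cohort size.
#' Quantiles use linear interpolation (type 7); "within the first month"
#' means TTO <= 30 days.
#'
#' @param cohort a \code{faers_cohort} from [build_cohort()] (needs
#'   \code{therapy} rows and the \code{is_target} drug flags).
#' @param breaks histogram interval edges in days (right-closed).
#' @return list of class \code{tto_summary}: \code{n_evaluable},
#'   \code{n_excluded}, \code{median_days}, \code{q1}, \code{q3},
#'   \code{frac_within_30d}, \code{histogram} (interval, n), \code{tto}
#'   (the evaluable TTO vector).
#' @export
time_to_onset <- function(cohort, breaks = c(0, 30, 60, 90, 180, 360, Inf)) {
  stopifnot(inherits(cohort, "faers_cohort"))
  demo <- cohort$demo
  n_total <- nrow(demo)
  if (is.null(cohort$therapy) || n_total == 0L) {
    return(empty_tto(n_total))
  }
  target_seq <- as.data.table(cohort$drugs)[is_target == TRUE,
                                            .(primaryid, drug_seq)]
  ther <- merge(as.data.table(cohort$therapy),
                target_seq, by.x = c("primaryid", "dsg_drug_seq"),
                by.y = c("primaryid", "drug_seq"))
  ther <- ther[date_kind(start_dt) == "full"]
  starts <- ther[, .(start = min(parse_date8(start_dt))), by = primaryid]

  ev <- demo[, .(primaryid, event_dt)]
  ev <- ev[date_kind(event_dt) == "full"]
  ev[, event := parse_date8(event_dt)]

  joined <- merge(ev[, .(primaryid, event)], starts, by = "primaryid")
  joined[, tto := as.numeric(event - start)]
  evaluable <- joined[tto >= 0]
  tto <- evaluable$tto
  if (length(tto) == 0L) return(empty_tto(n_total))

  q <- unname(quantile(tto, c(0.25, 0.5, 0.75), type = 7))
  hist_tab <- data.table(
    interval = interval_labels(breaks),
    n = as.integer(table(cut(tto, breaks = breaks, include.lowest = TRUE,
                             right = TRUE)))
  )
  structure(list(n_evaluable = length(tto),
                 n_excluded = n_total - length(tto),
                 median_days = q[2], q1 = q[1], q3 = q[3],
                 frac_within_30d = mean(tto <= 30),
                 histogram = hist_tab, tto = tto),
            class = "tto_summary")
}

empty_tto <- function(n_total) {
  structure(list(n_evaluable = 0L, n_excluded = n_total,
                 median_days = NA_real_, q1 = NA_real_, q3 = NA_real_,
                 frac_within_30d = NA_real_,
                 histogram = data.table(interval = character(), n = integer()),
                 tto = numeric(), empty = TRUE),
            class = "tto_summary")
}

interval_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  ifelse(is.infinite(hi), sprintf("> %g d", lo),
         sprintf("%g-%g d", lo, hi))
}

#' @export
print.tto_summary <- function(x, ...) {
  if (x$n_evaluable == 0L) {
    cat("Time to onset: no evaluable reports\n")
    return(invisible(x))
  }
  cat(sprintf("Time to onset: n=%d evaluable (%d excluded)\n",
              x$n_evaluable, x$n_excluded))
  cat(sprintf("  median %g days [IQR %g-%g]; %.1f%% within 30 days\n",
              x$median_days, x$q1, x$q3, 100 * x$frac_within_30d))
  invisible(x)
}
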