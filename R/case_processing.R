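#' Cohort configuration
#'
#' Describes how the analysis cohort is assembled from deduplicated
#' reports: which drug-name spellings identify the target drug, which drug
#' role is required, and which reaction PTs are removed as likely
#' indications rather than adverse events.
#'
#' @param target_names spellings matched (case-insensitively, by substring
#'   containment after whitespace normalization) against \code{drugname}
#'   and \code{prod_ai}. Containment is used because verbatim FAERS names
#'   carry salts and strengths ("VORTIOXETINE HYDROBROMIDE 10MG").
#' @param required_role drug role code the matching row must carry
#'   (default \code{"PS"}, primary suspect).
#' @param indication_exclusion_pts reaction PTs removed from the cohort's
#'   event lists because they name the treated condition, not a reaction.
#'   The default covers the depressive-disorder terms a vortioxetine-style
#'   cohort would exclude; override for other drugs.
#' @param date_window optional character vector \code{c(first, last)} of
#'   quarter labels (e.g. \code{"13Q3"}) restricting the analysis window.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(target_names = c("trintellix", "vortioxetine"),
                          required_role = "PS",
                          indication_exclusion_pts = c(
                            "major depressive disorder", "depression",
                            "depressive symptom"),
                          date_window = NULL) {
  if (length(target_names) == 0L || !all(nzchar(target_names))) {
    stop("target_names must be non-empty")
  }
  if (!required_role %in% .role_codes) {
    stop("required_role must be one of ", paste(.role_codes, collapse = "/"))
  }
  structure(list(target_names = target_names,
                 required_role = required_role,
                 indication_exclusion_pts = indication_exclusion_pts,
                 date_window = date_window),
            class = "cohort_config")
}

#' Deduplicate case versions by the FDA rule
#'
#' FAERS carries several versions of the same case (one per submission);
#' the recommended reduction keeps, within each \code{caseid}, the version
#' with the most recent \code{fda_dt}, breaking receipt-date ties by the
#' highest \code{primaryid}. PRIMARYIDs are compared numerically when every
#' version's id parses as a number, lexicographically otherwise.
#'
#' Partial receipt dates (YYYY or YYYYMM) are handled conservatively: a
#' partially dated version is dropped from the ordering only when a sibling
#' version has a complete date; if no version of the case has one, partial
#' dates are completed to their period end for ordering. Versions with a
#' missing or invalid \code{fda_dt} are excluded and logged.
#'
#' @param demo data.frame/data.table of DEMO records with columns
#'   \code{primaryid}, \code{caseid}, \code{fda_dt}.
#' @return character vector of surviving primaryids (one per caseid), with
#'   attribute \code{"excluded"}: a data.table of versions removed before
#'   ordering (\code{primaryid}, \code{caseid}, \code{reason}).
#' @export
deduplicate <- function(demo) {
  dt <- as.data.table(demo)[, .(primaryid, caseid, fda_dt)]
  dt[, kind := date_kind(fda_dt)]
  excluded <- dt[kind %in% c("missing", "invalid"),
                 .(primaryid, caseid, reason = paste0(kind, " fda_dt"))]
  dt <- dt[kind %in% c("full", "partial")]
  if (nrow(dt) == 0L) {
    out <- character()
    attr(out, "excluded") <- excluded
    return(out)
  }
  dt[, ord_key := date_order_key(fda_dt)]
  dt[, has_full := any(kind == "full"), by = caseid]
  dropped_partial <- dt[has_full & kind == "partial",
                        .(primaryid, caseid,
                          reason = "partial fda_dt with fully dated sibling")]
  dt <- dt[!(has_full & kind == "partial")]
  # primaryid comparison: numeric when every candidate in the case parses
  dt[, pid_num := suppressWarnings(as.numeric(primaryid))]
  dt[, all_num := !anyNA(pid_num), by = caseid]
  survivors <- dt[, {
    o <- if (all_num[1]) order(ord_key, pid_num) else order(ord_key, primaryid)
    .(primaryid = primaryid[o[.N]])
  }, by = caseid]
  out <- survivors$primaryid
  attr(out, "excluded") <- rbind(excluded, dropped_partial)
  out
}

# Row-level target match: role + normalized-containment name match.
match_target_rows <- function(drug_dt, config) {
  targets <- normalize_name(config$target_names)
  dn <- normalize_name(drug_dt$drugname)
  ai <- normalize_name(drug_dt$prod_ai)
  hit <- rep(FALSE, nrow(drug_dt))
  for (t in targets) {
    hit <- hit | grepl(t, dn, fixed = TRUE) | grepl(t, ai, fixed = TRUE)
  }
  hit & drug_dt$role_cod == config$required_role
}

#' Does a report match the target drug?
#'
#' True iff at least one drug row's \code{drugname} or \code{prod_ai}
#' contains a target name (after trimming, case-folding and collapsing
#' internal whitespace) \emph{and} that row carries the required role code.
#'
#' @param drugs data.frame/data.table of the report's drug rows
#'   (\code{drugname}, \code{prod_ai}, \code{role_cod}).
#' @param config a [cohort_config()].
#' @return logical scalar.
#' @export
match_target <- function(drugs, config) {
  dt <- as.data.table(drugs)
  if (nrow(dt) == 0L) stop("report has no drug rows")
  if (!"prod_ai" %in% names(dt)) dt[, prod_ai := ""]
  any(match_target_rows(dt, config))
}

#' Remove indication-like PTs from reaction lists
#'
#' Reaction PTs whose normalized name appears in the exclusion list are
#' removed (they name the treated condition, not an adverse event). A
#' report whose only PTs are excluded drops out of event-level analysis but
#' is retained for report-level demographics by the cohort builder.
#'
#' @param reactions data.table of reaction rows with \code{primaryid} and
#'   \code{pt_norm} (as produced by [read_faers_table()]).
#' @param config a [cohort_config()].
#' @return the filtered reaction table, with attribute \code{"removed"}
#'   giving the count of rows removed per excluded PT.
#' @export
exclude_indications <- function(reactions, config) {
  dt <- as.data.table(reactions)
  if (!"pt_norm" %in% names(dt)) dt[, pt_norm := normalize_name(pt)]
  excl <- normalize_name(config$indication_exclusion_pts)
  hit <- dt$pt_norm %in% excl
  removed <- dt[hit, .(n_removed = .N), by = pt_norm]
  out <- dt[!hit]
  attr(out, "removed") <- removed
  out
}

#' Assemble the analysis cohort
#'
#' Runs the case-processing chain on concatenated quarterly tables:
#' deduplicate case versions, restrict every table to survivors, split
#' reports into the target-drug cohort (a matching drug row with the
#' required role) and the comparator universe (all other deduplicated
#' reports), and strip indication-like PTs from the cohort's reaction
#' lists.
#'
#' @param tables named list of data.tables as returned in
#'   \code{read_faers_quarters()$tables} (DEMO required; DRUG, REAC, OUTC,
#'   THER, INDI used when present).
#' @param config a [cohort_config()].
#' @return a list of class \code{faers_cohort}: \code{demo}, \code{drugs},
#'   \code{reactions} (indication-stripped, with \code{is_target} drug
#'   flags), \code{outcomes}, \code{therapy}, \code{indications} for the
#'   cohort; \code{comparator} (list with \code{demo}, \code{reactions});
#'   and \code{log}, the per-stage record counts.
#' @export
build_cohort <- function(tables, config = cohort_config()) {
  stopifnot("DEMO" %in% names(tables))
  demo <- as.data.table(tables$DEMO)
  log <- list(demo_rows = nrow(demo))

  if (!is.null(config$date_window)) {
    stopifnot("quarter" %in% names(demo))
    win <- config$date_window
    keep_q <- demo$quarter >= win[1] & demo$quarter <= win[2]
    demo <- demo[keep_q]
    log$in_window <- nrow(demo)
  }

  survivors <- deduplicate(demo)
  log$dedup_excluded <- nrow(attr(survivors, "excluded"))
  log$deduplicated <- length(survivors)
  demo <- demo[primaryid %in% survivors]
  # a caseid can survive with the same primaryid listed once; demo rows are
  # unique by primaryid after dedup
  demo <- unique(demo, by = "primaryid")

  grab <- function(kind) {
    if (kind %in% names(tables)) {
      as.data.table(tables[[kind]])[primaryid %in% demo$primaryid]
    } else NULL
  }
  drugs <- grab("DRUG")
  reac <- grab("REAC")
  outc <- grab("OUTC")
  ther <- grab("THER")
  indi <- grab("INDI")

  if (is.null(drugs) || nrow(drugs) == 0L) stop("no drug rows after dedup")
  drugs[, is_target := match_target_rows(drugs, config)]
  target_ids <- unique(drugs[is_target == TRUE, primaryid])
  log$cohort_reports <- length(target_ids)

  in_cohort <- demo$primaryid %in% target_ids
  cohort_demo <- demo[in_cohort]
  comp_demo <- demo[!in_cohort]

  cohort_reac <- reac[primaryid %in% target_ids]
  log$cohort_reaction_rows <- nrow(cohort_reac)
  cohort_reac <- exclude_indications(cohort_reac, config)
  log$indication_rows_removed <-
    sum(attr(cohort_reac, "removed")$n_removed %||% 0L)
  log$cohort_reports_with_events <- length(unique(cohort_reac$primaryid))

  comp_reac <- reac[!primaryid %in% target_ids]

  structure(list(
    config = config,
    survivors = as.character(survivors),
    demo = cohort_demo,
    drugs = drugs[primaryid %in% target_ids],
    reactions = cohort_reac,
    outcomes = if (!is.null(outc)) outc[primaryid %in% target_ids] else NULL,
    therapy = if (!is.null(ther)) ther[primaryid %in% target_ids] else NULL,
    indications = if (!is.null(indi)) indi[primaryid %in% target_ids] else NULL,
    comparator = list(demo = comp_demo, reactions = comp_reac),
    log = log
  ), class = "faers_cohort")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.faers_cohort <- function(x, ...) {
  cat("FAERS analysis cohort\n")
  cat(sprintf("  deduplicated reports : %d\n", x$log$deduplicated))
  cat(sprintf("  cohort reports       : %d\n", x$log$cohort_reports))
  cat(sprintf("  with events retained : %d\n", x$log$cohort_reports_with_events))
  cat(sprintf("  comparator reports   : %d\n", nrow(x$comparator$demo)))
  invisible(x)
}
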