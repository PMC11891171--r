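#' @name faers_io
#' @title Reading and writing FAERS-style quarterly ASCII tables
#'
#' @description
#' FAERS distributes each quarter as a set of dollar-delimited text files,
#' one per table (DEMO, DRUG, REAC, OUTC, THER, INDI), first line a header.
#' Embedded delimiters are never escaped in that dialect, so parsing splits
#' on \code{$} and enforces the exact field count from the header; rows with
#' the wrong field count, or failing type validation, are quarantined into a
#' rejects table (file, line, reason) rather than silently dropped.
#' Column positions are discovered from the header, not assumed.
NULL

# Known columns per table. Mandatory columns must be present in the header;
# optional ones absent from a file come back as all-missing.
.faers_schema <- list(
  DEMO = list(
    cols = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
             "age_cod", "wt", "wt_cod", "occp_cod", "reporter_country"),
    mandatory = c("primaryid", "caseid", "fda_dt")
  ),
  DRUG = list(
    cols = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    mandatory = c("primaryid", "drug_seq", "role_cod", "drugname")
  ),
  REAC = list(
    cols = c("primaryid", "pt"),
    mandatory = c("primaryid", "pt")
  ),
  OUTC = list(
    cols = c("primaryid", "outc_cod"),
    mandatory = c("primaryid", "outc_cod")
  ),
  THER = list(
    cols = c("primaryid", "dsg_drug_seq", "start_dt"),
    mandatory = c("primaryid", "dsg_drug_seq")
  ),
  INDI = list(
    cols = c("primaryid", "indi_drug_seq", "indi_pt"),
    mandatory = c("primaryid", "indi_drug_seq", "indi_pt")
  )
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

# Read lines as UTF-8; if the bytes are not valid UTF-8, fall back to
# latin-1 (real FAERS files mix encodings file by file).
read_lines_enc <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(!validUTF8(raw))) {
    raw <- readLines(path, warn = FALSE)
    raw <- iconv(raw, from = "latin1", to = "UTF-8")
  }
  raw
}

#' Read one FAERS-style table
#'
#' @param path path to a dollar-delimited text file with a header row.
#' @param table_kind one of \code{"DEMO"}, \code{"DRUG"}, \code{"REAC"},
#'   \code{"OUTC"}, \code{"THER"}, \code{"INDI"}.
#' @return a list with \code{records} (a \code{data.table} of typed rows,
#'   one column per schema field plus derived columns such as
#'   \code{age_yr}/\code{wt_kg} for DEMO) and \code{rejects} (a
#'   \code{data.table} with \code{file}, \code{line}, \code{reason}).
#'   \code{nrow(records) + nrow(rejects)} equals the number of data lines.
#' @details
#' Missing-value codes are mapped, not rejected: a DEMO \code{sex} outside
#' \{F, M\} becomes missing, an unknown age-unit code yields a missing
#' normalized age. Structural failures (wrong field count, empty
#' \code{primaryid}, an 8-digit \code{fda_dt} that is not a calendar date,
#' a DRUG role code outside \{PS, SS, C, I\}) are quarantined.
#' Age units are normalized to years (DEC decades, YR, MON, WK, DY, HR);
#' weights to kilograms (KG, LBS).
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- toupper(table_kind)
  if (!table_kind %in% names(.faers_schema)) {
    stop("unknown table_kind: ", table_kind)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  schema <- .faers_schema[[table_kind]]

  lines <- read_lines_enc(path)
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  header <- tolower(trimws(strsplit(lines[1L], "$", fixed = TRUE)[[1L]]))
  missing_mand <- setdiff(schema$mandatory, header)
  if (length(missing_mand)) {
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing_mand, collapse = ", ")))
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  empty_rejects <- data.table(file = character(), line = integer(),
                              reason = character())
  if (length(body) == 0L) {
    rec <- empty_records(schema$cols, table_kind)
    return(structure(list(records = rec, rejects = empty_rejects,
                          table = table_kind, header = header),
                     class = "faers_table"))
  }

  parts <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a trailing empty field; pad to header length when the
  # raw line has the right number of delimiters
  nfield_raw <- lengths(parts)
  ndollar <- lengths(gregexpr("$", body, fixed = TRUE)) -
    (!grepl("$", body, fixed = TRUE))
  nfield <- pmax(nfield_raw, ndollar + 1L)
  ok_count <- nfield == length(header)

  rejects <- list()
  if (any(!ok_count)) {
    rejects[[length(rejects) + 1L]] <- data.table(
      file = basename(path), line = which(!ok_count) + 1L,
      reason = sprintf("field count %d != header %d",
                       nfield[!ok_count], length(header)))
  }
  keep <- which(ok_count)
  if (length(keep) == 0L) {
    rec <- empty_records(schema$cols, table_kind)
    return(structure(list(records = rec, rejects = rbindlist(rejects),
                          table = table_kind, header = header),
                     class = "faers_table"))
  }

  nc <- length(header)
  padded <- vapply(parts[keep], function(p) {
    length(p) <- nc
    p
  }, character(nc))
  mat <- t(matrix(padded, nrow = nc))
  mat[is.na(mat)] <- ""
  dt <- as.data.table(mat)
  setnames(dt, header)
  present <- intersect(schema$cols, header)
  dt <- dt[, ..present]
  for (col in setdiff(schema$cols, header)) dt[, (col) := ""]
  setcolorder(dt, schema$cols)
  for (col in schema$cols) dt[, (col) := trimws(get(col))]
  dt[, line := keep + 1L]

  bad <- validate_rows(dt, table_kind)
  if (any(bad$flag)) {
    rejects[[length(rejects) + 1L]] <- data.table(
      file = basename(path), line = dt$line[bad$flag],
      reason = bad$reason[bad$flag])
    dt <- dt[!bad$flag]
  }
  dt[, line := NULL]
  dt <- type_records(dt, table_kind)

  structure(list(records = dt,
                 rejects = if (length(rejects)) rbindlist(rejects) else empty_rejects,
                 table = table_kind, header = header),
            class = "faers_table")
}

empty_records <- function(cols, table_kind) {
  dt <- as.data.table(setNames(rep(list(character()), length(cols)), cols))
  type_records(dt, table_kind)
}

# Structural validation; returns flag + reason per row.
validate_rows <- function(dt, table_kind) {
  n <- nrow(dt)
  flag <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    if (length(why) == 1L) why <- rep(why, length(cond))
    new <- which(cond & !flag)
    flag[new] <<- TRUE
    reason[new] <<- why[new]
  }
  mark(!nzchar(dt$primaryid), "empty primaryid")
  if (table_kind == "DEMO") {
    mark(!nzchar(dt$caseid), "empty caseid")
    mark(date_kind(dt$fda_dt) == "invalid", "fda_dt not a calendar date")
    mark(date_kind(dt$event_dt) == "invalid", "event_dt not a calendar date")
  }
  if (table_kind == "DRUG") {
    mark(is.na(suppressWarnings(as.integer(dt$drug_seq))), "non-integer drug_seq")
    mark(!dt$role_cod %in% .role_codes,
         sprintf("role code '%s' not in PS/SS/C/I", dt$role_cod))
    mark(!nzchar(normalize_name(dt$drugname)) & !nzchar(normalize_name(dt$prod_ai)),
         "empty drugname and prod_ai")
  }
  if (table_kind == "REAC") {
    mark(!nzchar(normalize_name(dt$pt)), "empty pt")
  }
  if (table_kind == "OUTC") {
    mark(!dt$outc_cod %in% .outcome_codes,
         sprintf("outcome code '%s' unknown", dt$outc_cod))
  }
  if (table_kind %in% c("THER", "INDI")) {
    seq_col <- if (table_kind == "THER") "dsg_drug_seq" else "indi_drug_seq"
    mark(is.na(suppressWarnings(as.integer(dt[[seq_col]]))),
         paste0("non-integer ", seq_col))
    if (table_kind == "THER") {
      mark(date_kind(dt$start_dt) == "invalid", "start_dt not a calendar date")
    }
    if (table_kind == "INDI") {
      mark(!nzchar(normalize_name(dt$indi_pt)), "empty indi_pt")
    }
  }
  list(flag = flag, reason = reason)
}

.age_to_years <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 7 / 365.25,
                   DY = 1 / 365.25, HR = 1 / 8766)

# Apply type conversions and missing-value mapping (never rejects).
type_records <- function(dt, table_kind) {
  if (table_kind == "DEMO") {
    dt[, sex := fifelse(sex %in% c("F", "M"), sex, NA_character_)]
    dt[, age := suppressWarnings(as.numeric(age))]
    dt[, age_cod := toupper(age_cod)]
    factor_ <- .age_to_years[dt$age_cod]
    dt[, age_yr := age * unname(factor_)]
    dt[, wt := suppressWarnings(as.numeric(wt))]
    dt[, wt_kg := fifelse(toupper(wt_cod) == "KG", wt,
                   fifelse(toupper(wt_cod) == "LBS", wt * 0.453592, NA_real_))]
    dt[, occp_cod := fifelse(nzchar(occp_cod), occp_cod, NA_character_)]
    dt[, reporter_country := fifelse(nzchar(reporter_country),
                                     reporter_country, NA_character_)]
  }
  if (table_kind == "DRUG") {
    dt[, drug_seq := as.integer(drug_seq)]
  }
  if (table_kind == "REAC") {
    dt[, pt_norm := normalize_name(pt)]
  }
  if (table_kind == "THER") {
    dt[, dsg_drug_seq := as.integer(dsg_drug_seq)]
  }
  if (table_kind == "INDI") {
    dt[, indi_drug_seq := as.integer(indi_drug_seq)]
  }
  dt[]
}

#' Write one FAERS-style table
#'
#' Inverse of [read_faers_table()]: dollar-delimited, header first,
#' missing values as empty fields. Derived columns (\code{age_yr},
#' \code{wt_kg}, \code{pt_norm}, \code{quarter}) are not written.
#'
#' @param records data.frame/data.table of records.
#' @param path output file path.
#' @param table_kind table name, as in [read_faers_table()].
#' @return the path, invisibly.
#' @export
write_faers_table <- function(records, path, table_kind) {
  table_kind <- toupper(table_kind)
  schema <- .faers_schema[[table_kind]]
  if (is.null(schema)) stop("unknown table_kind: ", table_kind)
  dt <- as.data.table(records)
  for (col in setdiff(schema$cols, names(dt))) dt[, (col) := ""]
  dt <- dt[, schema$cols, with = FALSE]
  cols <- lapply(schema$cols, function(cl) {
    v <- as.character(dt[[cl]])
    v[is.na(v)] <- ""
    v
  })
  txt <- if (nrow(dt)) do.call(paste, c(cols, sep = "$")) else character()
  writeLines(c(paste(schema$cols, collapse = "$"), txt), path)
  invisible(path)
}

#' Read every quarter in a directory and concatenate
#'
#' Discovers files named \code{<TABLE><YY>Q<N>.txt} (e.g. \code{DEMO13Q3.txt}),
#' reads each with [read_faers_table()], and row-binds quarters per table.
#' Each record keeps its quarter label in a \code{quarter} column
#' (per-quarter provenance); deduplication is downstream, so the same
#' \code{caseid} appearing in several quarters is retained here.
#'
#' @param dir directory containing the quarterly files.
#' @return list with \code{tables} (named list of data.tables, one per table
#'   kind found) and \code{rejects} (combined rejects log).
#' @export
read_faers_quarters <- function(dir) {
  files <- list.files(dir, pattern = "^(DEMO|DRUG|REAC|OUTC|THER|INDI)[0-9]{2}Q[1-4]\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no FAERS quarterly files found in ", dir)
  kinds <- sub("[0-9]{2}Q[1-4]\\.txt$", "", basename(files))
  quarters <- sub("^(DEMO|DRUG|REAC|OUTC|THER|INDI)", "",
                  sub("\\.txt$", "", basename(files)))
  parsed <- Map(read_faers_table, files, kinds)
  concat_quarters(parsed, quarters)
}

#' Concatenate quarterly table reads
#'
#' @param parsed list of [read_faers_table()] results.
#' @param quarters character vector of quarter labels, parallel to
#'   \code{parsed}.
#' @return list with \code{tables} and \code{rejects}, as in
#'   [read_faers_quarters()].
#' @details Errors if two quarters of the same table were read with
#'   different headers (inconsistent schemas cannot be concatenated).
#' @export
concat_quarters <- function(parsed, quarters) {
  if (length(parsed) == 0L) stop("need at least one quarter")
  kinds <- vapply(parsed, `[[`, character(1), "table")
  for (k in unique(kinds)) {
    heads <- unique(lapply(parsed[kinds == k], function(p) sort(p$header)))
    if (length(heads) > 1L) {
      stop("inconsistent headers across quarters for table ", k)
    }
  }
  tables <- lapply(split(seq_along(parsed), kinds), function(idx) {
    pieces <- Map(function(p, q) {
      dt <- copy(p$records)
      dt[, quarter := q]
      dt
    }, parsed[idx], quarters[idx])
    rbindlist(pieces, use.names = TRUE)
  })
  rejects <- rbindlist(lapply(parsed, `[[`, "rejects"))
  list(tables = tables, rejects = rejects)
}
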