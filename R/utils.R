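#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero, the convention used
#' in regulatory report tables (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @export
#' @examples
#' round_half_up(0.5)     # 1, not 0
#' round_half_up(2.125, 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, report-style
#'
#' Computes \code{100 * count / total} rounded half-up to \code{digits}
#' decimal places, with the convention that an empty denominator yields 0.
#' This is the routine used for every percentage the pipeline prints.
#'
#' @param count numeric vector of counts.
#' @param total scalar denominator (missing values are part of the
#'   denominator in all demographic breakdowns).
#' @param digits decimal places (default 1, matching report tables).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct_of(6875, 11298)  # 60.9
pct_of <- function(count, total, digits = 1) {
  if (!length(total) == 1L || is.na(total)) stop("`total` must be a scalar")
  if (total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, digits)
}

# Lower-case, trim, collapse internal whitespace: the normalization applied
# to drug names and PT text before any matching.
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Classify a FAERS date string: "full" (8 digits, valid calendar date),
# "partial" (YYYY or YYYYMM), otherwise "missing".
date_kind <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  digits <- grepl("^[0-9]+$", x)
  out[digits & nchar(x) %in% c(4L, 6L)] <- "partial"
  full <- digits & nchar(x) == 8L
  if (any(full)) {
    ok <- !is.na(as.Date(x[full], format = "%Y%m%d"))
    out[full][ok] <- "full"
    # 8 digits but not a calendar date stays invalid
    out[full][!ok] <- "invalid"
  }
  out
}

# Parse full 8-digit dates to Date; anything else becomes NA.
parse_date8 <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

# Complete a partial date to its period end (YYYY -> Dec 31, YYYYMM -> last
# day of month) and return the 8-digit integer key used for ordering.
# Full dates pass through; missing/invalid come back NA.
date_order_key <- function(x) {
  x <- trimws(as.character(x))
  kind <- date_kind(x)
  out <- rep(NA_real_, length(x))
  out[kind == "full"] <- as.numeric(x[kind == "full"])
  p4 <- kind == "partial" & nchar(x) == 4L
  out[p4] <- as.numeric(paste0(x[p4], "1231"))
  p6 <- kind == "partial" & nchar(x) == 6L
  if (any(p6)) {
    first <- as.Date(paste0(x[p6], "01"), format = "%Y%m%d")
    last <- seq_month_end(first)
    out[p6] <- as.numeric(format(last, "%Y%m%d"))
  }
  out
}

seq_month_end <- function(first_of_month) {
  nxt <- as.Date(vapply(first_of_month, function(d) {
    format(seq(d, by = "1 month", length.out = 2)[2], "%Y-%m-%d")
  }, character(1)))
  nxt - 1L
}

# "13Q3"-style quarter label from year + quarter number.
quarter_label <- function(year, q) sprintf("%02dQ%d", year %% 100, q)

# First and last calendar day of a (year, quarter).
quarter_bounds <- function(year, q) {
  start <- as.Date(sprintf("%04d-%02d-01", year, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1L
  list(start = start, end = end)
}

fmt_date8 <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
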