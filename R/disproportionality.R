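#' @name disproportionality
#' @title Disproportionality statistics for drug-event 2x2 tables
#'
#' @description
#' For one drug-event pair the spontaneous-report universe reduces to a 2x2
#' table: \code{a} reports with the target drug and the target event,
#' \code{b} with the drug and other events, \code{c} with other drugs and
#' the event, \code{d} with neither. Four estimators are computed on that
#' table, in their closed (non-shrunk) forms:
#' \itemize{
#'   \item ROR = ad/(bc), with lognormal 95\% CI
#'     exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d));
#'   \item PRR = a(c+d)/(c(a+b)), with the Pearson chi-squared
#'     (ad-bc)^2 (a+b+c+d) / ((a+b)(c+d)(a+c)(b+d)), no continuity
#'     correction;
#'   \item the BCPNN information component IC = log2(a N / ((a+c)(a+b))),
#'     with IC025 = IC - 2 sqrt(V(IC));
#'   \item EBGM = a N / ((a+c)(a+b)) (the observed/expected ratio), with
#'     EBGM05 = exp(ln EBGM - 1.96 sqrt(1/a+1/b+1/c+1/d)).
#' }
#' IC equals log2(EBGM) identically in these forms. Zero cells leave the
#' affected statistic undefined (\code{NA}) unless the Haldane +0.5
#' correction is requested; an undefined statistic always fails its signal
#' flag.
NULL

as_abcd <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(table)))
    list(a = as.numeric(table$a), b = as.numeric(table$b),
         c = as.numeric(table$c), d = as.numeric(table$d))
  } else {
    x <- as.numeric(table)
    if (length(x) != 4L) stop("table must be c(a, b, c, d) or have columns a..d")
    list(a = x[1], b = x[2], c = x[3], d = x[4])
  }
}

apply_zero_correction <- function(t, zero_correction) {
  if (zero_correction == "haldane") {
    z <- t$a == 0 | t$b == 0 | t$c == 0 | t$d == 0
    for (cell in c("a", "b", "c", "d")) t[[cell]] <- t[[cell]] + 0.5 * z
  }
  t
}

#' Reporting odds ratio with 95\% CI
#'
#' @param table either \code{c(a, b, c, d)} or a data.frame with columns
#'   \code{a}, \code{b}, \code{c}, \code{d} (vectorized over rows).
#' @param zero_correction \code{"none"} (default: any zero cell leaves the
#'   statistic undefined) or \code{"haldane"} (+0.5 to every cell of a
#'   table containing a zero).
#' @return data.table with columns \code{ror}, \code{ror_ci_low},
#'   \code{ror_ci_high}.
#' @export
#' @examples
#' ror(c(20, 10, 10, 20))  # ROR 4, CI about [1.37, 11.7]
ror <- function(table, zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  t <- apply_zero_correction(as_abcd(table), zero_correction)
  ok <- t$a > 0 & t$b > 0 & t$c > 0 & t$d > 0
  est <- ifelse(ok, (t$a * t$d) / (t$b * t$c), NA_real_)
  se <- ifelse(ok, sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d), NA_real_)
  data.table(ror = est,
             ror_ci_low = exp(log(est) - 1.96 * se),
             ror_ci_high = exp(log(est) + 1.96 * se))
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' @inheritParams ror
#' @return data.table with columns \code{prr} and \code{chi2}. \code{prr}
#'   is undefined when \code{c == 0} or \code{a + b == 0}; \code{chi2} when
#'   any margin is zero.
#' @export
#' @examples
#' prr_chi2(c(20, 80, 10, 890))  # PRR 18, chi2 about 110.35
prr_chi2 <- function(table, zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  t <- apply_zero_correction(as_abcd(table), zero_correction)
  n <- t$a + t$b + t$c + t$d
  prr_ok <- t$c > 0 & (t$a + t$b) > 0
  prr <- ifelse(prr_ok, t$a * (t$c + t$d) / (t$c * (t$a + t$b)), NA_real_)
  denom <- (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d)
  chi2 <- ifelse(denom > 0,
                 (t$a * t$d - t$b * t$c)^2 * n / denom, NA_real_)
  data.table(prr = prr, chi2 = chi2)
}

# Delta-method variance of the information component on the log2 scale.
ic_variance_delta <- function(t) {
  (1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d) / log(2)^2
}

#' BCPNN information component with lower bound
#'
#' IC = log2(a N / ((a+c)(a+b))), the log2 observed-over-expected report
#' count. The lower bound is IC025 = IC - 2 sqrt(V(IC)). Two variance modes
#' are available: \code{"delta"} (default), the delta-method
#' V(IC) = (1/a + 1/b + 1/c + 1/d) / ln(2)^2, and \code{"fixed"}, where the
#' bound is a constant offset \code{ic025 = ic - kappa} (report tables in
#' this field sometimes show a near-constant IC-to-IC025 gap, which only a
#' degenerate variance reproduces; the fixed mode mimics such tables on
#' demand without claiming a variance model).
#'
#' @inheritParams ror
#' @param variance \code{"delta"} or \code{"fixed"}.
#' @param kappa offset used when \code{variance = "fixed"} (default 1.66).
#' @return data.table with columns \code{ic}, \code{ic025}. Undefined when
#'   \code{a == 0} (and, for the delta bound, when any cell is zero).
#' @export
#' @examples
#' bcpnn_ic(c(20, 80, 10, 890))  # IC = log2(6.667) ~ 2.74
bcpnn_ic <- function(table, variance = c("delta", "fixed"), kappa = 1.66,
                     zero_correction = c("none", "haldane")) {
  variance <- match.arg(variance)
  zero_correction <- match.arg(zero_correction)
  t <- apply_zero_correction(as_abcd(table), zero_correction)
  n <- t$a + t$b + t$c + t$d
  ok <- t$a > 0 & (t$a + t$c) > 0 & (t$a + t$b) > 0
  ic <- ifelse(ok, log2(t$a * n / ((t$a + t$c) * (t$a + t$b))), NA_real_)
  if (variance == "delta") {
    vok <- ok & t$b > 0 & t$c > 0 & t$d > 0
    v <- ifelse(vok, ic_variance_delta(t), NA_real_)
    ic025 <- ic - 2 * sqrt(v)
  } else {
    ic025 <- ic - kappa
  }
  data.table(ic = ic, ic025 = ic025)
}

#' Empirical Bayes geometric mean (closed form) with lower bound
#'
#' EBGM = a N / ((a+c)(a+b)), the observed/expected report-count ratio,
#' with EBGM05 = exp(ln EBGM - 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). These are
#' the closed, non-shrunk forms; the gamma-Poisson shrinkage variant is
#' deliberately not implemented (see the methods vignette).
#'
#' @inheritParams ror
#' @return data.table with columns \code{ebgm}, \code{ebgm05}. \code{ebgm}
#'   is undefined when \code{a == 0}; \code{ebgm05} additionally when any
#'   cell of the SE term is zero.
#' @export
#' @examples
#' mgps_ebgm(c(20, 80, 10, 890))  # EBGM ~ 6.667
mgps_ebgm <- function(table, zero_correction = c("none", "haldane")) {
  zero_correction <- match.arg(zero_correction)
  t <- apply_zero_correction(as_abcd(table), zero_correction)
  n <- t$a + t$b + t$c + t$d
  ok <- t$a > 0 & (t$a + t$c) > 0 & (t$a + t$b) > 0
  ebgm <- ifelse(ok, t$a * n / ((t$a + t$c) * (t$a + t$b)), NA_real_)
  se_ok <- t$a > 0 & t$b > 0 & t$c > 0 & t$d > 0
  se <- ifelse(se_ok, sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d), NA_real_)
  data.table(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se))
}

#' Signal criteria
#'
#' The conventional per-algorithm positivity rules: ROR positive when
#' n >= 3 and the CI lower limit > 1; PRR positive when PRR >= 2,
#' chi-squared >= 4 and n >= 3; BCPNN positive when IC025 > 0; MGPS
#' positive when EBGM05 > 2. All thresholds are configurable.
#'
#' @param min_cases minimum report count n (= a) for ROR/PRR flags.
#' @param ror_ci_low_gt ROR CI lower limit must exceed this.
#' @param prr_ge,chi2_ge PRR and chi-squared thresholds.
#' @param ic025_gt IC025 must exceed this.
#' @param ebgm05_gt EBGM05 must exceed this.
#' @return list of class \code{signal_criteria}.
#' @export
signal_criteria <- function(min_cases = 3, ror_ci_low_gt = 1, prr_ge = 2,
                            chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  structure(list(min_cases = min_cases, ror_ci_low_gt = ror_ci_low_gt,
                 prr_ge = prr_ge, chi2_ge = chi2_ge, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt),
            class = "signal_criteria")
}

#' Apply signal criteria to computed statistics
#'
#' Adds the four per-algorithm flags and the consensus flag (their
#' conjunction) to a statistics table. An undefined (NA) statistic fails
#' its flag.
#'
#' @param stats data.table with columns \code{n}, \code{ror_ci_low},
#'   \code{prr}, \code{chi2}, \code{ic025}, \code{ebgm05} (as produced by
#'   [compute_signals()]).
#' @param criteria a [signal_criteria()].
#' @return \code{stats} with logical columns \code{ror_pos},
#'   \code{prr_pos}, \code{bcpnn_pos}, \code{mgps_pos}, \code{consensus}.
#' @export
flag_signals <- function(stats, criteria = signal_criteria()) {
  dt <- as.data.table(stats)
  isT <- function(x) !is.na(x) & x
  dt[, ror_pos := isT(n >= criteria$min_cases &
                        ror_ci_low > criteria$ror_ci_low_gt)]
  dt[, prr_pos := isT(prr >= criteria$prr_ge & chi2 >= criteria$chi2_ge &
                        n >= criteria$min_cases)]
  dt[, bcpnn_pos := isT(ic025 > criteria$ic025_gt)]
  dt[, mgps_pos := isT(ebgm05 > criteria$ebgm05_gt)]
  dt[, consensus := ror_pos & prr_pos & bcpnn_pos & mgps_pos]
  dt[]
}

#' Build 2x2 contingency tables at PT or SOC level
#'
#' The default counting unit is the report-event pair: a deduplicated
#' report contributes one unit per distinct PT it lists (and one per
#' distinct SOC at SOC level, however many of its PTs map there), and the
#' table margins are pair counts. \code{unit = "report"} switches to
#' whole-report counting (margins are report counts). Cohort events are
#' tabulated against the comparator universe: every deduplicated report
#' not in the cohort.
#'
#' @param cohort a \code{faers_cohort} from [build_cohort()].
#' @param dictionary a PT -> SOC dictionary from [read_dictionary()] /
#'   [make_dictionary()].
#' @param level \code{"PT"} or \code{"SOC"}.
#' @param unit \code{"pair"} (default) or \code{"report"}.
#' @return data.table with \code{level}, \code{event_name},
#'   \code{event_code}, \code{a}, \code{b}, \code{c}, \code{d}, \code{n}
#'   (= a); one row per event observed in the cohort. PTs absent from the
#'   dictionary are kept at PT level with a missing code and dropped at
#'   SOC level; their count is in attribute \code{"unresolved"}.
#' @export
build_tables <- function(cohort, dictionary, level = c("PT", "SOC"),
                         unit = c("pair", "report")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  stopifnot(inherits(cohort, "faers_cohort"))
  dict <- as.data.table(dictionary)
  if (!"pt_norm" %in% names(dict)) dict[, pt_norm := normalize_name(pt_name)]

  coh <- unique(as.data.table(cohort$reactions)[, .(primaryid, pt_norm)])
  cmp <- unique(as.data.table(cohort$comparator$reactions)[, .(primaryid, pt_norm)])
  if (nrow(coh) == 0L) stop("empty cohort: no reaction rows")

  unresolved <- setdiff(unique(coh$pt_norm), dict$pt_norm)

  if (level == "PT") {
    name_map <- dict[, .(key = pt_norm, event_name = pt_name,
                         event_code = pt_code)]
    if (length(unresolved)) {
      name_map <- rbind(name_map,
                        data.table(key = unresolved, event_name = unresolved,
                                   event_code = NA_character_))
    }
    coh_ev <- coh[, .(primaryid, key = pt_norm)]
    cmp_ev <- cmp[, .(primaryid, key = pt_norm)]
  } else {
    coh_ev <- merge(coh, dict[, .(pt_norm, key = soc_name,
                                  event_code = soc_code)], by = "pt_norm")
    cmp_ev <- merge(cmp, dict[, .(pt_norm, key = soc_name)], by = "pt_norm")
    name_map <- unique(coh_ev[, .(key, event_name = key, event_code)])
    coh_ev <- unique(coh_ev[, .(primaryid, key)])
    cmp_ev <- unique(cmp_ev[, .(primaryid, key)])
  }

  if (unit == "pair") {
    n_coh <- nrow(coh_ev)
    n_cmp <- nrow(cmp_ev)
  } else {
    n_coh <- nrow(cohort$demo)
    n_cmp <- nrow(cohort$comparator$demo)
  }

  a_tab <- coh_ev[, .(a = .N), by = key]
  c_tab <- cmp_ev[, .(cnt = .N), by = key]
  out <- merge(a_tab, c_tab, by = "key", all.x = TRUE)
  out[is.na(cnt), cnt := 0L]
  out[, b := n_coh - a]
  out[, d := n_cmp - cnt]
  setnames(out, "cnt", "c")
  out <- merge(out, name_map, by = "key", all.x = TRUE)
  lvl <- level
  out[, level := lvl]
  out <- out[, .(level, event_name, event_code, a, b, c, d, n = a)]
  setorder(out, -n, event_name)
  setattr(out, "unresolved", unresolved)
  setattr(out, "unit", unit)
  out[]
}

#' Compute all four statistics, with flags, for a table set
#'
#' @param tables output of [build_tables()] (or any data.table with
#'   \code{a}, \code{b}, \code{c}, \code{d} columns).
#' @param criteria a [signal_criteria()].
#' @param ic_variance,kappa passed to [bcpnn_ic()].
#' @param zero_correction passed to every estimator.
#' @return the input with \code{ror}, \code{ror_ci_low}, \code{ror_ci_high},
#'   \code{prr}, \code{chi2}, \code{ic}, \code{ic025}, \code{ebgm},
#'   \code{ebgm05}, the four flags and \code{consensus} appended.
#' @export
compute_signals <- function(tables, criteria = signal_criteria(),
                            ic_variance = c("delta", "fixed"), kappa = 1.66,
                            zero_correction = c("none", "haldane")) {
  ic_variance <- match.arg(ic_variance)
  zero_correction <- match.arg(zero_correction)
  dt <- as.data.table(tables)
  if (!"n" %in% names(dt)) dt[, n := a]
  dt <- cbind(dt,
              ror(dt, zero_correction = zero_correction),
              prr_chi2(dt, zero_correction = zero_correction),
              bcpnn_ic(dt, variance = ic_variance, kappa = kappa,
                       zero_correction = zero_correction),
              mgps_ebgm(dt, zero_correction = zero_correction))
  flag_signals(dt, criteria)
}

#' Format a signal table for reporting
#'
#' Rounds to 2 decimals (half-up, the convention of printed report tables)
#' and assembles the compound display columns used in published signal
#' tables: "ROR (low - high)", "PRR (chi2)", "EBGM (EBGM05)", "IC (IC025)".
#'
#' @param stats output of [compute_signals()].
#' @param min_cases keep only events with \code{n >= min_cases}.
#' @return data.table ready to write.
#' @export
format_signal_table <- function(stats, min_cases = 1) {
  dt <- as.data.table(stats)[n >= min_cases]
  r2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", round_half_up(x, 2)))
  dt[, .(level, event_name, event_code, n,
         ror_95ci = sprintf("%s (%s - %s)", r2(ror), r2(ror_ci_low),
                            r2(ror_ci_high)),
         prr_chi2 = sprintf("%s (%s)", r2(prr), r2(chi2)),
         ebgm_ebgm05 = sprintf("%s (%s)", r2(ebgm), r2(ebgm05)),
         ic_ic025 = sprintf("%s (%s)", r2(ic), r2(ic025)),
         ror_pos, prr_pos, bcpnn_pos, mgps_pos, consensus)]
}

#' Forest-plot-ready long format
#'
#' One row per event: ROR point estimate with CI bounds, labelled, ordered
#' by descending case count — the layout a forest plot consumes directly.
#'
#' @param stats output of [compute_signals()].
#' @param min_cases keep only events with \code{n >= min_cases}.
#' @return data.table with \code{label}, \code{level}, \code{n},
#'   \code{estimate}, \code{low}, \code{high}.
#' @export
forest_data <- function(stats, min_cases = 1) {
  dt <- as.data.table(stats)[n >= min_cases]
  out <- dt[, .(label = event_name, level, n, estimate = ror,
                low = ror_ci_low, high = ror_ci_high)]
  setorder(out, -n, label)
  out[]
}
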