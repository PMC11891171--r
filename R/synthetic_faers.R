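#' Default PT/SOC vocabulary for the synthetic generator
#'
#' A compact MedDRA-style vocabulary: each preferred term (PT) belongs to
#' exactly one system organ class (SOC). Terms are drawn from the adverse
#' events typically reported for serotonergic antidepressants so the
#' synthetic stream exercises the same SOC mix a real extraction would.
#'
#' @return a \code{data.table} with columns \code{pt} and \code{soc}.
#' @export
default_pt_vocabulary <- function() {
  v <- rbind(
    data.table(soc = "Gastrointestinal disorders",
               pt = c("Nausea", "Vomiting", "Dry mouth", "Diarrhoea",
                      "Constipation", "Abdominal pain", "Dyspepsia", "Retching")),
    data.table(soc = "Psychiatric disorders",
               pt = c("Suicidal ideation", "Insomnia", "Irritability", "Anger",
                      "Apathy", "Agitation", "Mood swings", "Libido decreased",
                      "Anxiety", "Mania", "Abnormal dreams", "Nightmare",
                      "Panic attack", "Restlessness", "Depression",
                      "Hallucination", "Bruxism")),
    data.table(soc = "Nervous system disorders",
               pt = c("Headache", "Dizziness", "Somnolence", "Tremor",
                      "Serotonin syndrome", "Akathisia", "Disturbance in attention",
                      "Hypersomnia", "Paraesthesia", "Sedation")),
    data.table(soc = "Skin and subcutaneous tissue disorders",
               pt = c("Pruritus", "Rash", "Hyperhidrosis", "Urticaria")),
    data.table(soc = "General disorders and administration site conditions",
               pt = c("Fatigue", "Feeling abnormal", "Crying", "Malaise",
                      "Feeling jittery", "Drug ineffective")),
    data.table(soc = "Investigations",
               pt = c("Weight increased", "Weight decreased",
                      "Blood sodium decreased")),
    data.table(soc = "Metabolism and nutrition disorders",
               pt = c("Hyperphagia", "Decreased appetite", "Hyponatraemia")),
    data.table(soc = "Reproductive system and breast disorders",
               pt = c("Sexual dysfunction", "Erectile dysfunction",
                      "Anorgasmia")),
    data.table(soc = "Ear and labyrinth disorders",
               pt = c("Tinnitus", "Vertigo")),
    data.table(soc = "Renal and urinary disorders",
               pt = c("Urinary retention", "Pollakiuria")),
    data.table(soc = "Musculoskeletal and connective tissue disorders",
               pt = c("Muscle twitching", "Arthralgia", "Myalgia")),
    data.table(soc = "Social circumstances",
               pt = c("Alcohol use"))
  )
  v[, .(pt, soc)]
}

#' Configuration for the synthetic FAERS generator
#'
#' Defines the study conditions a synthetic run emulates: report volume,
#' the target drug's name spellings, a PT/SOC vocabulary with per-PT
#' ground-truth reporting-rate ratios, the duplicate-submission rate, and
#' the demographic missingness profile. Defaults mirror the scale and
#' missingness of a real spontaneous-report cohort (about 13% of reports
#' without sex, 56% without age, 79% without weight).
#'
#' @param n_reports number of distinct cases to generate (duplicate
#'   versions come on top of this).
#' @param n_quarters number of calendar quarters the stream spans.
#' @param target_drug_names spellings matched for the target drug; the
#'   generator also emits salted variants ("... HYDROBROMIDE 10MG") so name
#'   matching by containment is exercised.
#' @param n_other_drugs size of the comparator drug universe.
#' @param pt_vocabulary data.frame with columns \code{pt}, \code{soc}.
#' @param signal_spec named numeric vector: reporting-rate ratio rho per PT
#'   (rho = 1 is null; every name must be in the vocabulary).
#' @param exposed_fraction fraction of reports whose primary-suspect drug is
#'   the target (default 0.02: in spontaneous-report universes any single
#'   drug is a small share of reports; a large share would contaminate the
#'   observed/expected baseline that IC and EBGM divide by).
#' @param duplicate_fraction fraction of cases re-submitted as a second
#'   version with a later (or tied) receipt date.
#' @param tie_fraction fraction of duplicate pairs whose two versions share
#'   the same FDA_DT, exercising the PRIMARYID tie-break.
#' @param missing_sex_frac,missing_age_frac,missing_weight_frac,missing_date_frac
#'   missingness fractions in \code{[0,1]}; dates degrade to partial
#'   (YYYY/YYYYMM) or empty values.
#' @param mean_pts_per_report expected number of distinct reaction PTs per
#'   report (baseline rates are rescaled to hit this mean).
#' @param base_rate optional named numeric vector of per-PT baseline event
#'   probabilities, overriding the log-uniform draw for those PTs.
#' @param start_year,start_quarter calendar anchor of the first quarter.
#' @param seed integer RNG seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return a validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_reports = 50000L,
                             n_quarters = 4L,
                             target_drug_names = c("trintellix", "vortioxetine"),
                             n_other_drugs = 40L,
                             pt_vocabulary = default_pt_vocabulary(),
                             signal_spec = numeric(),
                             exposed_fraction = 0.02,
                             duplicate_fraction = 0.05,
                             tie_fraction = 0.20,
                             missing_sex_frac = 0.13,
                             missing_age_frac = 0.56,
                             missing_weight_frac = 0.79,
                             missing_date_frac = 0.15,
                             mean_pts_per_report = 2.5,
                             base_rate = NULL,
                             start_year = 2013L,
                             start_quarter = 3L,
                             seed = 1L) {
  vocab <- as.data.table(pt_vocabulary)
  if (!all(c("pt", "soc") %in% names(vocab)) || nrow(vocab) == 0L) {
    stop("pt_vocabulary must be a non-empty table with columns pt, soc")
  }
  if (anyDuplicated(vocab$pt)) stop("duplicate PT names in pt_vocabulary")
  if (n_reports < 0) stop("n_reports must be >= 0")
  if (n_quarters < 1) stop("n_quarters must be >= 1")
  if (length(target_drug_names) == 0L) stop("need at least one target name")
  fracs <- c(exposed_fraction = exposed_fraction,
             duplicate_fraction = duplicate_fraction,
             tie_fraction = tie_fraction,
             missing_sex_frac = missing_sex_frac,
             missing_age_frac = missing_age_frac,
             missing_weight_frac = missing_weight_frac,
             missing_date_frac = missing_date_frac)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0,1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (length(signal_spec)) {
    if (is.null(names(signal_spec)) || any(!nzchar(names(signal_spec)))) {
      stop("signal_spec must be a named vector (PT name -> rho)")
    }
    missing_pt <- setdiff(names(signal_spec), vocab$pt)
    if (length(missing_pt)) {
      stop("signal_spec PTs not in vocabulary: ",
           paste(missing_pt, collapse = ", "))
    }
    if (any(signal_spec < 0)) stop("reporting-rate ratios must be >= 0")
  }
  if (!is.null(base_rate)) {
    missing_pt <- setdiff(names(base_rate), vocab$pt)
    if (length(missing_pt)) {
      stop("base_rate PTs not in vocabulary: ",
           paste(missing_pt, collapse = ", "))
    }
    if (any(base_rate <= 0 | base_rate > 0.5)) {
      stop("base_rate values must lie in (0, 0.5]")
    }
  }
  if (mean_pts_per_report <= 0) stop("mean_pts_per_report must be positive")
  if (!start_quarter %in% 1:4) stop("start_quarter must be in 1..4")
  structure(list(
    n_reports = as.integer(n_reports), n_quarters = as.integer(n_quarters),
    target_drug_names = target_drug_names,
    n_other_drugs = as.integer(n_other_drugs),
    pt_vocabulary = vocab, signal_spec = signal_spec,
    exposed_fraction = exposed_fraction,
    duplicate_fraction = duplicate_fraction, tie_fraction = tie_fraction,
    missing_sex_frac = missing_sex_frac, missing_age_frac = missing_age_frac,
    missing_weight_frac = missing_weight_frac,
    missing_date_frac = missing_date_frac,
    mean_pts_per_report = mean_pts_per_report,
    base_rate = base_rate,
    start_year = as.integer(start_year),
    start_quarter = as.integer(start_quarter),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Quarter table for a config: label, year, q, calendar bounds.
config_quarters <- function(config) {
  yr <- config$start_year
  qn <- config$start_quarter
  out <- vector("list", config$n_quarters)
  for (i in seq_len(config$n_quarters)) {
    b <- quarter_bounds(yr, qn)
    out[[i]] <- data.table(idx = i, year = yr, q = qn,
                           label = quarter_label(yr, qn),
                           start = b$start, end = b$end)
    qn <- qn + 1L
    if (qn == 5L) { qn <- 1L; yr <- yr + 1L }
  }
  rbindlist(out)
}

#' Generate a synthetic FAERS-like quarterly file set
#'
#' Writes \code{n_quarters} sets of DEMO/DRUG/REAC/OUTC/THER/INDI files in
#' the dollar-delimited FAERS dialect (named \code{<TABLE><YY>Q<N>.txt}),
#' plus a \code{ground_truth.json} sidecar recording, for every PT, the
#' true reporting-rate ratio, and for every case, its exposure flag and
#' duplicate lineage with the designated dedup survivor.
#'
#' Mechanics: each report is exposed (target drug as primary suspect) with
#' probability \code{exposed_fraction}; each PT is drawn independently with
#' baseline probability p0 (log-uniform in [1e-4, 1e-2], rescaled so the
#' expected number of PTs per report matches the config) for unexposed
#' reports and min(rho * p0, 0.5) for exposed ones. Reports drawing no PT
#' receive one sampled proportionally to the rates, so every report has at
#' least one reaction. A \code{duplicate_fraction} share of cases is
#' re-submitted as a second version: later FDA_DT (or tied, at
#' \code{tie_fraction}, to exercise the PRIMARYID tie-break), and in half of
#' the dated pairs the two PRIMARYIDs are swapped so that the most recent
#' version carries the smaller id — the receipt date, not the id, must
#' decide those. FDA_DT is always a complete date; EVENT_DT and the therapy
#' START_DT degrade to partial or missing values at
#' \code{missing_date_frac}, and a small fixed share (2%) of reports get an
#' event date before therapy start to exercise time-to-onset exclusion.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{dir}, \code{files}, and
#'   \code{ground_truth} (list: \code{rho}, \code{baseline_rate},
#'   \code{exposed}, \code{lineage}).
#' @export
generate_faers <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  set.seed(config$seed)

  vocab <- config$pt_vocabulary
  J <- nrow(vocab)
  n <- config$n_reports
  qtab <- config_quarters(config)

  # per-PT event probabilities
  p0 <- exp(runif(J, log(1e-4), log(1e-2)))
  p0 <- p0 * (config$mean_pts_per_report / sum(p0))
  p0 <- pmin(p0, 0.5)
  if (!is.null(config$base_rate)) {
    p0[match(names(config$base_rate), vocab$pt)] <- unname(config$base_rate)
  }
  rho <- rep(1, J)
  if (length(config$signal_spec)) {
    rho[match(names(config$signal_spec), vocab$pt)] <- unname(config$signal_spec)
  }
  p1 <- pmin(rho * p0, 0.5)

  gt_rho <- setNames(as.list(rho), vocab$pt)
  gt_p0 <- setNames(as.list(p0), vocab$pt)

  if (n == 0L) {
    files <- write_quarter_files(dir, qtab,
                                 demo = empty_records(.faers_schema$DEMO$cols, "DEMO")[, quarter := character()],
                                 drug = empty_records(.faers_schema$DRUG$cols, "DRUG")[, quarter := character()],
                                 reac = empty_records(.faers_schema$REAC$cols, "REAC")[, quarter := character()],
                                 outc = empty_records(.faers_schema$OUTC$cols, "OUTC")[, quarter := character()],
                                 ther = empty_records(.faers_schema$THER$cols, "THER")[, quarter := character()],
                                 indi = empty_records(.faers_schema$INDI$cols, "INDI")[, quarter := character()])
    gt <- list(rho = gt_rho, baseline_rate = gt_p0,
               exposed = data.table(caseid = character(), exposed = logical()),
               lineage = data.table(caseid = character(), primaryid = character(),
                                    fda_dt = character(), survivor = logical()))
    write_ground_truth(gt, file.path(dir, "ground_truth.json"))
    return(invisible(list(dir = dir, files = files, ground_truth = gt)))
  }

  exposed <- runif(n) < config$exposed_fraction

  # reaction draws: n x J Bernoulli with exposure-dependent rates
  thr <- matrix(p0, n, J, byrow = TRUE)
  if (any(exposed)) thr[exposed, ] <- matrix(p1, sum(exposed), J, byrow = TRUE)
  hits <- matrix(runif(n * J), n, J) < thr
  none <- rowSums(hits) == 0L
  if (any(none)) {
    forced_np <- which(none & !exposed)
    forced_ex <- which(none & exposed)
    if (length(forced_np)) {
      hits[cbind(forced_np, sample.int(J, length(forced_np), replace = TRUE, prob = p0))] <- TRUE
    }
    if (length(forced_ex)) {
      hits[cbind(forced_ex, sample.int(J, length(forced_ex), replace = TRUE, prob = p1))] <- TRUE
    }
  }
  pair_idx <- which(hits, arr.ind = TRUE)
  reac0 <- data.table(report = pair_idx[, 1L], ptj = pair_idx[, 2L])
  setorder(reac0, report, ptj)

  # identifiers: FAERS-style caseid with a trailing version digit
  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # demographics
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3))
  sex_missing <- runif(n) < config$missing_sex_frac
  sex_code <- sex
  sex_code[sex_missing] <- sample(c("U", ""), sum(sex_missing), replace = TRUE)

  age_true <- pmin(pmax(rnorm(n, 45, 18), 12), 95)
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.92, 0.04, 0.04))
  age_val <- fifelse(age_cod == "YR", as.character(round(age_true)),
              fifelse(age_cod == "DEC", as.character(round(age_true / 10, 1)),
                      as.character(round(age_true * 12))))
  age_missing <- runif(n) < config$missing_age_frac
  age_val[age_missing] <- ""
  age_cod[age_missing] <- ""

  wt_true <- pmin(pmax(rnorm(n, 75, 15), 35), 160)
  wt_cod <- sample(c("KG", "LBS"), n, replace = TRUE, prob = c(0.95, 0.05))
  wt_val <- fifelse(wt_cod == "KG", as.character(round(wt_true, 1)),
                    as.character(round(wt_true / 0.453592, 1)))
  wt_missing <- runif(n) < config$missing_weight_frac
  wt_val[wt_missing] <- ""
  wt_cod[wt_missing] <- ""

  occp <- sample(c("CN", "MD", "OT", "HP", "PH", ""), n, replace = TRUE,
                 prob = c(0.503, 0.263, 0.117, 0.067, 0.025, 0.025))
  country <- sample(c("US", "JP", "FR", "CA", "GB", "DE", "IT"), n,
                    replace = TRUE,
                    prob = c(0.797, 0.043, 0.027, 0.045, 0.04, 0.028, 0.02))

  # dates: receipt date within an assigned quarter; therapy start precedes
  # the event by a log-normal time-to-onset (median ~7 days)
  q_idx <- sample.int(config$n_quarters, n, replace = TRUE)
  q_start <- qtab$start[q_idx]
  q_len <- as.integer(qtab$end[q_idx] - qtab$start[q_idx]) + 1L
  fda_date <- q_start + floor(runif(n) * q_len)
  tto_days <- round(rlnorm(n, meanlog = log(7), sdlog = 1.5))
  lag_days <- sample.int(61L, n, replace = TRUE) - 1L
  start_date <- fda_date - lag_days - tto_days
  event_date <- start_date + tto_days
  neg <- runif(n) < 0.02  # inaccurate reports: event precedes therapy start
  event_date[neg] <- start_date[neg] - sample.int(30L, sum(neg), replace = TRUE)

  event_str <- degrade_dates(event_date, config$missing_date_frac)
  start_str <- degrade_dates(start_date, config$missing_date_frac)
  fda_str <- fmt_date8(fda_date)

  demo <- data.table(primaryid = primaryid, caseid = caseid, fda_dt = fda_str,
                     event_dt = event_str, sex = sex_code, age = age_val,
                     age_cod = age_cod, wt = wt_val, wt_cod = wt_cod,
                     occp_cod = occp, reporter_country = country,
                     quarter = qtab$label[q_idx])

  # drugs: one primary suspect per report plus concomitants
  target_variants <- unique(c(
    toupper(config$target_drug_names),
    paste0(toupper(config$target_drug_names[1]), " 10MG"),
    "VORTIOXETINE HYDROBROMIDE",
    "Vortioxetine  Hydrobromide 20 MG"))
  other_universe <- sprintf("DRUG %02d", seq_len(config$n_other_drugs))
  ps_name <- character(n)
  ps_ai <- character(n)
  ps_name[exposed] <- sample(target_variants, sum(exposed), replace = TRUE)
  ps_ai[exposed] <- sample(c("VORTIOXETINE HYDROBROMIDE", ""), sum(exposed),
                           replace = TRUE, prob = c(0.7, 0.3))
  ps_name[!exposed] <- sample(other_universe, sum(!exposed), replace = TRUE)
  ps_ai[!exposed] <- ""

  n_con <- pmin(rpois_int(n, 1.2), 4L)
  con_report <- rep(seq_len(n), n_con)
  con_names <- sample(other_universe, length(con_report), replace = TRUE)
  con_roles <- sample(c("C", "SS", "I"), length(con_report), replace = TRUE,
                      prob = c(0.7, 0.2, 0.1))
  # decoys: target drug present but NOT as primary suspect (must not enter
  # the cohort under the role filter)
  decoy <- which(!exposed & runif(n) < 0.01)
  con_report <- c(con_report, decoy)
  con_names <- c(con_names, sample(target_variants, length(decoy), replace = TRUE))
  con_roles <- c(con_roles, sample(c("C", "SS"), length(decoy), replace = TRUE))
  con_ord <- order(con_report)
  con_report <- con_report[con_ord]
  con_names <- con_names[con_ord]
  con_roles <- con_roles[con_ord]
  con_seq <- sequence(tabulate(con_report, nbins = n)) + 1L

  drug <- rbind(
    data.table(report = seq_len(n), drug_seq = 1L, role_cod = "PS",
               drugname = ps_name, prod_ai = ps_ai),
    data.table(report = con_report, drug_seq = con_seq, role_cod = con_roles,
               drugname = con_names, prod_ai = "")
  )
  setorder(drug, report, drug_seq)

  # outcomes: at most one report in three carries any outcome; the code is
  # sampled with death/hospitalization rare, "other serious" dominant
  has_outc <- runif(n) < 0.313
  outc_codes <- c("OT", "HO", "DE", "LT", "DS", "CA", "RI")
  outc_prob <- c(2035, 961, 236, 154, 132, 11, 6)
  outc <- data.table(report = which(has_outc),
                     outc_cod = sample(outc_codes, sum(has_outc),
                                       replace = TRUE, prob = outc_prob))

  ther <- data.table(report = seq_len(n), dsg_drug_seq = 1L,
                     start_dt = start_str)
  indi_pool_target <- c("Major depressive disorder", "Depression")
  indi_pool_other <- c("Hypertension", "Diabetes mellitus", "Pain", "Asthma")
  indi <- data.table(report = seq_len(n), indi_drug_seq = 1L,
                     indi_pt = fifelse(exposed,
                       sample(indi_pool_target, n, replace = TRUE),
                       sample(indi_pool_other, n, replace = TRUE)))

  # duplicate versions: same case content, new primaryid, later or tied
  # receipt date
  ndup <- round(config$duplicate_fraction * n)
  lineage <- data.table(caseid = caseid, primaryid = primaryid,
                        fda_dt = fda_str, survivor = TRUE)
  dup_demo <- NULL
  if (ndup > 0L) {
    dup_idx <- sort(sample.int(n, ndup))
    tie <- runif(ndup) < config$tie_fraction
    delta <- integer(ndup)
    delta[!tie] <- sample.int(90L, sum(!tie), replace = TRUE)
    dup_date <- pmin(fda_date[dup_idx] + delta, max(qtab$end))
    # a tied pair can collapse onto the same date as the original even when
    # a positive delta was clipped to the window end; treat those as ties too
    tie <- dup_date == fda_date[dup_idx]
    pid_v1 <- primaryid[dup_idx]
    pid_v2 <- paste0(caseid[dup_idx], "2")
    # for half of the pairs, swap ids: in dated pairs the later version
    # then carries the smaller primaryid (FDA_DT, not the id, must decide),
    # and in tied pairs the tie-break must pick either member
    swap <- runif(ndup) < 0.5
    pid_new <- pid_v2
    pid_new[swap] <- pid_v1[swap]
    pid_old <- pid_v1
    pid_old[swap] <- pid_v2[swap]
    primaryid[dup_idx] <- pid_old
    demo[dup_idx, primaryid := pid_old]
    lineage[dup_idx, primaryid := pid_old]
    # survivor: later FDA_DT wins; on a tie, the higher primaryid
    surv_new <- !tie | (as.numeric(pid_new) > as.numeric(pid_old))
    dup_quarter <- qtab$label[findInterval(as.numeric(dup_date),
                                           as.numeric(qtab$start))]
    dup_demo <- copy(demo[dup_idx])
    dup_demo[, primaryid := pid_new]
    dup_demo[, fda_dt := fmt_date8(dup_date)]
    dup_demo[, quarter := dup_quarter]
    lineage[dup_idx, survivor := !surv_new]
    lineage <- rbind(lineage,
                     data.table(caseid = caseid[dup_idx], primaryid = pid_new,
                                fda_dt = fmt_date8(dup_date), survivor = surv_new))
    demo <- rbind(demo, dup_demo)
  }
  setorder(lineage, caseid, primaryid)

  # expand row tables to primaryids (duplicates replicate case content)
  pid_of_report <- primaryid
  quarter_of_pid <- setNames(demo$quarter, demo$primaryid)

  attach_pid <- function(dt) {
    out <- copy(dt)
    out[, primaryid := pid_of_report[report]]
    if (!is.null(dup_demo) && nrow(dup_demo)) {
      rep_of_case <- setNames(seq_len(n), caseid)
      map <- data.table(report = rep_of_case[dup_demo$caseid],
                        new_pid = dup_demo$primaryid)
      extra <- merge(map, dt, by = "report", allow.cartesian = TRUE)
      if (nrow(extra)) {
        extra[, primaryid := new_pid]
        extra[, new_pid := NULL]
        out <- rbind(out, extra, use.names = TRUE)
      }
    }
    out[, quarter := quarter_of_pid[primaryid]]
    out[, report := NULL]
    out[]
  }

  reac_rows <- attach_pid(reac0)
  reac_rows[, pt := vocab$pt[ptj]]
  reac_rows[, ptj := NULL]
  drug_rows <- attach_pid(drug)
  outc_rows <- attach_pid(outc)
  ther_rows <- attach_pid(ther)
  indi_rows <- attach_pid(indi)

  files <- write_quarter_files(dir, qtab, demo = demo, drug = drug_rows,
                               reac = reac_rows, outc = outc_rows,
                               ther = ther_rows, indi = indi_rows)

  gt <- list(rho = gt_rho, baseline_rate = gt_p0,
             exposed = data.table(caseid = caseid, exposed = exposed),
             lineage = lineage)
  write_ground_truth(gt, file.path(dir, "ground_truth.json"))
  invisible(list(dir = dir, files = files, ground_truth = gt))
}

# Poisson draw returned as integer (thin wrapper kept for seeding clarity)
rpois_int <- function(n, lambda) as.integer(stats::rpois(n, lambda))

# Degrade full dates: at `frac`, a date becomes missing (40%), YYYYMM (40%)
# or YYYY (20%).
degrade_dates <- function(dates, frac) {
  out <- fmt_date8(dates)
  n <- length(out)
  hit <- runif(n) < frac
  mode <- sample(c("miss", "ym", "y"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  out[hit & mode == "miss"] <- ""
  out[hit & mode == "ym"] <- substr(out[hit & mode == "ym"], 1, 6)
  out[hit & mode == "y"] <- substr(out[hit & mode == "y"], 1, 4)
  out
}

write_quarter_files <- function(dir, qtab, demo, drug, reac, outc, ther, indi) {
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
               THER = ther, INDI = indi)
  files <- character()
  for (i in seq_len(nrow(qtab))) {
    lab <- qtab$label[i]
    for (kind in names(tabs)) {
      dt <- tabs[[kind]]
      sub <- if (nrow(dt)) dt[quarter == lab] else dt
      path <- file.path(dir, sprintf("%s%s.txt", kind, lab))
      write_faers_table(sub, path, kind)
      files <- c(files, path)
    }
  }
  files
}

write_ground_truth <- function(gt, path) {
  payload <- list(
    rho = gt$rho,
    baseline_rate = gt$baseline_rate,
    exposed = gt$exposed,
    lineage = gt$lineage
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a generated ground-truth sidecar
#'
#' @param path path to \code{ground_truth.json}.
#' @return list with \code{rho} (named numeric), \code{baseline_rate},
#'   \code{exposed} and \code{lineage} data.tables.
#' @export
read_ground_truth <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(rho = unlist(g$rho),
       baseline_rate = unlist(g$baseline_rate),
       exposed = as.data.table(g$exposed),
       lineage = as.data.table(g$lineage))
}

#' Build a synthetic PT -> SOC dictionary
#'
#' Emits a two-level MedDRA-style mapping: every PT gets a distinct 8-digit
#' numeric code and belongs to exactly one SOC (a PT listed under two SOCs
#' is an error). This synthetic dictionary stands in for the licensed
#' terminology a production run would supply.
#'
#' @param config a [synthetic_config()] (its \code{pt_vocabulary} is used).
#' @param path optional file path; when given, the dictionary is written as
#'   a tab-separated file with columns pt_code, pt_name, soc_code, soc_name.
#' @return the dictionary \code{data.table}.
#' @export
make_dictionary <- function(config, path = NULL) {
  vocab <- as.data.table(config$pt_vocabulary)
  if (nrow(vocab) == 0L) stop("empty pt_vocabulary")
  if (anyDuplicated(vocab$pt)) {
    stop("duplicate PT names (a PT may map to only one SOC): ",
         paste(unique(vocab$pt[duplicated(vocab$pt)]), collapse = ", "))
  }
  socs <- unique(vocab$soc)
  dict <- data.table(
    pt_code = sprintf("%08d", 10000000L + seq_len(nrow(vocab))),
    pt_name = vocab$pt,
    soc_code = sprintf("%08d", 10090000L + match(vocab$soc, socs)),
    soc_name = vocab$soc
  )
  if (!is.null(path)) {
    fwrite(dict, path, sep = "\t")
  }
  dict
}

#' Read a PT -> SOC dictionary file
#'
#' @param path tab-separated file with columns pt_code, pt_name, soc_code,
#'   soc_name (as written by [make_dictionary()]).
#' @return a \code{data.table} with those columns plus \code{pt_norm}, the
#'   normalized PT name used for joining.
#' @export
read_dictionary <- function(path) {
  dict <- fread(path, sep = "\t", colClasses = "character")
  need <- c("pt_code", "pt_name", "soc_code", "soc_name")
  if (!all(need %in% names(dict))) {
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(normalize_name(dict$pt_name))) {
    stop("duplicate PT names in dictionary")
  }
  dict[, pt_norm := normalize_name(pt_name)]
  dict[]
}
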