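#' Run the full surveillance analysis end to end
#'
#' Single entry point over the whole chain: ingest (or synthesize)
#' quarterly tables, deduplicate, assemble the target-drug cohort, compute
#' PT- and SOC-level disproportionality signals, produce the demographic /
#' annual / time-to-onset summaries, and write every table plus a JSON run
#' manifest. With a fixed config (and, in synthetic mode, seed) the
#' emitted tables are byte-identical across runs.
#'
#' @param input_dir directory of FAERS-style quarterly files, or NULL when
#'   \code{synthetic} is given (exactly one of the two).
#' @param synthetic a [synthetic_config()]; the quarterly files are
#'   generated under \code{output_dir/synthetic_data} and analyzed.
#' @param output_dir where all outputs are written (created if needed).
#' @param dictionary path to a PT -> SOC dictionary file; required with
#'   \code{input_dir}, defaulted to the generated dictionary in synthetic
#'   mode.
#' @param cohort a [cohort_config()].
#' @param criteria a [signal_criteria()].
#' @param min_cases_for_report events with fewer cases are dropped from the
#'   formatted signal tables (audit tables keep everything); default 3,
#'   the usual case minimum (forest-plot style figures often raise it
#'   to 20).
#' @param unit counting unit for contingency tables, \code{"pair"} or
#'   \code{"report"}.
#' @param ic_variance,kappa,zero_correction passed to [compute_signals()].
#' @return invisibly, the manifest list (also written as
#'   \code{manifest.json}): config echo, input file checksums, per-stage
#'   record counts, package version.
#' @export
run_pipeline <- function(input_dir = NULL, synthetic = NULL,
                         output_dir, dictionary = NULL,
                         cohort = cohort_config(),
                         criteria = signal_criteria(),
                         min_cases_for_report = 3L,
                         unit = c("pair", "report"),
                         ic_variance = c("delta", "fixed"), kappa = 1.66,
                         zero_correction = c("none", "haldane")) {
  unit <- match.arg(unit)
  ic_variance <- match.arg(ic_variance)
  zero_correction <- match.arg(zero_correction)
  if (is.null(input_dir) == is.null(synthetic)) {
    stop("give exactly one of input_dir or synthetic")
  }
  if (min_cases_for_report < 1) stop("min_cases_for_report must be >= 1")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    data_dir <- file.path(output_dir, "synthetic_data")
    gen <- generate_faers(synthetic, data_dir)
    input_dir <- data_dir
    if (is.null(dictionary)) {
      dictionary <- file.path(data_dir, "dictionary.tsv")
      make_dictionary(synthetic, dictionary)
    }
  }
  if (is.null(dictionary)) stop("a dictionary path is required")
  dict <- read_dictionary(dictionary)

  ingest <- read_faers_quarters(input_dir)
  fwrite(ingest$rejects, file.path(output_dir, "rejects.tsv"), sep = "\t")

  coh <- build_cohort(ingest$tables, cohort)
  fwrite(coh$demo, file.path(output_dir, "cohort_reports.tsv"), sep = "\t")

  tab_pt <- build_tables(coh, dict, level = "PT", unit = unit)
  tab_soc <- build_tables(coh, dict, level = "SOC", unit = unit)
  sig_pt <- compute_signals(tab_pt, criteria, ic_variance = ic_variance,
                            kappa = kappa, zero_correction = zero_correction)
  sig_soc <- compute_signals(tab_soc, criteria, ic_variance = ic_variance,
                             kappa = kappa, zero_correction = zero_correction)

  # audit files carry the raw counts so every emitted signal row can be
  # recomputed from its 2x2 table
  fwrite(tab_pt, file.path(output_dir, "contingency_pt.tsv"), sep = "\t")
  fwrite(tab_soc, file.path(output_dir, "contingency_soc.tsv"), sep = "\t")
  fwrite(format_signal_table(sig_pt, min_cases = min_cases_for_report),
         file.path(output_dir, "signals_pt.tsv"), sep = "\t")
  fwrite(format_signal_table(sig_soc, min_cases = 1L),
         file.path(output_dir, "signals_soc.tsv"), sep = "\t")
  fwrite(forest_data(sig_pt, min_cases = min_cases_for_report),
         file.path(output_dir, "forest_pt.tsv"), sep = "\t")

  demog <- summarize_demographics(coh)
  demog_long <- rbindlist(lapply(
    c("sex", "age", "weight", "reporter", "country", "outcome"),
    function(blk) data.table(breakdown = blk, demog[[blk]])))
  fwrite(demog_long, file.path(output_dir, "demographics.tsv"), sep = "\t")

  annual <- annual_distribution(coh)
  fwrite(annual, file.path(output_dir, "annual_counts.tsv"), sep = "\t")

  tto <- time_to_onset(coh)
  tto_tab <- data.table(
    statistic = c("n_evaluable", "n_excluded", "median_days", "q1", "q3",
                  "frac_within_30d"),
    value = c(tto$n_evaluable, tto$n_excluded, tto$median_days, tto$q1,
              tto$q3, tto$frac_within_30d))
  fwrite(tto_tab, file.path(output_dir, "tto_summary.tsv"), sep = "\t")
  fwrite(tto$histogram, file.path(output_dir, "tto_histogram.tsv"), sep = "\t")

  input_files <- sort(list.files(input_dir, pattern = "\\.txt$",
                                 full.names = TRUE))
  checksums <- tools::md5sum(input_files)
  names(checksums) <- basename(input_files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("faersignal")),
    mode = if (is.null(synthetic)) "directory" else "synthetic",
    seed = if (is.null(synthetic)) NULL else synthetic$seed,
    config = list(
      cohort = unclass(cohort),
      criteria = unclass(criteria),
      unit = unit, ic_variance = ic_variance,
      zero_correction = zero_correction,
      min_cases_for_report = min_cases_for_report),
    input_checksums = as.list(checksums),
    counts = c(coh$log, list(
      rejected_rows = nrow(ingest$rejects),
      pt_events = nrow(tab_pt),
      soc_events = nrow(tab_soc),
      pt_consensus_signals = sum(sig_pt$consensus),
      soc_consensus_signals = sum(sig_soc$consensus),
      tto_evaluable = tto$n_evaluable))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
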