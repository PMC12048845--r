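## Report generation and serialization: the published-style outcome table,
## severity-stratified counts, cumulative-QALY trajectories, and run
## metadata sufficient to reproduce the run.

REPORT_ROWS <- c("ischemic_stroke", "major_bleeding", "hemorrhagic_stroke",
                 "other_intracranial_bleeding", "extracranial_major_bleeding",
                 "deaths", "life_years", "qalys")

#' Build a report bundle from a completed two-arm run
#'
#' Assembles the fixed outcome-table rows (event counts per cohort,
#' life-years, QALYs, differences and per-patient differences, with the
#' difference taken as with-NOAC minus without-NOAC), severity-stratified
#' event counts, per-cycle cumulative-QALY curves for both arms, and run
#' metadata (seed, package version, config hash).
#'
#' @param summary A `decision_summary`.
#' @param config The `model_config` that produced it (for metadata); if
#'   omitted, only version metadata is recorded.
#' @return A `report_bundle`.
#' @export
build_report <- function(summary, config = NULL) {
  stopifnot(inherits(summary, "decision_summary"))
  if (is.null(summary$without$trajectories) ||
      nrow(summary$without$trajectories) != summary$horizon) {
    abort("Incomplete cycle ledger: trajectories must cover every cycle.")
  }
  tab <- summary$table
  stopifnot(identical(tab$outcome, REPORT_ROWS))
  sev <- dplyr::bind_rows(
    dplyr::mutate(summary$without$severity_counts, arm = "without_noac"),
    dplyr::mutate(summary$with_noac$severity_counts, arm = "with_noac")
  )
  traj <- dplyr::bind_rows(
    dplyr::mutate(summary$without$trajectories, arm = "without_noac"),
    dplyr::mutate(summary$with_noac$trajectories, arm = "with_noac")
  )
  meta <- list(
    package_version = as.character(packageVersion("noacaf")),
    mode = summary$mode,
    n_patients = summary$n_patients,
    horizon = summary$horizon,
    seed = if (!is.null(config)) config$rng_seed else NA_integer_,
    config_name = if (!is.null(config)) config$name else NA_character_,
    config_hash = if (!is.null(config)) rlang::hash(unclass(config)) else NA_character_
  )
  structure(list(summary_table = tab, severity_counts = sev,
                 trajectories = traj, metadata = meta),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle: %s patients/arm, %s cycles, config %s>\n",
              x$metadata$n_patients, x$metadata$horizon,
              x$metadata$config_name))
  print(as.data.frame(x$summary_table), digits = 5, row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Deterministic file names: `summary.csv` / `summary.json` (outcome table
#' plus metadata), `severity_counts.csv`, and `trajectory_<arm>.csv` (one
#' row per cycle). The JSON file round-trips losslessly through
#' [read_report_bundle()].
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(bundle, dir, formats = c("csv", "json")) {
  stopifnot(inherits(bundle, "report_bundle"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if ("csv" %in% formats) {
    f <- file.path(dir, "summary.csv")
    write.csv(bundle$summary_table, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "severity_counts.csv")
    write.csv(bundle$severity_counts, f, row.names = FALSE)
    files <- c(files, f)
    for (arm in unique(bundle$trajectories$arm)) {
      f <- file.path(dir, paste0("trajectory_", arm, ".csv"))
      write.csv(bundle$trajectories[bundle$trajectories$arm == arm,
                                    names(bundle$trajectories) != "arm"],
                f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(
      list(summary_table = bundle$summary_table,
           severity_counts = bundle$severity_counts,
           trajectories = bundle$trajectories,
           metadata = bundle$metadata),
      f, auto_unbox = TRUE, digits = NA, na = "null"
    )
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a report bundle back from its JSON serialization
#'
#' @param dir Directory previously written by [write_outputs()].
#' @return A `report_bundle`.
#' @export
read_report_bundle <- function(dir) {
  f <- file.path(dir, "summary.json")
  if (!file.exists(f)) abort(sprintf("No summary.json under %s", dir))
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  structure(list(summary_table = tibble::as_tibble(x$summary_table),
                 severity_counts = tibble::as_tibble(x$severity_counts),
                 trajectories = tibble::as_tibble(x$trajectories),
                 metadata = x$metadata),
            class = "report_bundle")
}
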