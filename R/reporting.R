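# Publication-shaped outputs: the headline scenario table, tidy/JSON exports
# and run manifests.

fmt_count <- function(x) format(round_half_up(x), big.mark = ",",
                                scientific = FALSE, trim = TRUE)

#' Render the headline scenario table
#'
#' Lays out the five scenarios side by side in the published shape: people
#' screened, the screened comparisons (each scenario vs baseline, 3 vs 1,
#' 4 vs 2), new CRC cases, the screen-/symptom-detected split with percent
#' shares in parentheses, the case comparisons, and early-stage cases with
#' their share of all cases. Counts are rounded half-away-from-zero to whole
#' persons; comparisons are computed on unrounded values and then rounded.
#' This render uses thousands separators; the machine-readable exports from
#' [write_run_outputs()] do not.
#'
#' @param runs A `crc_run_set` from [run_all_published_scenarios()].
#' @param path Optional CSV destination.
#' @return A character data frame (rows = table rows, columns = scenarios),
#'   invisibly written to `path` if given.
#' @export
render_table3 <- function(runs, path = NULL) {
  oc <- runs$outcomes
  need <- c("baseline", "scenario1", "scenario2", "scenario3", "scenario4")
  if (!all(need %in% names(oc))) {
    stop("runs must contain the five published scenarios", call. = FALSE)
  }
  oc <- oc[need]
  tot <- function(name) vapply(oc, function(o) o$totals[[name]], numeric(1))
  pct_of_cases <- function(name) 100 * tot(name) / tot("total_cases")
  count_pct <- function(name) sprintf("%s (%.1f)", fmt_count(tot(name)),
                                      pct_of_cases(name))

  cmp_row <- function(outcome, pairs) {
    # pairs: named list scenario -> comparison (absolute is comparator-ref)
    row <- stats::setNames(rep("NA", 5), need)
    for (nm in names(pairs)) {
      d <- pairs[[nm]]
      i <- d$outcome == outcome
      row[nm] <- sprintf("%s (%+.1f)", fmt_count(abs(d$absolute[i])),
                         d$percent[i])
    }
    row
  }
  cm <- runs$comparisons
  vs_base <- function(outcome) {
    row <- cmp_row(outcome, list(
      scenario1 = cm$scenario1_vs_baseline, scenario2 = cm$scenario2_vs_baseline,
      scenario3 = cm$scenario3_vs_baseline, scenario4 = cm$scenario4_vs_baseline))
    row["baseline"] <- "1 [Reference]"
    row
  }
  row3v1 <- function(outcome) {
    row <- cmp_row(outcome, list(scenario3 = cm$scenario3_vs_scenario1))
    row["scenario1"] <- "1 [Reference]"
    row
  }
  row4v2 <- function(outcome) {
    row <- cmp_row(outcome, list(scenario4 = cm$scenario4_vs_scenario2))
    row["scenario2"] <- "1 [Reference]"
    row
  }

  tbl <- rbind(
    "People who complete CRC screening, No." = fmt_count(tot("screened_total")),
    "Screened, scenario vs baseline" = vs_base("screened_total"),
    "Screened, scenario 3 vs 1" = row3v1("screened_total"),
    "Screened, scenario 4 vs 2" = row4v2("screened_total"),
    "New CRC cases, No." = fmt_count(tot("total_cases")),
    "Screening detected CRC, No. (%)" = count_pct("screen_detected_total"),
    "Symptom detected CRC, No. (%)" = count_pct("symptom_detected"),
    "Cases, scenario vs baseline" = vs_base("total_cases"),
    "Cases, scenario 3 vs 1" = row3v1("total_cases"),
    "Cases, scenario 4 vs 2" = row4v2("total_cases"),
    "Early stage CRC, No. (%)" = count_pct("early_stage_cases")
  )
  out <- data.frame(row = rownames(tbl), tbl, row.names = NULL,
                    check.names = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Tidy long-format outcomes
#'
#' @param runs A `crc_run_set`.
#' @return Data frame with one row per scenario x outcome x year (plus
#'   `"total"` rows), no thousands separators.
#' @export
tidy_outcomes <- function(runs) {
  rows <- lapply(runs$outcomes, function(o) {
    yearly <- do.call(rbind, lapply(seq_len(nrow(o$by_year)), function(i) {
      data.frame(scenario = o$scenario_id, outcome = OUTCOME_NAMES,
                 year = as.character(o$by_year$year[i]),
                 value = as.numeric(o$by_year[i, OUTCOME_NAMES]))
    }))
    totals <- data.frame(scenario = o$scenario_id, outcome = OUTCOME_NAMES,
                         year = "total", value = unname(o$totals[OUTCOME_NAMES]))
    rbind(yearly, totals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write machine-readable run outputs plus a run manifest
#'
#' Writes the tidy long-format CSV, the headline-table CSV, a JSON export of
#' every scenario's totals and per-year outcomes, and a `manifest.json`
#' recording the timestamp, package version, parameter-file hash (when a
#' file is given), scenario ids, seed and the output file list. Output files
#' are byte-identical across reruns with the same inputs; only the manifest
#' timestamp differs.
#'
#' @param runs A `crc_run_set`.
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"`, `"json"`, or both.
#' @param seed Optional seed to record in the manifest.
#' @param params_file Optional parameter file path; hashed into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_run_outputs <- function(runs, out_dir, format = c("csv", "json"),
                              seed = NULL, params_file = NULL) {
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if ("csv" %in% format) {
    f <- file.path(out_dir, "outcomes_tidy.csv")
    utils::write.csv(tidy_outcomes(runs), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "scenario_table.csv")
    render_table3(runs, f)
    files <- c(files, f)
  }
  if ("json" %in% format) {
    f <- file.path(out_dir, "outcomes.json")
    payload <- lapply(runs$outcomes, function(o) list(
      scenario_id = o$scenario_id,
      q_undiagnosed = o$q_undiagnosed,
      totals = as.list(o$totals),
      by_year = o$by_year
    ))
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, f)
  }
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("crcscreen")),
    parameter_file = if (is.null(params_file)) NULL else params_file,
    parameter_file_md5 = if (is.null(params_file)) NULL else
      unname(tools::md5sum(params_file)),
    scenario_ids = names(runs$outcomes),
    q_undiagnosed = runs$params$symptomatic$q_undiagnosed,
    seed = seed,
    files = basename(files)
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, mf))
}
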