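#' Assemble the full quarterly monitoring report
#'
#' Runs every indicator for the given quarter and collects the results into a
#' `quarterly_report` with exactly 14 top-level indicator blocks (some with
#' sub-parts), plus provenance (engine version, configuration hash) and
#' footnotes describing the active conventions. Generation is pure: the same
#' store, quarter and configuration always produce an identical report.
#'
#' @param store an [event_store()].
#' @param quarter quarter label, e.g. `"2020Q4"`.
#' @param cfg an [indicator_config()].
#' @return an object of class `quarterly_report`.
#' @export
build_quarterly_report <- function(store, quarter, cfg = indicator_config()) {
  assert_quarter(quarter)
  qend <- quarter_end(quarter)
  ev <- with_effective_dates(store$dispensations)
  if (!nrow(ev) || min(ev$effective_date) > qend) {
    warning("quarter ", quarter, " precedes the first event; report has zero counts",
            call. = FALSE)
  }
  tl <- status_timelines(store, cfg)
  pv <- provider_volume(store, quarter, cfg)
  rf <- risk_factor_profile(store, quarter, cfg)

  blocks <- list(
    "1" = list(dispensed_distribution(store, quarter, "gender", cfg)),
    "2" = list(dispensed_distribution(store, quarter, "age", cfg)),
    "3" = list(dispensed_distribution(store, quarter, "ha_residence", cfg),
               dispensed_distribution(store, quarter, "ha_practice", cfg)),
    "4" = list(new_enrolments(store, quarter, "provider_type", cfg)),
    "5" = list(new_enrolments(store, quarter, "ha_residence", cfg),
               new_enrolments(store, quarter, "ha_practice", cfg)),
    "6" = list(first_dispensations(store, quarter, "ha_residence", cfg),
               first_dispensations(store, quarter, "ha_practice", cfg)),
    "7" = list(pv$a, pv$b),
    "8" = list(rf$a, rf$b),
    "9" = list(status_counts(store, quarter, cfg, timelines = tl)),
    "10" = list(usage_type_distribution(store, quarter, cfg, timelines = tl)),
    "11" = list(quantity_dispensed(store, quarter, "ha_residence", cfg),
                quantity_dispensed(store, quarter, "ha_practice", cfg)),
    "12" = list(testing_coverage(store, quarter, "syphilis", cfg, timelines = tl),
                incident = incident_cases(store, quarter, "syphilis",
                                          require_active = TRUE, cfg, timelines = tl)),
    "13" = list(gap_summary = days_to_first_dispensation(store, cfg, as_of = qend),
                testing_coverage(store, quarter, "hiv", cfg, timelines = tl)),
    "14" = list(adr = adr_event_count(store, quarter, cfg))
  )

  structure(list(
    quarter = quarter,
    blocks = blocks,
    cfg = cfg,
    provenance = list(engine_version = as.character(utils::packageVersion("prepmonitor")),
                      config_hash = rlang::hash(unclass(cfg))),
    footnotes = c(
      sprintf("testing-coverage window: %g days before to %g days after dispensation (inclusive endpoints: %s/%s)",
              cfg$lookback_days, cfg$grace_days,
              cfg$window_inclusive[1], cfg$window_inclusive[2]),
      sprintf("lapse rule: %s (>%d months; cutover quarter %s)",
              cfg$lapse_rule, cfg$lapse_months, cfg$status_cutover_quarter),
      sprintf("non-daily days of supply use a %gx tablet stretch factor",
              cfg$non_daily_stretch),
      sprintf("small-cell suppression threshold: %d", cfg$suppression_threshold))
  ), class = "quarterly_report")
}

#' @export
print.quarterly_report <- function(x, ...) {
  cat(sprintf("<quarterly_report> %s | %d indicator blocks\n",
              x$quarter, length(x$blocks)))
  invisible(x)
}

block_titles <- c(
  "1" = "Client gender identity",
  "2" = "Client age",
  "3" = "Health authority",
  "4" = "New BC-PrEP clients enrolled by provider type",
  "5" = "New BC-PrEP clients enrolled by health authority",
  "6" = "New BC-PrEP clients dispensed PrEP",
  "7" = "BC-PrEP clients per provider",
  "8" = "Key qualifying HIV risk factor(s) reported at enrolment",
  "9" = "BC-PrEP client status (active vs inactive)",
  "10" = "PrEP usage type among BC-PrEP clients",
  "11" = "PrEP quantity dispensed (per 30-tablet supply)",
  "12" = "Infectious syphilis testing and incident cases",
  "13" = "HIV testing",
  "14" = "Adverse drug reaction events")

#' Flatten a quarterly report to a tidy table
#'
#' One row per reported cell: stratified strata, the incident-case count, the
#' days-to-first-dispensation summary and the ADR triple all become rows with
#' columns `indicator`, `part`, `dimension`, `quarter`, `stratum`,
#' `numerator`, `denominator`, `percent`, `suppressed`. Scalar cells carry an
#' `NA` denominator and percent.
#'
#' @param report a [build_quarterly_report()] result.
#' @return a tibble.
#' @export
report_to_tidy <- function(report) {
  scalar_row <- function(indicator, part, stratum, value) {
    tibble::tibble(indicator = indicator, part = part, dimension = "",
                   quarter = report$quarter, stratum = stratum,
                   numerator = as.numeric(value), denominator = NA_real_,
                   percent = NA_integer_, suppressed = FALSE)
  }
  rows <- list()
  for (id in names(report$blocks)) {
    for (el_name in seq_along(report$blocks[[id]])) {
      el <- report$blocks[[id]][[el_name]]
      nm <- names(report$blocks[[id]])[el_name]
      if (inherits(el, "stratified_result")) {
        rows[[length(rows) + 1L]] <- as_tibble(el)
      } else if (identical(nm, "incident")) {
        rows[[length(rows) + 1L]] <- scalar_row(id, "b", "incident_clients", el)
      } else if (identical(nm, "gap_summary")) {
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          scalar_row(id, "a", "n", el$n),
          scalar_row(id, "a", "median", el$median),
          scalar_row(id, "a", "p25", el$p25),
          scalar_row(id, "a", "p75", el$p75),
          scalar_row(id, "a", "n_no_prior_test", el$n_no_prior_test))
      } else if (identical(nm, "adr")) {
        rows[[length(rows) + 1L]] <- dplyr::bind_rows(
          scalar_row(id, "", "events", el$events),
          scalar_row(id, "", "distinct_clients", el$distinct_clients),
          scalar_row(id, "", "discontinuation_linked", el$discontinuation_linked))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Apply small-cell suppression to a report
#'
#' Any stratum numerator strictly between 0 and `cfg$suppression_threshold`
#' is flagged suppressed. Within partition blocks, complementary suppression
#' is applied: when exactly one cell of a partition is suppressed its value
#' could be recovered by subtraction from the denominator, so the smallest
#' remaining positive cell is suppressed as well. Suppression only sets
#' flags; counts in the report object are unchanged, and writers render
#' flagged cells as a mask token.
#'
#' @param report a [build_quarterly_report()] result.
#' @param cfg an [indicator_config()]; defaults to the report's own.
#' @return the report with suppression flags set.
#' @export
suppress_small_cells <- function(report, cfg = NULL) {
  if (is.null(cfg)) cfg <- report$cfg
  thr <- cfg$suppression_threshold
  if (thr <= 0) return(report)
  for (id in names(report$blocks)) {
    for (i in seq_along(report$blocks[[id]])) {
      el <- report$blocks[[id]][[i]]
      if (!inherits(el, "stratified_result")) next
      num <- el$rows$numerator
      supp <- num > 0 & num < thr
      if (el$partition && sum(supp) == 1L) {
        candidates <- which(!supp & num > 0)
        if (length(candidates)) {
          supp[candidates[which.min(num[candidates])]] <- TRUE
        }
      }
      el$rows$suppressed <- supp
      report$blocks[[id]][[i]] <- el
    }
  }
  report
}

mask_tidy <- function(tidy, mask = "*") {
  tidy %>%
    mutate(numerator = ifelse(.data$suppressed, NA_real_, .data$numerator),
           percent = ifelse(.data$suppressed, NA_integer_, .data$percent))
}

#' Write a quarterly report to disk
#'
#' * `csv`: the tidy schema of [report_to_tidy()]; suppressed cells have
#'   empty numerator/percent fields and `suppressed = TRUE`.
#' * `json`: the tidy rows plus quarter, provenance and footnotes.
#' * `markdown`: one section per indicator with its title; suppressed cells
#'   render as `*`.
#'
#' @param report a [build_quarterly_report()] result.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, format = c("csv", "json", "markdown"), path) {
  format <- match.arg(format)
  tidy <- report_to_tidy(report)
  masked <- mask_tidy(tidy)
  if (format == "csv") {
    readr::write_csv(masked, path, na = "")
  } else if (format == "json") {
    payload <- list(quarter = report$quarter,
                    provenance = report$provenance,
                    footnotes = report$footnotes,
                    rows = masked)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    lines <- c(sprintf("# Quarterly PrEP monitoring report: %s", report$quarter), "")
    for (id in names(block_titles)) {
      sub <- masked %>% filter(.data$indicator == id)
      lines <- c(lines, sprintf("## Indicator %s. %s", id, block_titles[[id]]), "")
      lines <- c(lines, "| part | dimension | stratum | n | denominator | % |",
                 "|---|---|---|---|---|---|")
      fmt_num <- function(v, suppressed) {
        ifelse(suppressed, "*", ifelse(is.na(v), "", format(round(v, 1))))
      }
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |",
                                sub$part, sub$dimension, sub$stratum,
                                fmt_num(sub$numerator, sub$suppressed),
                                fmt_num(sub$denominator, FALSE),
                                ifelse(sub$suppressed, "*",
                                       ifelse(is.na(sub$percent), "",
                                              as.character(sub$percent)))))
      lines <- c(lines, "")
    }
    lines <- c(lines, "---", paste0("- ", report$footnotes))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a report written as CSV or JSON
#'
#' Returns the tidy row table (see [report_to_tidy()]); used for round-trip
#' checks and downstream analysis.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"` (guessed from the extension by default).
#' @return a tibble.
#' @export
read_report_tidy <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(
      indicator = readr::col_character(), part = readr::col_character(),
      dimension = readr::col_character(), quarter = readr::col_character(),
      stratum = readr::col_character(), numerator = readr::col_double(),
      denominator = readr::col_double(), percent = readr::col_integer(),
      suppressed = readr::col_logical()), na = "", progress = FALSE,
      show_col_types = FALSE) %>%
      mutate(part = coalesce(.data$part, ""),
             dimension = coalesce(.data$dimension, ""))
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    tibble::as_tibble(raw$rows) %>%
      mutate(numerator = as.numeric(.data$numerator),
             denominator = as.numeric(.data$denominator),
             percent = as.integer(.data$percent),
             part = coalesce(.data$part, ""),
             dimension = coalesce(.data$dimension, ""))
  }
}
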