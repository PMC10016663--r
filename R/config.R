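#' Indicator configuration
#'
#' All numeric conventions used by the indicator engine live in one object so
#' that every convention is auditable and serializable. Defaults reproduce the
#' program's published calculation rules:
#'
#' * `lookback_days = 30`, `grace_days = 15`: testing-coverage window around a
#'   dispensation (inclusive at both endpoints by default).
#' * `lapse_months = 6`: a prescription lapse of more than six calendar months
#'   renders a client inactive (lost to follow-up).
#' * `tablet_unit = 30`: dispensed quantity is reported in 30-tablet supply
#'   units.
#' * `age_breaks` / `age_labels`: age bins `<18, 18-28, 29-40, 41-48, >=49`
#'   (completed years, inclusive ranges).
#' * `provider_volume_breaks` / `provider_volume_labels`: provider caseload
#'   bins `1, 2-5, 6-19, 20-49, >=50` clients.
#' * `status_cutover_quarter = "2019Q2"`: before the last day of this quarter
#'   the lapse rule compares consecutive prescription dates; afterwards it
#'   compares against the expected refill date (see [classify_status()]).
#' * `lapse_rule`: `"cutover"` (the rule switch above), `"gap"` (gap rule
#'   everywhere) or `"refill"` (expected-refill rule everywhere).
#' * `non_daily_stretch = 2`: days of supply per tablet for non-daily
#'   (on-demand) use; daily use is 1 day per tablet. On-demand dosing has no
#'   fixed cadence, so this factor is a reporting convention and is flagged in
#'   every report footer.
#' * `suppression_threshold = 5`: counts in `1..4` are masked in public
#'   reports.
#' * `percent_rounding = "half_away"`: percentages are rounded to whole
#'   integers, halves away from zero.
#' * `quantile_type = 7`: quantile convention (linear interpolation between
#'   order statistics) for the days-to-first-dispensation summary.
#'
#' @param lookback_days,grace_days,lapse_months,tablet_unit,non_daily_stretch
#'   positive numeric scalars as described above.
#' @param age_breaks,age_labels,provider_volume_breaks,provider_volume_labels
#'   bin definitions; `*_breaks` are the lower edges of every bin but the
#'   first, `*_labels` name the bins.
#' @param suppression_threshold non-negative integer; `0` disables suppression.
#' @param status_cutover_quarter quarter label for the lapse-rule switch.
#' @param lapse_rule one of `"cutover"`, `"gap"`, `"refill"`.
#' @param percent_rounding `"half_away"` or `"half_even"`.
#' @param quantile_type integer passed to [stats::quantile()].
#' @param window_inclusive named logical vector `c(lower = , upper = )` giving
#'   the endpoint convention of the testing-coverage window.
#' @return an object of class `indicator_config` (a named list).
#' @seealso [write_indicator_config()], [read_indicator_config()]
#' @export
indicator_config <- function(lookback_days = 30,
                             grace_days = 15,
                             lapse_months = 6L,
                             tablet_unit = 30,
                             age_breaks = c(18, 29, 41, 49),
                             age_labels = c("<18", "18-28", "29-40", "41-48", "49+"),
                             provider_volume_breaks = c(2, 6, 20, 50),
                             provider_volume_labels = c("1", "2-5", "6-19", "20-49", "50+"),
                             suppression_threshold = 5L,
                             status_cutover_quarter = "2019Q2",
                             lapse_rule = c("cutover", "gap", "refill"),
                             non_daily_stretch = 2,
                             percent_rounding = c("half_away", "half_even"),
                             quantile_type = 7L,
                             window_inclusive = c(lower = TRUE, upper = TRUE)) {
  lapse_rule <- match.arg(lapse_rule)
  percent_rounding <- match.arg(percent_rounding)
  assert_quarter(status_cutover_quarter)
  stopifnot(
    lookback_days >= 0, grace_days >= 0, lapse_months > 0, tablet_unit > 0,
    non_daily_stretch > 0, suppression_threshold >= 0,
    length(age_labels) == length(age_breaks) + 1L,
    !is.unsorted(age_breaks, strictly = TRUE),
    length(provider_volume_labels) == length(provider_volume_breaks) + 1L,
    !is.unsorted(provider_volume_breaks, strictly = TRUE),
    all(c("lower", "upper") %in% names(window_inclusive))
  )
  structure(list(
    lookback_days = lookback_days,
    grace_days = grace_days,
    lapse_months = as.integer(lapse_months),
    tablet_unit = tablet_unit,
    age_breaks = age_breaks,
    age_labels = age_labels,
    provider_volume_breaks = provider_volume_breaks,
    provider_volume_labels = provider_volume_labels,
    suppression_threshold = as.integer(suppression_threshold),
    status_cutover_quarter = status_cutover_quarter,
    lapse_rule = lapse_rule,
    non_daily_stretch = non_daily_stretch,
    percent_rounding = percent_rounding,
    quantile_type = as.integer(quantile_type),
    window_inclusive = stats::setNames(as.logical(window_inclusive[c("lower", "upper")]),
                                       c("lower", "upper"))
  ), class = "indicator_config")
}

#' @export
print.indicator_config <- function(x, ...) {
  cat("<indicator_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Serialize / deserialize an indicator configuration as YAML
#'
#' @param cfg an [indicator_config()].
#' @param path file path.
#' @return `read_indicator_config()` returns an `indicator_config`;
#'   `write_indicator_config()` returns `path` invisibly.
#' @export
write_indicator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "indicator_config"))
  out <- unclass(cfg)
  out$window_inclusive <- as.list(stats::setNames(cfg$window_inclusive, c("lower", "upper")))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_indicator_config
#' @export
read_indicator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$window_inclusive <- c(lower = isTRUE(raw$window_inclusive$lower),
                            upper = isTRUE(raw$window_inclusive$upper))
  do.call(indicator_config, raw)
}

# bin helpers shared by the indicator engine -------------------------------

bin_label <- function(x, breaks, labels) {
  idx <- findInterval(x, breaks) + 1L
  out <- labels[idx]
  out[is.na(x)] <- NA_character_
  out
}

age_bin <- function(age, cfg) bin_label(age, cfg$age_breaks, cfg$age_labels)

volume_bin <- function(volume, cfg) {
  bin_label(volume, cfg$provider_volume_breaks, cfg$provider_volume_labels)
}
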