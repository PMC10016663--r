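#' Rounded display percentage
#'
#' Percentages in the quarterly report are displayed as whole integers;
#' the default rounding is to the nearest integer with halves away from zero.
#' A zero denominator yields `NA` (the percentage is absent, never a division
#' error).
#'
#' @param numerator,denominator numeric vectors (recycled).
#' @param cfg an [indicator_config()] (controls the rounding mode).
#' @return integer vector of percentages, `NA` where `denominator` is zero.
#' @examples
#' percent(4829, 6727)  # 72
#' percent(94, 112)     # 84
#' @export
percent <- function(numerator, denominator, cfg = indicator_config()) {
  p <- 100 * numerator / denominator
  out <- rep(NA_integer_, length(p))
  ok <- is.finite(p)
  out[ok] <- if (cfg$percent_rounding == "half_away") {
    as.integer(sign(p[ok]) * floor(abs(p[ok]) + 0.5))
  } else {
    as.integer(round(p[ok]))
  }
  out
}

#' One indicator's stratified output for one quarter
#'
#' A `stratified_result` holds one indicator block: one row per stratum with
#' numerator, denominator, display percentage and a suppression flag. For
#' partition-type indicators the stratum numerators sum to the denominator;
#' for coverage-type indicators each numerator is at most the denominator.
#'
#' @param indicator_id indicator number as character (`"1"`..`"14"`).
#' @param part sub-part label (`""`, `"a"` or `"b"`).
#' @param dimension stratification dimension label (`""`, `"residence"`,
#'   `"practice"`).
#' @param title human-readable indicator title.
#' @param quarter quarter label or `"cumulative"`.
#' @param strata character vector of stratum labels.
#' @param numerator,denominator numeric vectors (denominator recycled).
#' @param cfg an [indicator_config()] used for the display percentage.
#' @param partition logical: do the strata partition the denominator? (drives
#'   complementary suppression and the partition invariant).
#' @param notes character vector of free-text notes.
#' @return an object of class `stratified_result`.
#' @export
stratified_result <- function(indicator_id, part, dimension, title, quarter,
                              strata, numerator, denominator,
                              cfg = indicator_config(),
                              partition = FALSE, notes = character()) {
  rows <- tibble::tibble(
    stratum = as.character(strata),
    numerator = as.numeric(numerator),
    denominator = as.numeric(denominator),
    percent = percent(as.numeric(numerator), as.numeric(denominator), cfg),
    suppressed = FALSE
  )
  structure(list(
    indicator_id = as.character(indicator_id),
    part = part,
    dimension = dimension,
    title = title,
    quarter = quarter,
    rows = rows,
    partition = isTRUE(partition),
    notes = notes
  ), class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  hdr <- sprintf("Indicator %s%s%s | %s | %s",
                 x$indicator_id, x$part,
                 if (nzchar(x$dimension)) paste0(" (", x$dimension, ")") else "",
                 x$title, x$quarter)
  cat(hdr, "\n")
  print(x$rows, n = Inf)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @method as_tibble stratified_result
#' @export
as_tibble.stratified_result <- function(x, ...) {
  tibble::tibble(
    indicator = x$indicator_id, part = x$part, dimension = x$dimension,
    quarter = x$quarter, stratum = x$rows$stratum,
    numerator = x$rows$numerator, denominator = x$rows$denominator,
    percent = x$rows$percent, suppressed = x$rows$suppressed)
}

# complete a count table over a fixed stratum-level set
complete_counts <- function(counts, levels) {
  found <- stats::setNames(rep(0, length(levels)), levels)
  if (nrow(counts)) {
    found[counts$stratum] <- counts$n
    extra <- setdiff(counts$stratum, levels)
    if (length(extra)) {
      found <- c(found, stats::setNames(counts$n[match(extra, counts$stratum)], extra))
    }
  }
  found
}
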