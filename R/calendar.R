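#' Calendar-quarter helpers
#'
#' Quarters are represented as character labels `"YYYYQn"` (e.g. `"2019Q2"`,
#' April to June). The labels are fixed width, so lexicographic order equals
#' chronological order.
#'
#' @param d a `Date` vector (or something coercible via [as.Date()]).
#' @return `quarter_of()` returns a character vector of quarter labels.
#' @examples
#' quarter_of(as.Date(c("2018-01-01", "2019-06-30", "2020-12-31")))
#' @export
quarter_of <- function(d) {
  d <- as.Date(d)
  lt <- as.POSIXlt(d)
  sprintf("%04dQ%d", lt$year + 1900L, lt$mon %/% 3L + 1L)
}

assert_quarter <- function(q) {
  bad <- !grepl("^\\d{4}Q[1-4]$", q)
  if (any(bad)) {
    stop("invalid quarter label(s): ", paste(unique(q[bad]), collapse = ", "),
         " (expected 'YYYYQn')", call. = FALSE)
  }
  invisible(q)
}

#' @rdname quarter_of
#' @param q a quarter label such as `"2019Q2"`.
#' @return `quarter_start()` / `quarter_end()` return the first / last `Date`
#'   of the quarter.
#' @export
quarter_start <- function(q) {
  assert_quarter(q)
  yr <- as.integer(substr(q, 1, 4))
  idx <- as.integer(substr(q, 6, 6))
  as.Date(sprintf("%04d-%02d-01", yr, (idx - 1L) * 3L + 1L))
}

#' @rdname quarter_of
#' @export
quarter_end <- function(q) {
  assert_quarter(q)
  yr <- as.integer(substr(q, 1, 4))
  idx <- as.integer(substr(q, 6, 6))
  nxt <- ifelse(idx == 4L,
                sprintf("%04d-01-01", yr + 1L),
                sprintf("%04d-%02d-01", yr, idx * 3L + 1L))
  as.Date(nxt) - 1L
}

#' @rdname quarter_of
#' @param from,to quarter labels bounding the sequence (inclusive).
#' @param n alternative to `to`: number of quarters to generate.
#' @return `quarter_seq()` returns a character vector of consecutive quarters.
#' @export
quarter_seq <- function(from, to = NULL, n = NULL) {
  assert_quarter(from)
  yr <- as.integer(substr(from, 1, 4))
  idx <- as.integer(substr(from, 6, 6))
  code0 <- yr * 4L + (idx - 1L)
  if (is.null(n)) {
    assert_quarter(to)
    code1 <- as.integer(substr(to, 1, 4)) * 4L + (as.integer(substr(to, 6, 6)) - 1L)
    if (code1 < code0) stop("'to' precedes 'from'", call. = FALSE)
    codes <- code0:code1
  } else {
    codes <- code0 + seq_len(n) - 1L
  }
  sprintf("%04dQ%d", codes %/% 4L, codes %% 4L + 1L)
}

#' Month arithmetic with end-of-month clamping
#'
#' Adds `m` calendar months to `d`; when the target month is shorter than the
#' starting day-of-month the result is clamped to the last day of the target
#' month (2018-01-31 + 1 month is 2018-02-28). This is the convention the
#' ">6 months" prescription-lapse rules are evaluated under.
#'
#' @param d a `Date` vector.
#' @param m integer number of months (scalar, may be negative).
#' @return a `Date` vector.
#' @export
add_months <- function(d, m) {
  as.Date(d) %m+% months(as.integer(m))
}

#' Test whether a laboratory test date covers a dispensation
#'
#' A dispensation is "covered" by a test when the test falls within a lookback
#' window before the dispensation date or a grace period after it; by default
#' 30 days before through 15 days after, both endpoints inclusive (a 46-day
#' window).
#'
#' @param dispense_date,test_date `Date` vectors (recycled against each other).
#' @param cfg an [indicator_config()].
#' @return logical vector.
#' @examples
#' cfg <- indicator_config()
#' in_test_window(as.Date("2020-04-10"), as.Date("2020-03-11"), cfg) # exactly -30
#' @export
in_test_window <- function(dispense_date, test_date, cfg = indicator_config()) {
  dispense_date <- as.Date(dispense_date)
  test_date <- as.Date(test_date)
  lo <- dispense_date - cfg$lookback_days
  hi <- dispense_date + cfg$grace_days
  lower_ok <- if (cfg$window_inclusive[["lower"]]) test_date >= lo else test_date > lo
  upper_ok <- if (cfg$window_inclusive[["upper"]]) test_date <= hi else test_date < hi
  lower_ok & upper_ok
}

#' Age in completed years at a reference date
#'
#' @param dob,at `Date` vectors.
#' @return integer vector (`NA` where `dob` is missing).
#' @export
age_at <- function(dob, at) {
  dob <- as.POSIXlt(as.Date(dob))
  at <- as.POSIXlt(as.Date(at))
  age <- (at$year - dob$year) -
    as.integer(at$mon < dob$mon | (at$mon == dob$mon & at$mday < dob$mday))
  as.integer(age)
}
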