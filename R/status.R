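#' Expected refill date of a dispensation
#'
#' Projects the date a dispensed supply runs out. For daily use the days of
#' supply equal the tablet count; for non-daily (on-demand) use the tablet
#' count is stretched by `cfg$non_daily_stretch` (default 2 days per tablet),
#' a reporting convention since on-demand dosing has no fixed cadence. The
#' anchor is the effective dispense date: pickup date when recorded,
#' otherwise the prescription fill date.
#'
#' @param disp a tibble of dispensation rows (columns `fill_date`,
#'   `pickup_date`, `tablets`, `usage_type`).
#' @param cfg an [indicator_config()].
#' @return a `Date` vector, one element per dispensation row.
#' @examples
#' cfg <- indicator_config()
#' expected_refill_date(tibble::tibble(
#'   fill_date = as.Date("2020-01-01"), pickup_date = as.Date("2020-01-01"),
#'   tablets = 30L, usage_type = "daily"), cfg)  # 2020-01-31
#' @export
expected_refill_date <- function(disp, cfg = indicator_config()) {
  stopifnot(all(disp$tablets > 0))
  eff <- dplyr::coalesce(disp$pickup_date, disp$fill_date)
  eff + supply_days(disp$tablets, disp$usage_type, cfg)
}

supply_days <- function(tablets, usage_type, cfg) {
  round(tablets * ifelse(usage_type == "non_daily", cfg$non_daily_stretch, 1))
}

# Candidate lapse date after a dispensation, by rule. The client becomes
# inactive ON this date if no further dispensation precedes it.
#   gap rule:    day after (effective date + lapse_months)
#   refill rule: day after (expected refill date + lapse_months)
# Under "cutover" the gap rule applies when its candidate date falls on/before
# the last day of the cutover quarter, the refill rule otherwise. Since the
# refill candidate is never earlier than the gap candidate, the switch is
# well defined.
lapse_candidates <- function(eff, sdays, cfg) {
  g <- add_months(eff, cfg$lapse_months) + 1L
  r <- add_months(eff + sdays, cfg$lapse_months) + 1L
  switch(cfg$lapse_rule,
    gap = list(date = g, reason = rep("lapse_between_prescriptions", length(g))),
    refill = list(date = r, reason = rep("lapse_past_expected_refill", length(r))),
    cutover = {
      cut_end <- quarter_end(cfg$status_cutover_quarter)
      use_gap <- g <= cut_end
      list(date = as.Date(ifelse(use_gap, g, r), origin = "1970-01-01"),
           reason = ifelse(use_gap, "lapse_between_prescriptions",
                           "lapse_past_expected_refill"))
    })
}

#' Status timelines for every dispensed client
#'
#' Builds the per-client active/inactive event timeline implied by the whole
#' dispensation history and any formal discontinuation notification:
#'
#' * a client is active from their first dispensation (effective date);
#' * a lapse entry (inactive) is recorded on the candidate lapse date after a
#'   dispensation whenever the next dispensation falls strictly after it (or
#'   there is no further dispensation -- the entry after the last dispensation
#'   is the scheduled date the client becomes lost to follow-up);
#' * a dispensation after a lapse re-activates the client on its effective
#'   date (reason `re_dispensation`);
#' * a formal discontinuation notification makes the client inactive on the
#'   notification date; the earlier of notification and lapse wins, and no
#'   re-activation follows a formal notification.
#'
#' Entries carry dates, so the client's status at any date is simply the state
#' of the last entry on/before that date (see [status_at()]); entries dated in
#' the future relative to a query date are ignored by lookup.
#'
#' @param store an [event_store()].
#' @param cfg an [indicator_config()]; `cfg$lapse_rule` selects the lapse rule
#'   (see [indicator_config()]).
#' @return tibble `client_id`, `effective_date`, `state`, `reason`, ordered
#'   per client.
#' @export
status_timelines <- function(store, cfg = indicator_config()) {
  dp <- store$dispensations
  if (!nrow(dp)) {
    return(tibble::tibble(client_id = character(), effective_date = as.Date(character()),
                          state = character(), reason = character()))
  }
  d <- with_effective_dates(dp) %>%
    mutate(sdays = supply_days(.data$tablets, .data$usage_type, cfg))
  d <- d[order(d$client_id, d$effective_date, d$.disp_id), ]
  n <- nrow(d)
  nxt <- c(d$effective_date[-1], as.Date(NA))
  same_client <- c(d$client_id[-1] == d$client_id[-n], FALSE)
  nxt[!same_client] <- NA
  d$nxt <- nxt
  d$is_first <- !duplicated(d$client_id)

  cand <- lapse_candidates(d$effective_date, d$sdays, cfg)
  # lapse occurs iff the next effective date is strictly after the candidate
  # (a re-dispensation exactly on the candidate date collapses to no lapse);
  # for the last dispensation the candidate is always a scheduled entry
  lapses <- !is.na(d$nxt) & d$nxt > cand$date | is.na(d$nxt)

  first_entries <- d %>% filter(.data$is_first) %>%
    mutate(state = "active", reason = "first_dispensation") %>%
    select("client_id", "effective_date", "state", "reason")
  lapse_entries <- tibble::tibble(
    client_id = d$client_id[lapses],
    effective_date = cand$date[lapses],
    state = "inactive",
    reason = cand$reason[lapses])
  react <- !is.na(d$nxt) & d$nxt > cand$date
  react_entries <- tibble::tibble(
    client_id = d$client_id[react],
    effective_date = d$nxt[react],
    state = "active",
    reason = "re_dispensation")

  # rank orders same-day entries: activation first, notification last
  ent <- bind_rows(
    first_entries %>% mutate(rank = 1L),
    react_entries %>% mutate(rank = 1L),
    lapse_entries %>% mutate(rank = 2L)
  )

  nt <- store$notifications %>% filter(.data$kind == "formal_discontinuation")
  if (nrow(nt)) {
    nt <- nt %>%
      group_by(.data$client_id) %>%
      summarise(notif_date = min(.data$notification_date), .groups = "drop")
    first_eff <- first_entries %>% select("client_id", first_date = "effective_date")
    nt <- nt %>% inner_join(first_eff, by = "client_id") %>%
      mutate(notif_date = pmax(.data$notif_date, .data$first_date))
    ent <- ent %>% left_join(nt %>% select("client_id", "notif_date"), by = "client_id") %>%
      filter(is.na(.data$notif_date) | .data$effective_date <= .data$notif_date) %>%
      select(-"notif_date")
    notif_entries <- nt %>%
      transmute(client_id = .data$client_id, effective_date = .data$notif_date,
                state = "inactive", reason = "formal_notification", rank = 3L)
    ent <- bind_rows(ent, notif_entries)
  }

  ent <- ent[order(ent$client_id, ent$effective_date, ent$rank), ]
  # collapse runs of equal state (e.g. lapse already inactive when the
  # notification arrives) keeping the earliest entry of each run
  ne <- nrow(ent)
  first_of_client <- !duplicated(ent$client_id)
  prev_state <- c("", ent$state[-ne])
  ent <- ent[first_of_client | ent$state != prev_state, ]
  ent$rank <- NULL
  ent
}

#' @importFrom dplyr transmute slice_max pull
NULL

#' Look up client status at a date
#'
#' @param timelines output of [status_timelines()].
#' @param client_id character vector of clients to look up.
#' @param date a single `Date`, or a vector recycled against `client_id`.
#' @return character vector: `"active"`, `"inactive"`, or `NA` for clients
#'   with no timeline entry on/before `date` (not yet dispensed).
#' @export
status_at <- function(timelines, client_id, date) {
  q <- tibble::tibble(client_id = client_id, qdate = as.Date(date),
                      .row = seq_along(client_id))
  hit <- q %>%
    inner_join(timelines %>% mutate(.ord = row_number()), by = "client_id",
               relationship = "many-to-many") %>%
    filter(.data$effective_date <= .data$qdate)
  hit <- hit[order(hit$.row, hit$.ord), ]
  hit <- hit[!duplicated(hit$.row, fromLast = TRUE), ]
  out <- rep(NA_character_, length(client_id))
  out[hit$.row] <- hit$state
  out
}

#' Status timeline for a single client
#'
#' Returns the client's active/inactive timeline truncated at `as_of`. Errors
#' for a client with no dispensation: enrolment without dispensation leaves
#' program status undefined (such clients are outside the status indicator's
#' denominator).
#'
#' @param store an [event_store()].
#' @param client_id a single client identifier.
#' @param as_of assessment date.
#' @param cfg an [indicator_config()].
#' @return tibble `client_id`, `effective_date`, `state`, `reason`.
#' @export
classify_status <- function(store, client_id, as_of, cfg = indicator_config()) {
  stopifnot(length(client_id) == 1)
  if (!any(store$dispensations$client_id == client_id)) {
    stop("client '", client_id, "' has no dispensation; program status is undefined",
         call. = FALSE)
  }
  sub <- store
  sub$dispensations <- store$dispensations %>% filter(.data$client_id == !!client_id)
  sub$notifications <- store$notifications %>% filter(.data$client_id == !!client_id)
  status_timelines(sub, cfg) %>% filter(.data$effective_date <= as.Date(as_of))
}

#' Active/inactive counts at quarter end (indicator: client status)
#'
#' Denominator: all clients ever dispensed by the end of the quarter.
#' Numerators: those active / inactive on the last day of the quarter per
#' [status_timelines()].
#'
#' @param store an [event_store()].
#' @param quarter quarter label, e.g. `"2020Q4"`.
#' @param cfg an [indicator_config()].
#' @param timelines optional precomputed [status_timelines()] (recomputed when
#'   `NULL`).
#' @return a [stratified_result()] with strata `active`, `inactive`.
#' @export
status_counts <- function(store, quarter, cfg = indicator_config(), timelines = NULL) {
  qend <- quarter_end(quarter)
  if (is.null(timelines)) timelines <- status_timelines(store, cfg)
  firsts <- timelines[!duplicated(timelines$client_id), ]  # ordered per client
  eligible <- firsts[firsts$effective_date <= qend, ]
  states <- status_at(timelines, eligible$client_id, qend)
  counts <- c(active = sum(states == "active", na.rm = TRUE),
              inactive = sum(states == "inactive", na.rm = TRUE))
  stratified_result(
    indicator_id = "9", part = "", dimension = "",
    title = "BC-PrEP client status (active vs inactive)",
    quarter = quarter,
    strata = names(counts), numerator = unname(counts),
    denominator = nrow(eligible), cfg = cfg, partition = TRUE)
}
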