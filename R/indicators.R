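#' @importFrom tibble as_tibble tibble
NULL

# dispensations with effective dates restricted to a quarter
disp_in_quarter <- function(store, quarter) {
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  with_effective_dates(store$dispensations) %>%
    filter(.data$effective_date >= qs, .data$effective_date <= qe)
}

# one row per client: first dispensation (by effective date, file order ties)
first_disp_of <- function(disp) {
  d <- disp[order(disp$client_id, disp$effective_date, disp$.disp_id), ]
  d[!duplicated(d$client_id), ]
}

# one row per client: last dispensation on/before a date
last_disp_by <- function(disp, as_of) {
  d <- disp[disp$effective_date <= as_of, ]
  d <- d[order(d$client_id, d$effective_date, d$.disp_id), ]
  d[!duplicated(d$client_id, fromLast = TRUE), ]
}

#' Distribution of clients dispensed PrEP in a quarter
#'
#' Indicator family covering client gender identity, age and health authority:
#' the denominator is the unique clients with at least one dispensation whose
#' effective date falls in the quarter.
#'
#' * `gender`: the most recently recorded gender identity on/before quarter
#'   end (clients with no record by then fall into `other_unspecified`).
#' * `age`: age in completed years at the client's first dispensation of the
#'   quarter, binned per `cfg$age_breaks`; a missing date of birth goes to an
#'   `Unknown` stratum.
#' * `ha_residence`: the client's health authority of residence.
#' * `ha_practice`: the prescriber's health authority of practice as recorded
#'   on the client's first dispensation of the quarter.
#'
#' @param store an [event_store()].
#' @param quarter quarter label.
#' @param dimension one of `"gender"`, `"age"`, `"ha_residence"`,
#'   `"ha_practice"`.
#' @param cfg an [indicator_config()].
#' @return a [stratified_result()] (partition type).
#' @export
dispensed_distribution <- function(store, quarter,
                                   dimension = c("gender", "age", "ha_residence",
                                                 "ha_practice"),
                                   cfg = indicator_config()) {
  dimension <- match.arg(dimension)
  dd <- disp_in_quarter(store, quarter)
  firsts <- first_disp_of(dd)
  den <- nrow(firsts)

  spec <- switch(dimension,
    gender = {
      g <- gender_as_of(store, quarter_end(quarter))
      lab <- firsts %>% left_join(g, by = "client_id") %>%
        mutate(stratum = coalesce(.data$gender_identity, "other_unspecified"))
      list(labels = lab$stratum, levels = GENDER_LEVELS,
           id = "1", part = "", dimn = "",
           title = "Client gender identity")
    },
    age = {
      lab <- firsts %>% left_join(store$clients, by = "client_id") %>%
        mutate(stratum = coalesce(age_bin(age_at(.data$date_of_birth,
                                                 .data$effective_date), cfg),
                                  "Unknown"))
      lv <- cfg$age_labels
      if (any(lab$stratum == "Unknown")) lv <- c(lv, "Unknown")
      list(labels = lab$stratum, levels = lv, id = "2", part = "", dimn = "",
           title = "Client age")
    },
    ha_residence = {
      lab <- firsts %>% left_join(store$clients, by = "client_id") %>%
        mutate(stratum = coalesce(.data$ha_of_residence, "Unknown"))
      list(labels = lab$stratum, levels = HA_LEVELS, id = "3", part = "",
           dimn = "residence",
           title = "Health authority (clients' HA of residence)")
    },
    ha_practice = {
      list(labels = coalesce(firsts$prescriber_ha_of_practice, "Unknown"),
           levels = HA_LEVELS, id = "3", part = "", dimn = "practice",
           title = "Health authority (providers' HA of practice)")
    })

  counts <- tibble(stratum = spec$labels) %>% count(.data$stratum)
  num <- complete_counts(counts, spec$levels)
  stratified_result(spec$id, spec$part, spec$dimn, spec$title, quarter,
                    names(num), unname(num), den, cfg, partition = TRUE)
}

#' New clients authorized for enrolment in a quarter
#'
#' Denominator: clients whose authorization date falls in the quarter
#' (including clients never yet dispensed). Stratified by the enrolling
#' provider's type (physicians are split into family vs specialist via the
#' provider roster, emulating the licensing-college linkage), the client's
#' health authority of residence, or the enrolling provider's health authority
#' of practice. An enrolling provider absent from the roster falls into an
#' `Unknown` stratum.
#'
#' @inheritParams dispensed_distribution
#' @param dimension one of `"provider_type"`, `"ha_residence"`,
#'   `"ha_practice"`.
#' @return a [stratified_result()] (partition type).
#' @export
new_enrolments <- function(store, quarter,
                           dimension = c("provider_type", "ha_residence",
                                         "ha_practice"),
                           cfg = indicator_config()) {
  dimension <- match.arg(dimension)
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  en <- store$enrolments %>%
    filter(.data$authorization_date >= qs, .data$authorization_date <= qe)
  den <- nrow(en)

  spec <- switch(dimension,
    provider_type = {
      lab <- en %>%
        left_join(store$providers, by = c(enrolling_provider_id = "provider_id"))
      list(labels = coalesce(lab$provider_type, "Unknown"),
           levels = PROVIDER_TYPES, id = "4", part = "", dimn = "",
           title = "New BC-PrEP clients enrolled by provider type")
    },
    ha_residence = {
      lab <- en %>% left_join(store$clients, by = "client_id")
      list(labels = coalesce(lab$ha_of_residence, "Unknown"), levels = HA_LEVELS,
           id = "5", part = "", dimn = "residence",
           title = "New BC-PrEP clients enrolled by HA (clients' residence)")
    },
    ha_practice = {
      lab <- en %>%
        left_join(store$providers, by = c(enrolling_provider_id = "provider_id"))
      list(labels = coalesce(lab$ha_of_practice, "Unknown"), levels = HA_LEVELS,
           id = "5", part = "", dimn = "practice",
           title = "New BC-PrEP clients enrolled by HA (providers' practice)")
    })
  lv <- spec$levels
  if (dimension == "provider_type" && any(spec$labels == "Unknown")) {
    lv <- c(lv, "Unknown")
  }
  counts <- tibble(stratum = spec$labels) %>% count(.data$stratum)
  num <- complete_counts(counts, lv)
  stratified_result(spec$id, spec$part, spec$dimn, spec$title, quarter,
                    names(num), unname(num), den, cfg, partition = TRUE)
}

#' New clients dispensed PrEP for the first time in a quarter
#'
#' Denominator: clients whose earliest effective dispense date over their
#' whole history falls in the quarter. Stratified by the client's health
#' authority of residence or the prescriber's health authority of practice on
#' that first dispensation.
#'
#' @inheritParams dispensed_distribution
#' @param dimension `"ha_residence"` or `"ha_practice"`.
#' @return a [stratified_result()] (partition type).
#' @export
first_dispensations <- function(store, quarter,
                                dimension = c("ha_residence", "ha_practice"),
                                cfg = indicator_config()) {
  dimension <- match.arg(dimension)
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  firsts <- first_disp_of(with_effective_dates(store$dispensations)) %>%
    filter(.data$effective_date >= qs, .data$effective_date <= qe)
  den <- nrow(firsts)
  if (dimension == "ha_residence") {
    lab <- firsts %>% left_join(store$clients, by = "client_id")
    labels <- coalesce(lab$ha_of_residence, "Unknown")
    dimn <- "residence"
    title <- "New BC-PrEP clients dispensed PrEP (clients' HA of residence)"
  } else {
    labels <- coalesce(firsts$prescriber_ha_of_practice, "Unknown")
    dimn <- "practice"
    title <- "New BC-PrEP clients dispensed PrEP (providers' HA of practice)"
  }
  counts <- tibble(stratum = labels) %>% count(.data$stratum)
  num <- complete_counts(counts, HA_LEVELS)
  stratified_result("6", "", dimn, title, quarter, names(num), unname(num),
                    den, cfg, partition = TRUE)
}

#' Clients per provider (caseload volume)
#'
#' A provider's volume is the number of distinct clients they dispensed PrEP
#' to within the quarter, binned per `cfg$provider_volume_breaks`.
#'
#' * Part a: providers per volume bin; denominator = distinct providers with
#'   at least one in-quarter dispensation (a partition).
#' * Part b: clients covered by each volume bin; a client is attributed to the
#'   bin of every provider who dispensed to them that quarter (deduplicated
#'   per client and bin), so a client seen by providers in two bins counts in
#'   both while the denominator stays distinct clients. Numerators may
#'   therefore jointly exceed the denominator.
#'
#' @inheritParams dispensed_distribution
#' @return a list with elements `a` and `b`, both [stratified_result()]s.
#' @export
provider_volume <- function(store, quarter, cfg = indicator_config()) {
  dd <- disp_in_quarter(store, quarter)
  pairs <- dd %>% distinct(.data$prescriber_id, .data$client_id)
  vol <- pairs %>% count(.data$prescriber_id, name = "volume") %>%
    mutate(bin = volume_bin(.data$volume, cfg))

  counts_a <- vol %>% count(bin, name = "n") %>% rename(stratum = "bin")
  num_a <- complete_counts(counts_a, cfg$provider_volume_labels)
  a <- stratified_result("7", "a", "",
                         "BC-PrEP clients per provider (providers by volume)",
                         quarter, names(num_a), unname(num_a), nrow(vol), cfg,
                         partition = TRUE)

  cover <- pairs %>% inner_join(vol %>% select("prescriber_id", "bin"),
                                by = "prescriber_id") %>%
    distinct(.data$client_id, .data$bin)
  counts_b <- cover %>% count(bin, name = "n") %>% rename(stratum = "bin")
  num_b <- complete_counts(counts_b, cfg$provider_volume_labels)
  b <- stratified_result("7", "b", "",
                         "BC-PrEP clients per provider (clients covered by volume bin)",
                         quarter, names(num_b), unname(num_b),
                         n_distinct(pairs$client_id), cfg, partition = FALSE,
                         notes = "a client may appear under several volume bins")
  list(a = a, b = b)
}

# canonical label for a risk-factor combination
risk_category_label <- function(sets) {
  vapply(sets, function(s) {
    s <- sort(unique(s))
    if (!length(s)) "none recorded"
    else if (length(s) == 1L) paste(s, "only")
    else paste(s, collapse = "+")
  }, character(1))
}

#' Key qualifying HIV risk factors at enrolment
#'
#' Among clients dispensed PrEP for the first time, the six key qualifying
#' HIV risk factors recorded at enrolment (codes `a`..`f`; `d` is a risk-index
#' score at or above the qualifying threshold, recorded as a flag).
#'
#' * Part a (per quarter): one row per factor; providers may record several
#'   factors per client, so numerators are non-mutually exclusive and may
#'   jointly exceed the denominator (first-time-dispensed clients in the
#'   quarter).
#' * Part b (cumulative to quarter end): clients partitioned by their exact
#'   factor combination (e.g. `"d only"`, `"a+d"`, `"none recorded"`);
#'   numerators sum to the denominator (all first-time-dispensed clients to
#'   date).
#'
#' @inheritParams dispensed_distribution
#' @return a list with elements `a` and `b`, both [stratified_result()]s.
#' @export
risk_factor_profile <- function(store, quarter, cfg = indicator_config()) {
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  firsts <- first_disp_of(with_effective_dates(store$dispensations))
  in_q <- firsts %>% filter(.data$effective_date >= qs, .data$effective_date <= qe)
  cum <- firsts %>% filter(.data$effective_date <= qe)

  get_sets <- function(ids) {
    en <- store$enrolments %>% filter(.data$client_id %in% ids)
    sets <- parse_risk_factors(en$risk_factors)
    miss <- setdiff(ids, en$client_id)
    c(sets, rep(list(character()), length(miss)))
  }

  sets_q <- get_sets(in_q$client_id)
  num_a <- vapply(RISK_FACTORS, function(f) {
    sum(vapply(sets_q, function(s) f %in% s, logical(1)))
  }, numeric(1))
  a <- stratified_result("8", "a", "",
                         "Key qualifying HIV risk factors (per factor, non-exclusive)",
                         quarter, RISK_FACTORS, unname(num_a), length(sets_q), cfg,
                         partition = FALSE,
                         notes = "factors are non-mutually exclusive")

  sets_c <- get_sets(cum$client_id)
  cats <- risk_category_label(sets_c)
  counts <- tibble(stratum = cats) %>% count(.data$stratum) %>%
    arrange(dplyr::desc(.data$n), .data$stratum)
  b <- stratified_result("8", "b", "",
                         "Key qualifying HIV risk factor combinations (cumulative)",
                         quarter, counts$stratum, counts$n, length(sets_c), cfg,
                         partition = TRUE,
                         notes = "cumulative over all first-time-dispensed clients")
  list(a = a, b = b)
}

#' PrEP usage type among active clients
#'
#' Denominator: clients active at quarter end per the status engine. The
#' usage type (prescribed daily vs non-daily) is taken from the client's most
#' recent dispensation on/before quarter end.
#'
#' @inheritParams dispensed_distribution
#' @param timelines optional precomputed [status_timelines()].
#' @return a [stratified_result()] (partition type).
#' @export
usage_type_distribution <- function(store, quarter, cfg = indicator_config(),
                                    timelines = NULL) {
  qend <- quarter_end(quarter)
  if (is.null(timelines)) timelines <- status_timelines(store, cfg)
  clients <- unique(timelines$client_id)
  states <- status_at(timelines, clients, qend)
  active <- clients[!is.na(states) & states == "active"]

  ev <- with_effective_dates(store$dispensations)
  latest <- last_disp_by(ev[ev$client_id %in% active, ], qend)
  counts <- latest %>% count(.data$usage_type) %>%
    rename(stratum = "usage_type")
  num <- complete_counts(counts, USAGE_TYPES)
  stratified_result("10", "", "", "PrEP usage type among active BC-PrEP clients",
                    quarter, names(num), unname(num), length(active), cfg,
                    partition = TRUE,
                    notes = sprintf("non-daily days of supply use a %gx stretch factor",
                                    cfg$non_daily_stretch))
}

#' PrEP quantity dispensed in 30-tablet supply units
#'
#' Tablets dispensed in the quarter (by effective dispense date) divided by
#' `cfg$tablet_unit`, reported by the clients' health authority of residence
#' or the prescribers' health authority of practice (recorded per
#' dispensation). Unit counts are kept at full precision so the per-HA units
#' sum exactly to total tablets / unit; round at display time.
#'
#' @inheritParams dispensed_distribution
#' @param dimension `"ha_residence"` or `"ha_practice"`.
#' @return a [stratified_result()] (partition type; numerators are unit
#'   counts, not client counts).
#' @export
quantity_dispensed <- function(store, quarter,
                               dimension = c("ha_residence", "ha_practice"),
                               cfg = indicator_config()) {
  dimension <- match.arg(dimension)
  dd <- disp_in_quarter(store, quarter)
  if (dimension == "ha_residence") {
    dd <- dd %>% left_join(store$clients, by = "client_id") %>%
      mutate(stratum = coalesce(.data$ha_of_residence, "Unknown"))
    dimn <- "residence"
    title <- "PrEP quantity dispensed per 30-tablet supply (clients' HA of residence)"
  } else {
    dd <- dd %>% mutate(stratum = coalesce(.data$prescriber_ha_of_practice, "Unknown"))
    dimn <- "practice"
    title <- "PrEP quantity dispensed per 30-tablet supply (providers' HA of practice)"
  }
  per_ha <- dd %>% group_by(.data$stratum) %>%
    summarise(n = sum(.data$tablets) / cfg$tablet_unit, .groups = "drop")
  num <- complete_counts(per_ha, HA_LEVELS)
  stratified_result("11", "", dimn, title, quarter, names(num), unname(num),
                    sum(dd$tablets) / cfg$tablet_unit, cfg, partition = TRUE)
}

#' Testing coverage around dispensations
#'
#' Denominator: dispensations with an effective date in the quarter whose
#' client is active on that date. Numerator: dispensations with at least one
#' test of the given assay within the coverage window ([in_test_window()];
#' default 30 days before through 15 days after the dispensation). One test
#' may satisfy several dispensations.
#'
#' @inheritParams usage_type_distribution
#' @param assay `"hiv"` or `"syphilis"`.
#' @return a [stratified_result()] with a single `covered` stratum.
#' @export
testing_coverage <- function(store, quarter, assay = c("hiv", "syphilis"),
                             cfg = indicator_config(), timelines = NULL) {
  assay <- match.arg(assay)
  if (is.null(timelines)) timelines <- status_timelines(store, cfg)
  dd <- disp_in_quarter(store, quarter)
  if (nrow(dd)) {
    dd <- dd[status_at(timelines, dd$client_id, dd$effective_date) %in% "active", ]
  }
  tests <- store$lab_tests %>% filter(.data$assay == !!assay)
  covered <- dd %>%
    inner_join(tests %>% select("client_id", "test_date"), by = "client_id",
               relationship = "many-to-many") %>%
    filter(in_test_window(.data$effective_date, .data$test_date, cfg)) %>%
    distinct(.data$.disp_id)
  id <- if (assay == "syphilis") "12" else "13"
  part <- if (assay == "syphilis") "a" else "b"
  title <- sprintf("%s testing within the coverage window of a dispensed prescription",
                   if (assay == "hiv") "HIV" else "Infectious syphilis")
  stratified_result(id, part, "", title, quarter, "covered", nrow(covered),
                    nrow(dd), cfg, partition = FALSE)
}

#' Days between the most recent negative HIV test and first dispensation
#'
#' For each client dispensed by `as_of`, the gap in days between their first
#' effective dispense date and the most recent negative HIV test on/before
#' it. Clients with no prior negative test are excluded from the summary and
#' counted separately.
#'
#' @param store an [event_store()].
#' @param cfg an [indicator_config()] (`cfg$quantile_type` sets the quantile
#'   convention).
#' @param as_of optional cut-off date: only clients first dispensed on/before
#'   it enter the summary (default: all).
#' @return a list with `n`, `median`, `p25`, `p75`, `n_no_prior_test`.
#' @export
days_to_first_dispensation <- function(store, cfg = indicator_config(), as_of = NULL) {
  firsts <- first_disp_of(with_effective_dates(store$dispensations))
  if (!is.null(as_of)) firsts <- firsts %>% filter(.data$effective_date <= as.Date(as_of))
  neg <- store$lab_tests %>%
    filter(.data$assay == "hiv", .data$result == "negative") %>%
    select("client_id", "test_date")
  m <- firsts %>%
    inner_join(neg, by = "client_id", relationship = "many-to-many") %>%
    filter(.data$test_date <= .data$effective_date)
  m <- m[order(m$client_id, m$test_date), ]
  m <- m[!duplicated(m$client_id, fromLast = TRUE), ]  # most recent prior test
  g <- as.numeric(m$effective_date - m$test_date)
  qs <- if (length(g)) {
    stats::quantile(g, c(0.25, 0.5, 0.75), type = cfg$quantile_type, names = FALSE)
  } else rep(NA_real_, 3)
  list(n = length(g), median = qs[2], p25 = qs[1], p75 = qs[3],
       n_no_prior_test = nrow(firsts) - length(g))
}

#' Incident cases in a quarter
#'
#' Count of distinct clients with a `positive_incident` result of the given
#' assay dated within the quarter, optionally restricted to clients active at
#' the test date.
#'
#' @inheritParams usage_type_distribution
#' @param assay `"hiv"` or `"syphilis"`.
#' @param require_active restrict to clients active on the test date.
#' @return integer count.
#' @export
incident_cases <- function(store, quarter, assay = c("syphilis", "hiv"),
                           require_active = TRUE, cfg = indicator_config(),
                           timelines = NULL) {
  assay <- match.arg(assay)
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  pos <- store$lab_tests %>%
    filter(.data$assay == !!assay, .data$result == "positive_incident",
           .data$test_date >= qs, .data$test_date <= qe)
  if (require_active && nrow(pos)) {
    if (is.null(timelines)) timelines <- status_timelines(store, cfg)
    pos <- pos[status_at(timelines, pos$client_id, pos$test_date) %in% "active", ]
  }
  n_distinct(pos$client_id)
}

#' Adverse drug reaction event counts
#'
#' Reports are collapsed to clinical events by (client, event date, event
#' label); events whose causality is classified `unlikely` are excluded.
#' Returns the retained event count, the distinct clients over retained
#' events, and how many retained events resulted in PrEP discontinuation.
#'
#' @param store an [event_store()].
#' @param quarter quarter label, or `NULL` for all quarters combined.
#' @param cfg an [indicator_config()].
#' @return a list with `events`, `distinct_clients`, `discontinuation_linked`.
#' @export
adr_event_count <- function(store, quarter = NULL, cfg = indicator_config()) {
  ar <- store$adr_reports
  if (!is.null(quarter)) {
    qs <- quarter_start(quarter); qe <- quarter_end(quarter)
    ar <- ar %>% filter(.data$event_date >= qs, .data$event_date <= qe)
  }
  events <- ar %>%
    mutate(.ord = row_number()) %>%
    arrange(.data$client_id, .data$event_date, .data$event_label, .data$.ord) %>%
    group_by(.data$client_id, .data$event_date, .data$event_label) %>%
    slice(1L) %>%
    ungroup() %>%
    filter(.data$causality != "unlikely")
  list(events = nrow(events),
       distinct_clients = n_distinct(events$client_id),
       discontinuation_linked = sum(events$resulted_in_discontinuation))
}
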