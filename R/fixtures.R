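# Tiny hand-built event stores with annotated expectations, used as shared
# edge-case fixtures by the test suite. Each element is list(store, annotations).

fx_client <- function(id, dob = "1985-06-15", ha = "Vancouver Coastal",
                      gender = "cis_male", gdate = "2018-01-05") {
  list(
    clients = tibble(client_id = id, date_of_birth = as.Date(dob),
                     ha_of_residence = ha),
    gender_history = tibble(client_id = id, effective_date = as.Date(gdate),
                            gender_identity = gender, seq = 1L))
}

fx_provider <- function(id = "P1", type = "family_physician",
                        ha = "Vancouver Coastal") {
  tibble(provider_id = id, provider_type = type, ha_of_practice = ha)
}

fx_disp <- function(id, fill, tablets = 30L, pickup = NA, usage = "daily",
                    prescriber = "P1", ha = "Vancouver Coastal") {
  tibble(client_id = id, prescriber_id = prescriber,
         fill_date = as.Date(fill), pickup_date = as.Date(pickup),
         tablets = as.integer(tablets), usage_type = usage,
         prescriber_ha_of_practice = ha)
}

fx_enrol <- function(id, auth, provider = "P1", risk = "d") {
  tibble(client_id = id, authorization_date = as.Date(auth),
         enrolling_provider_id = provider, risk_factors = risk,
         risk_factors_unknown = risk == "")
}

#' Named suite of tiny hand-built event stores
#'
#' Each fixture is a `list(store =, annotations =)` where the annotations are
#' hand-worked expected values for the edge case the fixture exercises:
#'
#' * `window_boundary`: tests at exactly -31/-30/+15/+16 days around one
#'   dispensation (coverage window endpoints).
#' * `lapse_boundary`: hand-worked inactive dates for a pre-cutover gap
#'   lapse, a post-cutover expected-refill lapse and a dominating formal
#'   notification, under both the `"cutover"` and the single-rule
#'   configurations.
#' * `dup_adr`: duplicate reports of one clinical event plus an "unlikely"
#'   event.
#' * `multi_provider`: one client dispensed by providers in two volume bins.
#' * `risk_combo`: the canonical risk-factor combination categories.
#'
#' @return a named list of fixtures.
#' @export
fixture_suite <- function() {
  out <- list()

  # --- window_boundary ----------------------------------------------------
  cl <- fx_client("W1")
  store <- event_store(
    clients = cl$clients, gender_history = cl$gender_history,
    enrolments = fx_enrol("W1", "2018-01-10"),
    dispensations = fx_disp("W1", "2018-04-10"),
    lab_tests = tibble(
      client_id = "W1",
      test_date = as.Date("2018-04-10") + c(-31, -30, 15, 16),
      assay = c("hiv", "syphilis", "hiv", "syphilis"),
      result = "negative"),
    providers = fx_provider())
  out$window_boundary <- list(
    store = store,
    annotations = list(
      dispense_date = as.Date("2018-04-10"),
      # -31 misses, -30 hits (syphilis); +15 hits (hiv), +16 misses
      hiv_covered = TRUE, syphilis_covered = TRUE,
      in_window = c(`-31` = FALSE, `-30` = TRUE, `15` = TRUE, `16` = FALSE)))

  # --- lapse_boundary -----------------------------------------------------
  clA <- fx_client("LA"); clB <- fx_client("LB"); clC <- fx_client("LC")
  store <- event_store(
    clients = bind_rows(clA$clients, clB$clients, clC$clients),
    gender_history = bind_rows(clA$gender_history, clB$gender_history,
                               clC$gender_history),
    enrolments = bind_rows(fx_enrol("LA", "2018-01-02"),
                           fx_enrol("LB", "2019-12-15"),
                           fx_enrol("LC", "2019-01-05")),
    dispensations = bind_rows(
      # LA: single pre-cutover fill 2018-01-10 (no pickup), 30 tablets daily.
      #   gap-rule candidate: 2018-07-10 + 1 day = 2018-07-11 (on/before
      #   2019-06-30, so the cutover configuration uses the gap rule)
      #   refill-rule candidate: supply ends 2018-02-09; +6m +1d = 2018-08-10
      fx_disp("LA", "2018-01-10"),
      # LB: single post-cutover fill picked up 2020-01-01, 30 tablets daily.
      #   supply ends 2020-01-31; +6 months = 2020-07-31; inactive 2020-08-01
      #   gap-rule candidate would be 2020-07-02
      fx_disp("LB", "2019-12-30", pickup = "2020-01-01"),
      # LC: quarterly 90-tablet fills continuing, but a formal notification
      #   2019-05-10 dominates any lapse
      fx_disp("LC", "2019-01-10", tablets = 90L),
      fx_disp("LC", "2019-04-10", tablets = 90L),
      fx_disp("LC", "2019-07-10", tablets = 90L)),
    notifications = tibble(client_id = "LC",
                           notification_date = as.Date("2019-05-10"),
                           kind = "formal_discontinuation"),
    providers = fx_provider())
  out$lapse_boundary <- list(
    store = store,
    annotations = list(
      LA = list(cutover = as.Date("2018-07-11"),
                gap = as.Date("2018-07-11"),
                refill = as.Date("2018-08-10"),
                reason_cutover = "lapse_between_prescriptions"),
      LB = list(cutover = as.Date("2020-08-01"),
                gap = as.Date("2020-07-02"),
                refill = as.Date("2020-08-01"),
                reason_cutover = "lapse_past_expected_refill"),
      LC = list(inactive = as.Date("2019-05-10"),
                reason = "formal_notification")))

  # --- dup_adr ------------------------------------------------------------
  cl1 <- fx_client("A1"); cl2 <- fx_client("A2")
  store <- event_store(
    clients = bind_rows(cl1$clients, cl2$clients),
    gender_history = bind_rows(cl1$gender_history, cl2$gender_history),
    enrolments = bind_rows(fx_enrol("A1", "2018-01-10"),
                           fx_enrol("A2", "2018-01-12")),
    dispensations = bind_rows(fx_disp("A1", "2018-02-01"),
                              fx_disp("A2", "2018-02-03")),
    adr_reports = tibble(
      report_id = sprintf("R%d", 1:4),
      client_id = c("A1", "A1", "A1", "A2"),
      event_date = as.Date(c("2018-03-01", "2018-03-01", "2018-04-01",
                             "2018-03-15")),
      event_label = c("nausea", "nausea", "rash", "headache"),
      causality = c("possible_or_higher", "possible_or_higher",
                    "unlikely", "possible_or_higher"),
      resulted_in_discontinuation = c(TRUE, TRUE, FALSE, FALSE)),
    providers = fx_provider())
  out$dup_adr <- list(
    store = store,
    annotations = list(events = 2L,         # nausea (deduped) + headache
                       distinct_clients = 2L,
                       discontinuation_linked = 1L))

  # --- multi_provider -----------------------------------------------------
  ids <- c("M1", sprintf("M%d", 2:7))
  cls <- lapply(ids, fx_client)
  providers <- bind_rows(fx_provider("P1"),
                         fx_provider("P2", type = "specialist_physician"))
  # P1 dispenses to M1 only (volume 1); P2 to M1..M7 (volume 7, bin 6-19)
  disps <- bind_rows(
    fx_disp("M1", "2018-02-01", prescriber = "P1"),
    bind_rows(lapply(ids, function(id) {
      fx_disp(id, "2018-02-15", prescriber = "P2")
    })))
  store <- event_store(
    clients = bind_rows(lapply(cls, `[[`, "clients")),
    gender_history = bind_rows(lapply(cls, `[[`, "gender_history")),
    enrolments = bind_rows(lapply(ids, function(id) fx_enrol(id, "2018-01-10"))),
    dispensations = disps,
    providers = providers)
  out$multi_provider <- list(
    store = store,
    annotations = list(
      quarter = "2018Q1",
      part_a = c("1" = 1, "6-19" = 1),          # two providers
      part_a_denominator = 2L,
      part_b = c("1" = 1, "6-19" = 7),          # M1 counted in both bins
      part_b_denominator = 7L))

  # --- risk_combo ---------------------------------------------------------
  ids <- c("K1", "K2", "K3", "K4")
  risks <- c("", "d", "a;d", "a;b;d")
  cls <- lapply(ids, fx_client)
  store <- event_store(
    clients = bind_rows(lapply(cls, `[[`, "clients")),
    gender_history = bind_rows(lapply(cls, `[[`, "gender_history")),
    enrolments = bind_rows(mapply(function(id, r) fx_enrol(id, "2018-01-10", risk = r),
                                  ids, risks, SIMPLIFY = FALSE)),
    dispensations = bind_rows(lapply(ids, function(id) fx_disp(id, "2018-02-01"))),
    providers = fx_provider())
  out$risk_combo <- list(
    store = store,
    annotations = list(
      quarter = "2018Q1",
      categories = c("none recorded" = 1, "d only" = 1, "a+d" = 1, "a+b+d" = 1),
      part_a = c(a = 2, b = 1, c = 0, d = 3, e = 0, f = 0),
      denominator = 4L))

  out
}
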