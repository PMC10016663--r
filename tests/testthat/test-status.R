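cfg <- indicator_config()

test_that("expected refill date follows the days-supply convention", {
  d <- tibble::tibble(fill_date = as.Date("2020-01-01"),
                      pickup_date = as.Date("2020-01-01"),
                      tablets = 30L, usage_type = "daily")
  expect_equal(expected_refill_date(d, cfg), as.Date("2020-01-31"))
  # fill-date fallback when pickup is unrecorded, 90-day supply
  d <- tibble::tibble(fill_date = as.Date("2020-01-01"),
                      pickup_date = as.Date(NA),
                      tablets = 90L, usage_type = "daily")
  expect_equal(expected_refill_date(d, cfg), as.Date("2020-03-31"))
  # non-daily use stretches the supply by the configured factor (default 2)
  d$usage_type <- "non_daily"
  d$tablets <- 30L
  expect_equal(expected_refill_date(d, cfg), as.Date("2020-01-01") + 60)
})

mk_status_store <- function(disp, notifications = NULL) {
  ids <- unique(disp$client_id)
  cl <- mk_clients(ids)
  event_store(clients = cl$clients, gender_history = cl$gender_history,
              enrolments = dplyr::bind_rows(lapply(ids, mk_enrol)),
              dispensations = disp,
              notifications = notifications,
              providers = mk_providers())
}

test_that("clients refilling on schedule never lapse", {
  fills <- as.Date("2018-02-01") + seq(0, 990, by = 90)
  store <- mk_status_store(
    dplyr::bind_rows(lapply(fills, function(f) mk_disp("C1", f, tablets = 90L))))
  tl <- classify_status(store, "C1", as_of = as.Date("2020-12-31"), cfg)
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$state, "active")
  expect_equal(tl$reason, "first_dispensation")
})

test_that("a single supply lapses 6 months past the expected refill date", {
  store <- mk_status_store(mk_disp("C1", "2019-12-30", pickup = "2020-01-01"))
  tl <- classify_status(store, "C1", as_of = as.Date("2020-09-01"), cfg)
  # supply ends 2020-01-31; +6 months = 2020-07-31 < as_of, so inactive
  expect_equal(tl$state, c("active", "inactive"))
  expect_equal(tl$reason[2], "lapse_past_expected_refill")
  expect_equal(tl$effective_date[2], as.Date("2020-08-01"))
  # before the lapse date the client is still active
  tl_early <- classify_status(store, "C1", as_of = as.Date("2020-07-31"), cfg)
  expect_equal(tl_early$state, "active")
})

test_that("formal notification dominates and is never re-activated", {
  store <- mk_status_store(
    dplyr::bind_rows(mk_disp("C1", "2019-01-10", tablets = 90L),
                     mk_disp("C1", "2019-04-10", tablets = 90L),
                     mk_disp("C1", "2019-07-10", tablets = 90L)),
    notifications = tibble::tibble(client_id = "C1",
                                   notification_date = as.Date("2019-05-10"),
                                   kind = "formal_discontinuation"))
  tl <- classify_status(store, "C1", as_of = as.Date("2020-12-31"), cfg)
  expect_equal(tl$state, c("active", "inactive"))
  expect_equal(tl$reason, c("first_dispensation", "formal_notification"))
  expect_equal(tl$effective_date[2], as.Date("2019-05-10"))
})

test_that("an earlier lapse wins over a later formal notification", {
  store <- mk_status_store(
    mk_disp("C1", "2018-01-10"),
    notifications = tibble::tibble(client_id = "C1",
                                   notification_date = as.Date("2019-03-01"),
                                   kind = "formal_discontinuation"))
  tl <- classify_status(store, "C1", as_of = as.Date("2020-12-31"), cfg)
  # gap-rule lapse 2018-07-11 precedes the notification
  expect_equal(tl$effective_date[2], as.Date("2018-07-11"))
  expect_equal(tl$reason[2], "lapse_between_prescriptions")
  expect_equal(nrow(tl), 2L)
})

test_that("a dispensation after a lapse re-activates the client", {
  store <- mk_status_store(
    dplyr::bind_rows(mk_disp("C1", "2019-10-01"),
                     mk_disp("C1", "2020-09-01")))
  tl <- classify_status(store, "C1", as_of = as.Date("2020-12-31"), cfg)
  # the scheduled lapse after the second fill falls beyond as_of
  expect_equal(tl$state, c("active", "inactive", "active"))
  expect_equal(tl$reason[3], "re_dispensation")
  expect_equal(tl$effective_date[3], as.Date("2020-09-01"))
  # with a later horizon the scheduled lapse entry appears
  tl2 <- classify_status(store, "C1", as_of = as.Date("2021-06-30"), cfg)
  expect_equal(tl2$state, c("active", "inactive", "active", "inactive"))
})

test_that("status is undefined for enrolled-but-never-dispensed clients", {
  cl <- mk_clients(c("C1", "C2"))
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = dplyr::bind_rows(mk_enrol("C1"), mk_enrol("C2")),
                       dispensations = mk_disp("C1", "2018-02-01"),
                       providers = mk_providers())
  expect_error(classify_status(store, "C2", as_of = as.Date("2018-12-31"), cfg),
               "no dispensation")
})

test_that("lapse-boundary fixture matches hand-worked timelines per rule", {
  fx <- fixture_suite()$lapse_boundary
  as_of <- as.Date("2020-12-31")
  for (rule in c("cutover", "gap", "refill")) {
    rcfg <- indicator_config(lapse_rule = rule)
    for (id in c("LA", "LB")) {
      tl <- classify_status(fx$store, id, as_of, rcfg)
      expect_equal(tl$effective_date[2], fx$annotations[[id]][[rule]],
                   label = paste(id, rule))
      if (rule == "cutover") {
        expect_equal(tl$reason[2], fx$annotations[[id]]$reason_cutover)
      }
    }
  }
  tl <- classify_status(fx$store, "LC", as_of, indicator_config())
  expect_equal(tl$effective_date[nrow(tl)], fx$annotations$LC$inactive)
  expect_equal(tl$reason[nrow(tl)], fx$annotations$LC$reason)
})

test_that("timeline states alternate with non-decreasing dates (simulated)", {
  sim <- get_demo_sim()
  tl <- status_timelines(sim$store, cfg)
  by_client <- split(tl, tl$client_id)
  for (t in by_client) {
    expect_equal(t$state[1], "active")
    expect_equal(t$reason[1], "first_dispensation")
    expect_true(all(diff(as.numeric(t$effective_date)) >= 0))
    expect_true(all(t$state[-1] != t$state[-nrow(t)]))  # strict alternation
    react <- which(t$state == "active")[-1]
    expect_true(all(t$reason[react] == "re_dispensation"))
  }
})

test_that("status counts partition the ever-dispensed denominator", {
  sim <- get_demo_sim()
  res <- status_counts(sim$store, "2019Q2", cfg)
  expect_equal(sum(res$rows$numerator), unique(res$rows$denominator))
  states <- res$rows
  expect_setequal(states$stratum, c("active", "inactive"))
})
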