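cfg <- indicator_config()

one_client_store <- function() {
  cl <- mk_clients("C1", dob = "1991-06-16")
  event_store(clients = cl$clients, gender_history = cl$gender_history,
              enrolments = mk_enrol("C1"),
              dispensations = mk_disp("C1", "2020-06-15"),
              providers = mk_providers())
}

test_that("dispensed distribution counts a lone cisgender-male client", {
  res <- dispensed_distribution(one_client_store(), "2020Q2", "gender", cfg)
  row <- res$rows[res$rows$stratum == "cis_male", ]
  expect_equal(row$numerator, 1)
  expect_equal(row$denominator, 1)
  expect_equal(row$percent, 100L)
  expect_equal(sum(res$rows$numerator), 1)
})

test_that("age bins use completed years at the dispensation date", {
  # born 1991-06-16, dispensed 2020-06-15: 28 completed years -> 18-28
  res <- dispensed_distribution(one_client_store(), "2020Q2", "age", cfg)
  expect_equal(res$rows$numerator[res$rows$stratum == "18-28"], 1)
  # dispensed one day later (the 29th birthday) -> 29-40
  cl <- mk_clients("C1", dob = "1991-06-16")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2020-06-16"),
                       providers = mk_providers())
  res <- dispensed_distribution(store, "2020Q2", "age", cfg)
  expect_equal(res$rows$numerator[res$rows$stratum == "29-40"], 1)
})

test_that("new enrolments stratify by provider type with display rounding", {
  cl <- mk_clients(c("C1", "C2", "C3"))
  store <- event_store(
    clients = cl$clients, gender_history = cl$gender_history,
    enrolments = dplyr::bind_rows(
      mk_enrol("C1", "2018-02-01", provider = "P1"),
      mk_enrol("C2", "2018-02-10", provider = "P1"),
      mk_enrol("C3", "2018-03-01", provider = "P2")),
    dispensations = mk_disp("C1", "2018-02-05"),
    providers = mk_providers(c("P1", "P2"),
                             type = c("family_physician", "specialist_physician")))
  res <- new_enrolments(store, "2018Q1", "provider_type", cfg)
  fp <- res$rows[res$rows$stratum == "family_physician", ]
  sp <- res$rows[res$rows$stratum == "specialist_physician", ]
  expect_equal(fp$numerator, 2); expect_equal(fp$percent, 67L)
  expect_equal(sp$numerator, 1); expect_equal(sp$percent, 33L)
  expect_equal(unique(res$rows$denominator), 3)

  # empty quarter: zero rows, percentages absent
  res0 <- new_enrolments(store, "2019Q3", "provider_type", cfg)
  expect_true(all(res0$rows$numerator == 0))
  expect_true(all(is.na(res0$rows$percent)))
})

test_that("first dispensations count each client exactly once, in one quarter", {
  cl <- mk_clients("C1")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = dplyr::bind_rows(
                         mk_disp("C1", "2018-02-01"),
                         mk_disp("C1", "2018-05-01")),
                       providers = mk_providers())
  q1 <- first_dispensations(store, "2018Q1", "ha_residence", cfg)
  q2 <- first_dispensations(store, "2018Q2", "ha_residence", cfg)
  expect_equal(sum(q1$rows$numerator), 1)
  expect_equal(sum(q2$rows$numerator), 0)
})

test_that("first dispensations over all quarters partition ever-dispensed clients", {
  sim <- get_demo_sim()
  per_q <- vapply(sim$quarters, function(q) {
    sum(first_dispensations(sim$store, q, "ha_residence", cfg)$rows$numerator)
  }, numeric(1))
  ever <- length(unique(sim$store$dispensations$client_id))
  expect_equal(sum(per_q), ever)
})

test_that("provider volume bins providers and covers clients per bin", {
  # hand enumeration: provider volumes [1, 1, 3, 60]
  ids <- sprintf("C%02d", 1:60)
  cl <- mk_clients(c(ids, "D1", "D2", "E1", "E2", "E3"))
  disp <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(ids, function(i) mk_disp(i, "2018-02-01", prescriber = "P4"))),
    mk_disp("D1", "2018-02-02", prescriber = "P1"),
    mk_disp("D2", "2018-02-03", prescriber = "P2"),
    dplyr::bind_rows(lapply(c("E1", "E2", "E3"),
                            function(i) mk_disp(i, "2018-02-04", prescriber = "P3"))))
  store <- event_store(
    clients = cl$clients, gender_history = cl$gender_history,
    enrolments = dplyr::bind_rows(lapply(cl$clients$client_id, mk_enrol)),
    dispensations = disp,
    providers = mk_providers(c("P1", "P2", "P3", "P4")))
  res <- provider_volume(store, "2018Q1", cfg)
  a <- res$a$rows
  expect_equal(a$numerator[a$stratum == "1"], 2)
  expect_equal(a$numerator[a$stratum == "2-5"], 1)
  expect_equal(a$numerator[a$stratum == "50+"], 1)
  expect_equal(unique(a$denominator), 4)
  expect_equal(sum(a$numerator), 4)
  b <- res$b$rows
  expect_equal(b$numerator[b$stratum == "50+"], 60)
  expect_equal(unique(b$denominator), 65)
})

test_that("a client seen by providers in two volume bins counts once per bin", {
  fx <- fixture_suite()$multi_provider
  res <- provider_volume(fx$store, fx$annotations$quarter, cfg)
  for (bin in names(fx$annotations$part_a)) {
    expect_equal(res$a$rows$numerator[res$a$rows$stratum == bin],
                 unname(fx$annotations$part_a[bin]), label = paste("a", bin))
  }
  expect_equal(unique(res$a$rows$denominator), fx$annotations$part_a_denominator)
  for (bin in names(fx$annotations$part_b)) {
    expect_equal(res$b$rows$numerator[res$b$rows$stratum == bin],
                 unname(fx$annotations$part_b[bin]), label = paste("b", bin))
  }
  expect_equal(unique(res$b$rows$denominator), fx$annotations$part_b_denominator)
  # coverage numerators may jointly exceed the distinct-client denominator
  expect_gt(sum(res$b$rows$numerator), fx$annotations$part_b_denominator)
})

test_that("risk factor profile splits factors and partitions combinations", {
  fx <- fixture_suite()$risk_combo
  res <- risk_factor_profile(fx$store, fx$annotations$quarter, cfg)
  for (f in names(fx$annotations$part_a)) {
    expect_equal(res$a$rows$numerator[res$a$rows$stratum == f],
                 unname(fx$annotations$part_a[f]), label = f)
  }
  expect_equal(unique(res$a$rows$denominator), 4)
  for (cat in names(fx$annotations$categories)) {
    expect_equal(res$b$rows$numerator[res$b$rows$stratum == cat],
                 unname(fx$annotations$categories[cat]), label = cat)
  }
  # part b partitions its denominator
  expect_equal(sum(res$b$rows$numerator), unique(res$b$rows$denominator))
  # part a selections are at least the clients in part b with >= 1 factor
  expect_gte(sum(res$a$rows$numerator), 3)
})

test_that("usage type uses the most recent dispensation before quarter end", {
  cl <- mk_clients("C1")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = dplyr::bind_rows(
                         mk_disp("C1", "2020-01-10", usage = "non_daily"),
                         mk_disp("C1", "2020-02-20", usage = "daily")),
                       providers = mk_providers())
  res <- usage_type_distribution(store, "2020Q1", cfg)
  expect_equal(res$rows$numerator[res$rows$stratum == "daily"], 1)
  expect_equal(res$rows$numerator[res$rows$stratum == "non_daily"], 0)
  expect_equal(unique(res$rows$denominator), 1)
})

test_that("tablet units divide by 30 and are conserved across strata", {
  cl <- mk_clients(c("C1", "C2"), ha = c("Fraser", "Northern"))
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = dplyr::bind_rows(mk_enrol("C1"), mk_enrol("C2")),
                       dispensations = dplyr::bind_rows(
                         mk_disp("C1", "2020-01-10", tablets = 90L),
                         mk_disp("C2", "2020-02-10", tablets = 50L)),
                       providers = mk_providers())
  res <- quantity_dispensed(store, "2020Q1", "ha_residence", cfg)
  expect_equal(res$rows$numerator[res$rows$stratum == "Fraser"], 3.0)
  expect_equal(res$rows$numerator[res$rows$stratum == "Northern"], 50 / 30)
  expect_equal(sum(res$rows$numerator), (90 + 50) / 30)
  expect_equal(unique(res$rows$denominator), (90 + 50) / 30)
  # empty quarter: zero units
  res0 <- quantity_dispensed(store, "2020Q3", "ha_residence", cfg)
  expect_equal(sum(res0$rows$numerator), 0)
})

test_that("testing coverage respects the window boundaries", {
  fx <- fixture_suite()$window_boundary
  # the -30 day syphilis test and +15 day hiv test are inside the window;
  # the -31 and +16 day tests are outside
  syph <- testing_coverage(fx$store, "2018Q2", "syphilis", cfg)
  hiv <- testing_coverage(fx$store, "2018Q2", "hiv", cfg)
  expect_equal(syph$rows$numerator, 1)
  expect_equal(hiv$rows$numerator, 1)
  expect_equal(syph$rows$denominator, 1)

  # nearest tests at -31 and +16 days: not covered
  cl <- mk_clients("C1")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2018-04-10"),
                       lab_tests = tibble::tibble(
                         client_id = "C1",
                         test_date = as.Date("2018-04-10") + c(-31, 16),
                         assay = "hiv", result = "negative"),
                       providers = mk_providers())
  expect_equal(testing_coverage(store, "2018Q2", "hiv", cfg)$rows$numerator, 0)
})

test_that("coverage numerators equal a brute-force all-pairs check", {
  sim <- get_demo_sim()
  q <- sim$quarters[length(sim$quarters)]
  for (assay in c("hiv", "syphilis")) {
    eng <- testing_coverage(sim$store, q, assay, cfg)
    expect_equal(eng$rows$numerator, oracle_coverage_count(sim$store, q, assay),
                 label = assay)
    expect_lte(eng$rows$numerator, eng$rows$denominator)
  }
})

test_that("days to first dispensation summarises prior negative HIV tests", {
  ids <- c("C1", "C2", "C3", "C4")
  cl <- mk_clients(ids)
  # gaps 3, 7, 30 days; C4 has no prior negative test
  disp <- dplyr::bind_rows(lapply(ids, function(i) mk_disp(i, "2020-02-01")))
  tests <- tibble::tibble(
    client_id = c("C1", "C2", "C3"),
    test_date = as.Date("2020-02-01") - c(3, 7, 30),
    assay = "hiv", result = "negative")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = dplyr::bind_rows(lapply(ids, mk_enrol)),
                       dispensations = disp, lab_tests = tests,
                       providers = mk_providers())
  res <- days_to_first_dispensation(store, cfg)
  expect_equal(res$n, 3)
  expect_equal(res$median, 7)
  expect_equal(res$n_no_prior_test, 1)

  # a negative test on the dispensation date itself gives gap 0
  tests2 <- dplyr::bind_rows(tests, tibble::tibble(
    client_id = "C4", test_date = as.Date("2020-02-01"),
    assay = "hiv", result = "negative"))
  store2 <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                        enrolments = dplyr::bind_rows(lapply(ids, mk_enrol)),
                        dispensations = disp, lab_tests = tests2,
                        providers = mk_providers())
  res2 <- days_to_first_dispensation(store2, cfg)
  expect_equal(res2$n, 4)
  expect_equal(res2$n_no_prior_test, 0)
})

test_that("gap quartiles match a sort-and-index oracle", {
  set.seed(7)
  gaps <- sample(0:120, 37, replace = TRUE)
  ids <- sprintf("C%02d", seq_along(gaps))
  cl <- mk_clients(ids)
  disp <- dplyr::bind_rows(lapply(ids, function(i) mk_disp(i, "2020-02-01")))
  tests <- tibble::tibble(client_id = ids,
                          test_date = as.Date("2020-02-01") - gaps,
                          assay = "hiv", result = "negative")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = dplyr::bind_rows(lapply(ids, mk_enrol)),
                       dispensations = disp, lab_tests = tests,
                       providers = mk_providers())
  res <- days_to_first_dispensation(store, cfg)
  oq <- oracle_quartiles(gaps)
  expect_equal(c(res$p25, res$median, res$p75), oq)
})

test_that("incident cases honour the active-client restriction", {
  cl <- mk_clients("C1")
  # client lapses mid-2020 (single 30-tablet fill in January), incident test
  # in Q4 while inactive
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2020-01-01",
                                               pickup = "2020-01-01"),
                       lab_tests = tibble::tibble(
                         client_id = "C1", test_date = as.Date("2020-11-15"),
                         assay = "syphilis", result = "positive_incident"),
                       providers = mk_providers())
  expect_equal(incident_cases(store, "2020Q4", "syphilis", TRUE, cfg), 0L)
  expect_equal(incident_cases(store, "2020Q4", "syphilis", FALSE, cfg), 1L)
  expect_equal(incident_cases(store, "2020Q2", "syphilis", TRUE, cfg), 0L)
})

test_that("ADR counts deduplicate events and drop unlikely causality", {
  fx <- fixture_suite()$dup_adr
  res <- adr_event_count(fx$store, quarter = NULL, cfg)
  expect_equal(res$events, fx$annotations$events)
  expect_equal(res$distinct_clients, fx$annotations$distinct_clients)
  expect_equal(res$discontinuation_linked, fx$annotations$discontinuation_linked)
  # quarter filtering by event date
  q1 <- adr_event_count(fx$store, "2018Q1", cfg)
  expect_equal(q1$events, 2L)  # both retained events fall in 2018 Q1
})

test_that("ADR discontinuation share reproduces the published proportion", {
  # 112 distinct retained events, 94 discontinuation-linked, plus duplicate
  # reports and unlikely-causality events that must be excluded
  n <- 112
  ids <- sprintf("C%03d", 1:n)
  cl <- mk_clients(ids)
  disp <- dplyr::bind_rows(lapply(ids, function(i) mk_disp(i, "2018-02-01")))
  base <- tibble::tibble(
    report_id = sprintf("R%03d", 1:n), client_id = ids,
    event_date = as.Date("2018-03-01") + (seq_len(n) %% 200),
    event_label = "nausea",
    causality = "possible_or_higher",
    resulted_in_discontinuation = c(rep(TRUE, 94), rep(FALSE, n - 94)))
  dupes <- base[1:20, ]; dupes$report_id <- sprintf("D%03d", 1:20)
  unlikely <- tibble::tibble(
    report_id = sprintf("U%03d", 1:8), client_id = ids[1:8],
    event_date = as.Date("2018-09-01"), event_label = "rash",
    causality = "unlikely", resulted_in_discontinuation = FALSE)
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = dplyr::bind_rows(lapply(ids, mk_enrol)),
                       dispensations = disp,
                       adr_reports = dplyr::bind_rows(base, dupes, unlikely),
                       providers = mk_providers())
  res <- adr_event_count(store, quarter = NULL, cfg)
  expect_equal(res$events, 112L)
  expect_equal(res$discontinuation_linked, 94L)
  expect_equal(percent(res$discontinuation_linked, res$events), 84L)
})

test_that("partition indicators sum to their denominators on simulated data", {
  sim <- get_demo_sim()
  rep <- build_quarterly_report(sim$store, sim$quarters[5])
  for (id in names(rep$blocks)) {
    for (el in rep$blocks[[id]]) {
      if (!inherits(el, "stratified_result")) next
      if (el$partition) {
        expect_equal(sum(el$rows$numerator), unique(el$rows$denominator),
                     label = paste("indicator", el$indicator_id, el$part,
                                   el$dimension))
      } else {
        expect_true(all(el$rows$numerator <= el$rows$denominator |
                          el$indicator_id == "8"),
                    label = paste("coverage", el$indicator_id))
      }
    }
  }
})
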