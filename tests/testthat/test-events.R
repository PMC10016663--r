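test_that("write then read is the identity on a simulated store", {
  sim <- get_demo_sim()
  dir <- withr::local_tempdir()
  write_event_store(sim$store, dir)
  back <- read_event_store(dir)
  for (tb in c("clients", "gender_history", "enrolments", "dispensations",
               "lab_tests", "adr_reports", "providers", "notifications")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(sim$store[[tb]]),
                 label = tb)
  }
})

test_that("an empty store writes exactly six header-only files", {
  store <- event_store()
  dir <- withr::local_tempdir()
  paths <- write_event_store(store, dir)
  expect_length(paths, 6)
  expect_false(file.exists(file.path(dir, "notifications.csv")))
  for (p in paths) expect_length(readLines(p), 1L)  # header only
  back <- read_event_store(dir)
  expect_equal(nrow(back$clients), 0L)
  expect_equal(nrow(back$notifications), 0L)
})

test_that("a missing pickup date is serialized as an empty field, not a date", {
  cl <- mk_clients("C1")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2018-02-01", pickup = NA),
                       providers = mk_providers())
  dir <- withr::local_tempdir()
  write_event_store(store, dir)
  raw <- readLines(file.path(dir, "dispensations.csv"))[2]
  fields <- strsplit(raw, ",")[[1]]
  expect_identical(fields[4], "")  # pickup_date column
  back <- read_event_store(dir)
  expect_true(is.na(back$dispensations$pickup_date))
})

test_that("referential integrity failures name the offending identifiers", {
  cl <- mk_clients("C1")
  expect_error(
    event_store(clients = cl$clients, gender_history = cl$gender_history,
                enrolments = mk_enrol("C1"),
                dispensations = mk_disp("X9", "2018-02-01"),
                providers = mk_providers()),
    "X9")
  expect_error(
    event_store(clients = cl$clients, gender_history = cl$gender_history,
                enrolments = mk_enrol("C1", provider = "P9"),
                dispensations = mk_disp("C1", "2018-02-01"),
                providers = mk_providers()),
    "P9")
})

test_that("validation rejects exactly the mutated invariant violations", {
  cl <- mk_clients(c("C1", "C2"))
  good <- list(clients = cl$clients, gender_history = cl$gender_history,
               enrolments = dplyr::bind_rows(mk_enrol("C1"), mk_enrol("C2")),
               dispensations = mk_disp("C1", "2018-02-01", pickup = "2018-02-02"),
               providers = mk_providers())
  expect_silent(do.call(event_store, good))

  bad <- good
  bad$dispensations$pickup_date <- as.Date("2018-01-15")  # pickup before fill
  expect_error(do.call(event_store, bad), "pickup_date before fill_date")

  bad <- good
  bad$dispensations$tablets <- 0L
  expect_error(do.call(event_store, bad), "non-positive tablet")

  bad <- good
  bad$clients <- dplyr::bind_rows(bad$clients, bad$clients[1, ])
  expect_error(do.call(event_store, bad), "duplicate client_id")

  bad <- good
  bad$enrolments$risk_factors[1] <- ""
  expect_error(do.call(event_store, bad), "not flagged unknown")

  bad <- good
  bad$enrolments$risk_factors[1] <- "z"
  expect_error(do.call(event_store, bad), "unknown risk-factor code")

  bad <- good
  bad$clients$date_of_birth[1] <- as.Date("2019-01-01")  # after events
  expect_error(do.call(event_store, bad), "date_of_birth")

  bad <- good
  bad$dispensations$usage_type <- "weekly"
  expect_error(do.call(event_store, bad), "invalid usage_type")
})

test_that("reader reports missing columns and unparseable dates by location", {
  cl <- mk_clients("C1")
  store <- event_store(clients = cl$clients, gender_history = cl$gender_history,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2018-02-01"),
                       providers = mk_providers())
  dir <- withr::local_tempdir()
  write_event_store(store, dir)

  # drop a required column
  disp <- readr::read_csv(file.path(dir, "dispensations.csv"),
                          show_col_types = FALSE)
  readr::write_csv(disp[setdiff(names(disp), "tablets")],
                   file.path(dir, "dispensations.csv"), na = "")
  expect_error(read_event_store(dir), "missing required column.*tablets")

  # corrupt a date
  write_event_store(store, dir)
  lines <- readLines(file.path(dir, "lab_tests.csv"))
  if (length(lines) == 1) {
    # ensure at least one test row exists for the mutation
    writeLines(c(lines, "C1,not-a-date,hiv,negative"),
               file.path(dir, "lab_tests.csv"))
  } else {
    lines[2] <- sub("\\d{4}-\\d{2}-\\d{2}", "2018-13-40", lines[2])
    writeLines(lines, file.path(dir, "lab_tests.csv"))
  }
  expect_error(read_event_store(dir), "unparseable date at data row")
})

test_that("gender history resolves most-recent identity with file-order ties", {
  cl <- mk_clients("C1")
  gh <- tibble::tibble(
    client_id = "C1",
    effective_date = as.Date(c("2018-01-02", "2018-06-01", "2018-06-01")),
    gender_identity = c("cis_male", "trans_female", "other_unspecified"),
    seq = 1:3)
  store <- event_store(clients = cl$clients, gender_history = gh,
                       enrolments = mk_enrol("C1"),
                       dispensations = mk_disp("C1", "2018-02-01"),
                       providers = mk_providers())
  expect_equal(gender_as_of(store, "2018-05-31")$gender_identity, "cis_male")
  # same-date tie: the later file record wins
  expect_equal(gender_as_of(store, "2018-06-01")$gender_identity,
               "other_unspecified")
})
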