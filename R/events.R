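#' @importFrom dplyr %>% mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join distinct n n_distinct row_number first
#'   bind_rows count rename if_else coalesce lead lag slice across full_join
#' @importFrom rlang .data
#' @importFrom lubridate %m+%
NULL

# controlled vocabularies ---------------------------------------------------

HA_LEVELS <- c("Interior", "Fraser", "Vancouver Coastal", "Vancouver Island",
               "Northern", "Unknown")
GENDER_LEVELS <- c("cis_male", "cis_female", "trans_male", "trans_female",
                   "other_unspecified")
PROVIDER_TYPES <- c("family_physician", "specialist_physician", "nurse_practitioner")
USAGE_TYPES <- c("daily", "non_daily")
ASSAYS <- c("hiv", "syphilis")
RESULTS <- c("negative", "positive_incident", "positive_prevalent", "indeterminate")
CAUSALITY <- c("possible_or_higher", "unlikely")
RISK_FACTORS <- c("a", "b", "c", "d", "e", "f")

# one entry per serialized table: column name -> type tag
# c = character, D = ISO date, i = integer, l = logical; "D?" allows empty
.table_schemas <- list(
  clients = c(client_id = "c", date_of_birth = "D?", ha_of_residence = "c",
              gender_identity = "c", gender_effective_date = "D"),
  enrolments = c(client_id = "c", authorization_date = "D",
                 enrolling_provider_id = "c", risk_factors = "c?",
                 risk_factors_unknown = "l"),
  dispensations = c(client_id = "c", prescriber_id = "c", fill_date = "D",
                    pickup_date = "D?", tablets = "i", usage_type = "c",
                    prescriber_ha_of_practice = "c"),
  lab_tests = c(client_id = "c", test_date = "D", assay = "c", result = "c"),
  adr_reports = c(report_id = "c", client_id = "c", event_date = "D",
                  event_label = "c", causality = "c",
                  resulted_in_discontinuation = "l"),
  providers = c(provider_id = "c", provider_type = "c", ha_of_practice = "c"),
  notifications = c(client_id = "c", notification_date = "D", kind = "c")
)

empty_table <- function(name) {
  schema <- .table_schemas[[name]]
  cols <- lapply(schema, function(tag) {
    switch(substr(tag, 1, 1),
           c = character(), D = as.Date(character()),
           i = integer(), l = logical())
  })
  tibble::as_tibble(cols)
}

#' Construct a validated program event store
#'
#' The event store is the in-memory form of the six (plus one optional)
#' delimited event tables a PrEP program's registry exports: client roster
#' (with a dated gender-identity history), enrolment authorizations, pharmacy
#' dispensations, laboratory test results, adverse-drug-reaction reports,
#' provider roster, and formal discontinuation notifications.
#'
#' In memory the client roster is split into `clients` (one row per client:
#' `client_id`, `date_of_birth`, `ha_of_residence`) and `gender_history`
#' (`client_id`, `effective_date`, `gender_identity`, `seq`); `seq` preserves
#' file order and breaks ties when two records share an effective date (the
#' later record wins).
#'
#' @param clients,gender_history,enrolments,dispensations,lab_tests,adr_reports,providers,notifications
#'   tibbles with the documented columns; missing arguments default to empty
#'   tables.
#' @param validate run [validate_event_store()] (default `TRUE`).
#' @return an object of class `event_store`.
#' @export
event_store <- function(clients = NULL, gender_history = NULL, enrolments = NULL,
                        dispensations = NULL, lab_tests = NULL, adr_reports = NULL,
                        providers = NULL, notifications = NULL, validate = TRUE) {
  or_empty <- function(x, name) {
    if (is.null(x)) return(empty_table(name))
    tibble::as_tibble(x)
  }
  store <- structure(list(
    clients = if (is.null(clients)) {
      tibble::tibble(client_id = character(), date_of_birth = as.Date(character()),
                     ha_of_residence = character())
    } else tibble::as_tibble(clients),
    gender_history = if (is.null(gender_history)) {
      tibble::tibble(client_id = character(), effective_date = as.Date(character()),
                     gender_identity = character(), seq = integer())
    } else tibble::as_tibble(gender_history),
    enrolments = or_empty(enrolments, "enrolments"),
    dispensations = or_empty(dispensations, "dispensations"),
    lab_tests = or_empty(lab_tests, "lab_tests"),
    adr_reports = or_empty(adr_reports, "adr_reports"),
    providers = or_empty(providers, "providers"),
    notifications = or_empty(notifications, "notifications")
  ), class = "event_store")
  if (!"seq" %in% names(store$gender_history)) {
    store$gender_history$seq <- seq_len(nrow(store$gender_history))
  }
  if (validate) validate_event_store(store)
  store
}

#' @export
print.event_store <- function(x, ...) {
  cat("<event_store>\n")
  cat(sprintf("  clients:        %6d\n", nrow(x$clients)))
  cat(sprintf("  enrolments:     %6d\n", nrow(x$enrolments)))
  cat(sprintf("  dispensations:  %6d\n", nrow(x$dispensations)))
  cat(sprintf("  lab tests:      %6d\n", nrow(x$lab_tests)))
  cat(sprintf("  ADR reports:    %6d\n", nrow(x$adr_reports)))
  cat(sprintf("  providers:      %6d\n", nrow(x$providers)))
  cat(sprintf("  notifications:  %6d\n", nrow(x$notifications)))
  invisible(x)
}

#' Validate the referential and domain invariants of an event store
#'
#' Checks identifier uniqueness, referential integrity (every referenced
#' client/provider exists in its roster), controlled vocabularies, date
#' ordering (pickup on/after fill, birth before any event, gender history
#' non-decreasing, notification on/after authorization), positive tablet
#' counts, and the risk-factor contract (an empty factor set must be flagged
#' unknown). Stops with a message naming the offending rows on the first
#' group of violations found.
#'
#' @param store an [event_store()].
#' @return the store, invisibly.
#' @export
validate_event_store <- function(store) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  few <- function(x) paste(utils::head(unique(x), 5), collapse = ", ")

  cl <- store$clients
  if (anyDuplicated(cl$client_id)) {
    note(paste0("duplicate client_id in client roster: ",
                few(cl$client_id[duplicated(cl$client_id)])))
  }
  pr <- store$providers
  if (anyDuplicated(pr$provider_id)) {
    note(paste0("duplicate provider_id in provider roster: ",
                few(pr$provider_id[duplicated(pr$provider_id)])))
  }
  if (anyDuplicated(store$adr_reports$report_id)) {
    note(paste0("duplicate report_id in ADR reports: ",
                few(store$adr_reports$report_id[duplicated(store$adr_reports$report_id)])))
  }
  if (anyDuplicated(store$enrolments$client_id)) {
    note(paste0("more than one enrolment authorization per client: ",
                few(store$enrolments$client_id[duplicated(store$enrolments$client_id)])))
  }

  # referential integrity
  ref_check <- function(ids, label) {
    orphan <- setdiff(ids, cl$client_id)
    if (length(orphan)) {
      note(paste0(label, " references unknown client_id: ", few(orphan)))
    }
  }
  ref_check(store$gender_history$client_id, "gender history")
  ref_check(store$enrolments$client_id, "enrolments")
  ref_check(store$dispensations$client_id, "dispensations")
  ref_check(store$lab_tests$client_id, "lab tests")
  ref_check(store$adr_reports$client_id, "ADR reports")
  ref_check(store$notifications$client_id, "notifications")
  orphan_prov <- setdiff(c(store$dispensations$prescriber_id,
                           store$enrolments$enrolling_provider_id),
                         pr$provider_id)
  if (length(orphan_prov)) {
    note(paste0("unknown provider id referenced: ", few(orphan_prov)))
  }

  # controlled vocabularies
  vocab <- function(x, levels, label) {
    bad <- setdiff(stats::na.omit(unique(x)), levels)
    if (length(bad)) note(paste0("invalid ", label, ": ", few(bad)))
  }
  vocab(cl$ha_of_residence, HA_LEVELS, "ha_of_residence")
  vocab(store$gender_history$gender_identity, GENDER_LEVELS, "gender_identity")
  vocab(pr$provider_type, PROVIDER_TYPES, "provider_type")
  vocab(pr$ha_of_practice, HA_LEVELS, "provider ha_of_practice")
  vocab(store$dispensations$usage_type, USAGE_TYPES, "usage_type")
  vocab(store$dispensations$prescriber_ha_of_practice, HA_LEVELS,
        "prescriber_ha_of_practice")
  vocab(store$lab_tests$assay, ASSAYS, "assay")
  vocab(store$lab_tests$result, RESULTS, "test result")
  vocab(store$adr_reports$causality, CAUSALITY, "ADR causality")
  vocab(store$notifications$kind, "formal_discontinuation", "notification kind")

  dp <- store$dispensations
  if (nrow(dp)) {
    bad <- which(!is.na(dp$pickup_date) & dp$pickup_date < dp$fill_date)
    if (length(bad)) note(paste0("pickup_date before fill_date for client(s): ",
                                 few(dp$client_id[bad])))
    bad <- which(is.na(dp$tablets) | dp$tablets <= 0)
    if (length(bad)) note(paste0("non-positive tablet count for client(s): ",
                                 few(dp$client_id[bad])))
  }

  en <- store$enrolments
  if (nrow(en)) {
    sets <- parse_risk_factors(en$risk_factors)
    bad_letters <- which(vapply(sets, function(s) length(setdiff(s, RISK_FACTORS)) > 0,
                                logical(1)))
    if (length(bad_letters)) {
      note(paste0("unknown risk-factor code for client(s): ", few(en$client_id[bad_letters])))
    }
    bad_empty <- which(lengths(sets) == 0 & !en$risk_factors_unknown)
    if (length(bad_empty)) {
      note(paste0("empty risk-factor set not flagged unknown for client(s): ",
                  few(en$client_id[bad_empty])))
    }
  }

  gh <- store$gender_history
  if (nrow(gh)) {
    dec <- gh %>%
      arrange(.data$client_id, .data$seq) %>%
      group_by(.data$client_id) %>%
      summarise(ok = !is.unsorted(.data$effective_date), .groups = "drop")
    if (any(!dec$ok)) {
      note(paste0("gender history dates decrease for client(s): ",
                  few(dec$client_id[!dec$ok])))
    }
  }

  # date_of_birth precedes every event of the client
  ev_dates <- bind_rows(
    store$dispensations %>% select(client_id = "client_id", date = "fill_date"),
    store$lab_tests %>% select(client_id = "client_id", date = "test_date"),
    store$enrolments %>% select(client_id = "client_id", date = "authorization_date"),
    store$adr_reports %>% select(client_id = "client_id", date = "event_date")
  )
  if (nrow(ev_dates) && nrow(cl)) {
    first_ev <- ev_dates %>% group_by(.data$client_id) %>%
      summarise(min_date = min(.data$date), .groups = "drop") %>%
      inner_join(cl, by = "client_id") %>%
      filter(!is.na(.data$date_of_birth), .data$date_of_birth >= .data$min_date)
    if (nrow(first_ev)) {
      note(paste0("date_of_birth on/after an event for client(s): ",
                  few(first_ev$client_id)))
    }
  }

  nt <- store$notifications
  if (nrow(nt) && nrow(en)) {
    bad <- nt %>% inner_join(en, by = "client_id") %>%
      filter(.data$notification_date < .data$authorization_date)
    if (nrow(bad)) {
      note(paste0("notification before authorization for client(s): ",
                  few(bad$client_id)))
    }
  }

  if (length(problems)) {
    stop("event store validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(store)
}

# risk-factor serialization: semicolon-joined letters, "" = none recorded
parse_risk_factors <- function(x) {
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

format_risk_factors <- function(sets) {
  vapply(sets, function(s) paste(sort(s), collapse = ";"), character(1))
}

# reading ------------------------------------------------------------------

parse_iso_dates <- function(x, table, col, required = TRUE) {
  x[!is.na(x) & x == ""] <- NA_character_
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("table '%s', column '%s': unparseable date at data row(s) %s",
                 table, col, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (required) {
    miss <- which(is.na(x))
    if (length(miss)) {
      stop(sprintf("table '%s', column '%s': missing date at data row(s) %s",
                   table, col, paste(utils::head(miss, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  out
}

read_one_table <- function(path, name) {
  schema <- .table_schemas[[name]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("table '%s' (%s): missing required column(s): %s",
                 name, path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[names(schema)]
  for (col in names(schema)) {
    tag <- schema[[col]]
    raw[[col]] <- switch(substr(tag, 1, 1),
      c = {
        v <- raw[[col]]
        if (endsWith(tag, "?")) v else {
          if (any(v == "")) {
            stop(sprintf("table '%s', column '%s': empty value at data row(s) %s",
                         name, col,
                         paste(utils::head(which(v == ""), 5), collapse = ", ")),
                 call. = FALSE)
          }
          v
        }
      },
      D = parse_iso_dates(raw[[col]], name, col, required = !endsWith(tag, "?")),
      i = {
        v <- suppressWarnings(as.integer(raw[[col]]))
        bad <- which(raw[[col]] != "" & is.na(v))
        if (length(bad)) {
          stop(sprintf("table '%s', column '%s': non-integer value at data row(s) %s",
                       name, col, paste(utils::head(bad, 5), collapse = ", ")),
               call. = FALSE)
        }
        v
      },
      l = {
        v <- toupper(raw[[col]]) %in% c("TRUE", "T", "1")
        bad <- which(!toupper(raw[[col]]) %in% c("TRUE", "T", "1", "FALSE", "F", "0"))
        if (length(bad)) {
          stop(sprintf("table '%s', column '%s': non-logical value at data row(s) %s",
                       name, col, paste(utils::head(bad, 5), collapse = ", ")),
               call. = FALSE)
        }
        v
      })
  }
  raw
}

#' Read a program event store from delimited text tables
#'
#' @param paths either a directory containing the canonical file names
#'   (`clients.csv`, `enrolments.csv`, `dispensations.csv`, `lab_tests.csv`,
#'   `adr_reports.csv`, `providers.csv`, and optionally `notifications.csv`),
#'   or a named character vector of file paths with those table names.
#' @param validate run [validate_event_store()] after assembly.
#' @return an [event_store()].
#' @export
read_event_store <- function(paths, validate = TRUE) {
  tables <- names(.table_schemas)
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- stats::setNames(file.path(paths, paste0(tables, ".csv")), tables)
  }
  required <- setdiff(tables, "notifications")
  missing_req <- required[!required %in% names(paths) | !file.exists(paths[required])]
  if (length(missing_req)) {
    stop("missing event table file(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }

  roster <- read_one_table(paths[["clients"]], "clients")
  clients <- roster %>%
    distinct(.data$client_id, .keep_all = TRUE) %>%
    select("client_id", "date_of_birth", "ha_of_residence")
  incons <- roster %>%
    distinct(.data$client_id, .data$date_of_birth, .data$ha_of_residence) %>%
    count(.data$client_id) %>% filter(.data$n > 1)
  if (nrow(incons)) {
    stop("client roster: inconsistent date_of_birth/ha_of_residence across gender ",
         "history rows for client(s): ",
         paste(utils::head(incons$client_id, 5), collapse = ", "), call. = FALSE)
  }
  gender_history <- roster %>%
    mutate(seq = row_number()) %>%
    group_by(.data$client_id) %>%
    mutate(seq = row_number()) %>%
    ungroup() %>%
    select("client_id", effective_date = "gender_effective_date",
           gender_identity = "gender_identity", "seq")

  notif <- if ("notifications" %in% names(paths) && file.exists(paths[["notifications"]])) {
    tb <- read_one_table(paths[["notifications"]], "notifications")
    tb
  } else {
    empty_table("notifications")
  }

  event_store(
    clients = clients,
    gender_history = gender_history,
    enrolments = read_one_table(paths[["enrolments"]], "enrolments"),
    dispensations = read_one_table(paths[["dispensations"]], "dispensations"),
    lab_tests = read_one_table(paths[["lab_tests"]], "lab_tests"),
    adr_reports = read_one_table(paths[["adr_reports"]], "adr_reports"),
    providers = read_one_table(paths[["providers"]], "providers"),
    notifications = notif,
    validate = validate
  )
}

#' Write a program event store as delimited text tables
#'
#' Serializes the store to UTF-8 comma-delimited files with header rows.
#' Missing values (an unrecorded pickup date) are written as empty fields.
#' `notifications.csv` is written only when the store holds notifications, so
#' an empty store produces exactly six header-only files.
#' `read_event_store()` composed with `write_event_store()` is the identity on
#' every field.
#'
#' @param store an [event_store()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths written, invisibly.
#' @export
write_event_store <- function(store, dir) {
  stopifnot(inherits(store, "event_store"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write1 <- function(tb, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tb, path, na = "")
    path
  }
  roster <- store$gender_history %>%
    arrange(.data$client_id, .data$seq) %>%
    left_join(store$clients, by = "client_id") %>%
    select("client_id", "date_of_birth", "ha_of_residence",
           gender_identity = "gender_identity",
           gender_effective_date = "effective_date")
  # keep original client order from the roster table
  ord <- match(roster$client_id, store$clients$client_id)
  roster <- roster[order(ord), ]

  out <- c(
    clients = write1(roster, "clients"),
    enrolments = write1(store$enrolments, "enrolments"),
    dispensations = write1(store$dispensations, "dispensations"),
    lab_tests = write1(store$lab_tests, "lab_tests"),
    adr_reports = write1(store$adr_reports, "adr_reports"),
    providers = write1(store$providers, "providers")
  )
  if (nrow(store$notifications)) {
    out <- c(out, notifications = write1(store$notifications, "notifications"))
  }
  invisible(out)
}

# effective dispense date: pickup when recorded, else fill (applied uniformly)
with_effective_dates <- function(dispensations) {
  dispensations %>%
    mutate(effective_date = coalesce(.data$pickup_date, .data$fill_date),
           .disp_id = row_number())
}

#' Most recently recorded gender identity per client
#'
#' Resolves the dated gender-identity history at a reference date: the record
#' with the latest effective date on/before `as_of` wins; ties on the same
#' date are broken by file order (the later record wins).
#'
#' @param store an [event_store()].
#' @param as_of reference `Date`.
#' @return tibble with `client_id`, `gender_identity`.
#' @export
gender_as_of <- function(store, as_of) {
  gh <- store$gender_history
  gh <- gh[gh$effective_date <= as.Date(as_of), ]
  gh <- gh[order(gh$client_id, gh$effective_date, gh$seq), ]
  gh[!duplicated(gh$client_id, fromLast = TRUE), c("client_id", "gender_identity")]
}
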