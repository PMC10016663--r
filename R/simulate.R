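#' Simulation configuration for the synthetic PrEP cohort
#'
#' Defaults emulate the structure of a province-wide publicly funded PrEP
#' program over 12 calendar quarters: enrolment growing quarter over quarter
#' to roughly 2,000 clients, ~98.5% cisgender-male clients concentrated in
#' one urban health authority, refill cadences implied by 30/60/90-tablet
#' supplies, laboratory tests scheduled around dispensations, rare HIV
#' seroconversion, occasional incident syphilis, silent refill lapses and
#' formal discontinuations, and adverse-drug-reaction reports including
#' duplicates and "unlikely" causality classifications.
#'
#' All probabilities are per the unit stated in the argument name; mixes must
#' sum to 1.
#'
#' @param start_quarter first enrolment quarter.
#' @param n_quarters number of quarters simulated.
#' @param base_arrivals,arrival_growth arrivals in the first quarter and the
#'   multiplicative growth per quarter.
#' @param covid_dip optional `list(quarter =, factor =)` scaling arrivals in
#'   one quarter (an arrival-rate dip scenario); `NULL` disables it.
#' @param gender_mix,age_mix,ha_mix,provider_type_mix,risk_mix,tablets_mix
#'   named probability vectors. `risk_mix` names are semicolon-joined
#'   risk-factor codes (`""` = none recorded). `age_mix` names the age bins.
#' @param gender_change_prob probability a client records a later gender
#'   identity change.
#' @param n_providers,provider_weight_sd provider pool size and the log-sd of
#'   the caseload weights (heavier tails concentrate clients on few
#'   providers).
#' @param alt_provider_prob per-dispensation probability of an alternate
#'   prescriber.
#' @param never_dispense_prob probability an authorized client never picks up
#'   a prescription.
#' @param first_disp_delay_max max days from authorization to first fill.
#' @param nondaily_prob,usage_switch_prob non-daily usage share and
#'   per-refill switch probability.
#' @param pickup_recorded_prob,pickup_delay_max probability the pickup date
#'   is recorded, and its max lag after the fill date.
#' @param refill_jitter integer range (days) added to the supply length
#'   between refills.
#' @param silent_lapse_prob,break_prob,formal_disc_prob per-refill
#'   probabilities of stopping silently, taking a lapse-length break then
#'   returning, or formally discontinuing.
#' @param hiv_test_prob,syphilis_test_prob per-dispensation probability of a
#'   test scheduled inside the coverage window.
#' @param out_of_window_test_prob per-dispensation probability of an extra
#'   test just outside the window.
#' @param baseline_hiv_test_prob,baseline_test_max_days probability and max
#'   lead time of a negative HIV test before the first dispensation.
#' @param syphilis_incidence_qtr,hiv_incidence_qtr per-active-client
#'   per-quarter incidence probabilities.
#' @param adr_prob,adr_duplicate_prob,adr_unlikely_prob,adr_discont_prob
#'   adverse-drug-reaction report parameters: lifetime event probability per
#'   dispensed client, duplicate-report probability, "unlikely" causality
#'   probability, and probability the event resulted in discontinuation.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(start_quarter = "2018Q1",
                       n_quarters = 12L,
                       base_arrivals = 85,
                       arrival_growth = 1.12,
                       covid_dip = NULL,
                       gender_mix = c(cis_male = 0.985, cis_female = 0.004,
                                      trans_male = 0.003, trans_female = 0.005,
                                      other_unspecified = 0.003),
                       gender_change_prob = 0.01,
                       age_mix = c("<18" = 0.005, "18-28" = 0.30, "29-40" = 0.43,
                                   "41-48" = 0.15, "49+" = 0.115),
                       ha_mix = c(Interior = 0.05, Fraser = 0.13,
                                  "Vancouver Coastal" = 0.68,
                                  "Vancouver Island" = 0.09,
                                  Northern = 0.03, Unknown = 0.02),
                       n_providers = 160L,
                       provider_type_mix = c(family_physician = 0.60,
                                             specialist_physician = 0.25,
                                             nurse_practitioner = 0.15),
                       provider_weight_sd = 1.8,
                       alt_provider_prob = 0.03,
                       risk_mix = c("d" = 0.72, "a;d" = 0.16, "a" = 0.04,
                                    "b;d" = 0.02, "a;b;d" = 0.013, "c" = 0.01,
                                    "e" = 0.008, "f" = 0.004, "none" = 0.025),
                       never_dispense_prob = 0.034,
                       first_disp_delay_max = 60L,
                       tablets_mix = c("30" = 0.55, "60" = 0.15, "90" = 0.30),
                       nondaily_prob = 0.05,
                       usage_switch_prob = 0.02,
                       pickup_recorded_prob = 0.8,
                       pickup_delay_max = 2L,
                       refill_jitter = c(-3L, 7L),
                       silent_lapse_prob = 0.02,
                       break_prob = 0.01,
                       formal_disc_prob = 0.008,
                       hiv_test_prob = 0.88,
                       syphilis_test_prob = 0.75,
                       out_of_window_test_prob = 0.05,
                       baseline_hiv_test_prob = 0.97,
                       baseline_test_max_days = 45L,
                       syphilis_incidence_qtr = 0.01,
                       hiv_incidence_qtr = 0.0004,
                       adr_prob = 0.015,
                       adr_duplicate_prob = 0.25,
                       adr_unlikely_prob = 0.15,
                       adr_discont_prob = 0.84) {
  cfg <- as.list(environment())
  for (nm in c("gender_mix", "age_mix", "ha_mix", "provider_type_mix",
               "risk_mix", "tablets_mix")) {
    mx <- cfg[[nm]]
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-8) {
      stop("invalid mix '", nm, "': probabilities must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  probs <- c(cfg$gender_change_prob, cfg$alt_provider_prob, cfg$never_dispense_prob,
             cfg$nondaily_prob, cfg$usage_switch_prob, cfg$pickup_recorded_prob,
             cfg$silent_lapse_prob, cfg$break_prob, cfg$formal_disc_prob,
             cfg$hiv_test_prob, cfg$syphilis_test_prob, cfg$out_of_window_test_prob,
             cfg$baseline_hiv_test_prob, cfg$syphilis_incidence_qtr,
             cfg$hiv_incidence_qtr, cfg$adr_prob, cfg$adr_duplicate_prob,
             cfg$adr_unlikely_prob, cfg$adr_discont_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  assert_quarter(cfg$start_quarter)
  structure(cfg, class = "sim_config")
}

# --- independent helpers used for ground-truth bookkeeping ----------------
# These deliberately re-derive calendar/bin arithmetic from the stated rules
# rather than calling the engine, so the ground truth is an independent
# oracle. They assume the *default* indicator configuration.

sim_quarter_of <- function(d) {
  lt <- as.POSIXlt(d)
  paste0(lt$year + 1900L, "Q", lt$mon %/% 3L + 1L)
}

sim_add_months <- function(d, m) {
  lt <- as.POSIXlt(d)
  mon0 <- lt$mon + m
  y <- lt$year + 1900L + mon0 %/% 12L
  mo <- mon0 %% 12L + 1L
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  mdays <- c(31L, ifelse(leap, 29L, 28L), 31L, 30L, 31L, 30L, 31L, 31L, 30L,
             31L, 30L, 31L)[mo]
  as.Date(sprintf("%04d-%02d-%02d", y, mo, pmin(lt$mday, mdays)))
}

# stated lapse rule, default configuration: gap rule when its candidate date
# falls on/before 2019-06-30, expected-refill rule otherwise
sim_lapse_date <- function(eff, sdays) {
  cut_end <- as.Date("2019-06-30")
  g <- sim_add_months(eff, 6L) + 1L
  if (g <= cut_end) g else sim_add_months(eff + sdays, 6L) + 1L
}

sim_age <- function(dob, at) {
  b <- as.POSIXlt(dob); a <- as.POSIXlt(at)
  (a$year - b$year) - as.integer(a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday))
}

sim_age_bin <- function(a) {
  ifelse(a < 18, "<18",
  ifelse(a <= 28, "18-28",
  ifelse(a <= 40, "29-40",
  ifelse(a <= 48, "41-48", "49+"))))
}

sim_vol_bin <- function(v) {
  ifelse(v == 1, "1",
  ifelse(v <= 5, "2-5",
  ifelse(v <= 19, "6-19",
  ifelse(v <= 49, "20-49", "50+"))))
}

sim_risk_label <- function(risk_string) {
  vapply(strsplit(ifelse(risk_string == "", "", risk_string), ";", fixed = TRUE),
         function(s) {
           s <- sort(unique(s))
           if (!length(s)) "none recorded"
           else if (length(s) == 1L) paste(s, "only")
           else paste(s, collapse = "+")
         }, character(1))
}

sim_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (!n) return(c(NA_real_, NA_real_, NA_real_))
  vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# age sampled uniformly within the configured bin (completed years)
.age_bin_ranges <- list("<18" = c(16, 17), "18-28" = c(18, 28), "29-40" = c(29, 40),
                        "41-48" = c(41, 48), "49+" = c(49, 64))

#' Simulate a synthetic PrEP-program cohort with bookkept ground truth
#'
#' Generates the six program event tables together with the exact indicator
#' values the scripted events imply. Ground truth is bookkept during
#' generation (client attributes, scripted status episodes, brute-force
#' window matches on the final test table), not by running the indicator
#' engine, so it is an independent oracle for every pipeline stage. The
#' ground truth assumes the default [indicator_config()].
#'
#' @param config a [sim_config()].
#' @param seed integer random seed; a fixed seed reproduces the store
#'   byte-for-byte.
#' @return a list with elements
#'   \describe{
#'     \item{store}{an [event_store()];}
#'     \item{truth}{a list: `cells` (tibble `quarter, indicator, part,
#'       dimension, stratum, numerator`), `denoms` (tibble `quarter,
#'       indicator, part, dimension, denominator`);}
#'     \item{quarters}{the simulated quarter labels.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  qs <- quarter_seq(config$start_quarter, n = config$n_quarters)
  data_start <- quarter_start(qs[1])
  data_end <- quarter_end(qs[length(qs)])

  set.seed(as.integer(seed))
  stream_seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  # ---- stream 1: providers, clients, enrolments --------------------------
  set.seed(stream_seeds[1])
  np <- config$n_providers
  providers <- tibble(
    provider_id = sprintf("P%04d", seq_len(np)),
    provider_type = sample(names(config$provider_type_mix), np, replace = TRUE,
                           prob = config$provider_type_mix),
    ha_of_practice = sample(names(config$ha_mix), np, replace = TRUE,
                            prob = config$ha_mix),
    weight = stats::rlnorm(np, 0, config$provider_weight_sd))

  arrivals <- round(config$base_arrivals * config$arrival_growth^(seq_along(qs) - 1L))
  if (!is.null(config$covid_dip)) {
    hit <- match(config$covid_dip$quarter, qs)
    if (!is.na(hit)) arrivals[hit] <- round(arrivals[hit] * config$covid_dip$factor)
  }
  n_clients <- sum(arrivals)
  arrival_q <- rep(qs, arrivals)
  qstarts <- quarter_start(arrival_q)
  qlen <- as.integer(quarter_end(arrival_q) - qstarts) + 1L

  age_bins <- sample(names(config$age_mix), n_clients, replace = TRUE,
                     prob = config$age_mix)
  age_years <- vapply(age_bins, function(b) {
    r <- .age_bin_ranges[[b]]
    sample(r[1]:r[2], 1L)
  }, numeric(1))

  clients <- tibble(
    client_id = sprintf("C%05d", seq_len(n_clients)),
    arrival_q = arrival_q,
    authorization_date = qstarts + floor(stats::runif(n_clients) * qlen),
    gender0 = sample(names(config$gender_mix), n_clients, replace = TRUE,
                     prob = config$gender_mix),
    ha_of_residence = sample(names(config$ha_mix), n_clients, replace = TRUE,
                             prob = config$ha_mix),
    risk = {
      r <- sample(names(config$risk_mix), n_clients, replace = TRUE,
                  prob = config$risk_mix)
      ifelse(r == "none", "", r)
    },
    primary_provider = sample(providers$provider_id, n_clients, replace = TRUE,
                              prob = providers$weight),
    never_dispense = stats::runif(n_clients) < config$never_dispense_prob,
    nondaily = stats::runif(n_clients) < config$nondaily_prob)
  clients$date_of_birth <- clients$authorization_date -
    round(age_years * 365.25) - sample(0:120, n_clients, replace = TRUE)

  has_change <- stats::runif(n_clients) < config$gender_change_prob
  change_delay <- sample(30:500, n_clients, replace = TRUE)
  change_date <- clients$authorization_date + change_delay
  new_gender <- vapply(clients$gender0, function(g) {
    sample(setdiff(names(config$gender_mix), g), 1L)
  }, character(1))
  clients$gender_change_date <- dplyr::if_else(
    has_change & change_date <= data_end, change_date, as.Date(NA))
  clients$gender_change_to <- ifelse(!is.na(clients$gender_change_date),
                                     new_gender, NA_character_)

  # ---- stream 2: dispensation schedules and status episodes --------------
  set.seed(stream_seeds[2])
  prov_ha <- stats::setNames(providers$ha_of_practice, providers$provider_id)
  tablets_lv <- as.integer(names(config$tablets_mix))
  jit <- config$refill_jitter

  episodes <- vector("list", n_clients)   # per client: list(inact =, ret =)
  notif_date <- rep(as.Date(NA), n_clients)
  # accumulated dispensation columns (dates as numeric days; NA = no pickup)
  acc <- list(client = character(), fill = numeric(), pickup = numeric(),
              eff = numeric(), tablets = integer(), usage = character(),
              prescriber = character())
  data_end_n <- as.numeric(data_end)
  auth_n <- as.numeric(clients$authorization_date)
  p1 <- config$formal_disc_prob
  p2 <- p1 + config$silent_lapse_prob
  p3 <- p2 + config$break_prob

  for (i in seq_len(n_clients)) {
    if (clients$never_dispense[i]) next
    fill <- auth_n[i] + sample(0:config$first_disp_delay_max, 1L)
    if (fill > data_end_n) next
    usage_nondaily <- clients$nondaily[i]
    f_fill <- numeric(); f_pickup <- numeric(); f_eff <- numeric()
    f_tab <- integer(); f_usage <- character(); f_presc <- character()
    inact <- numeric(); ret <- numeric()
    pending_lapse <- NA_real_
    repeat {
      tablets <- sample(tablets_lv, 1L, prob = config$tablets_mix)
      pickup <- if (stats::runif(1) < config$pickup_recorded_prob) {
        fill + sample(0:config$pickup_delay_max, 1L)
      } else NA_real_
      eff <- if (is.na(pickup)) fill else pickup
      prescriber <- if (stats::runif(1) < config$alt_provider_prob) {
        sample(providers$provider_id, 1L, prob = providers$weight)
      } else clients$primary_provider[i]
      if (stats::runif(1) < config$usage_switch_prob) {
        # re-prescription draws afresh from the usage mix, so the cohort
        # share stays at nondaily_prob instead of drifting toward parity
        usage_nondaily <- stats::runif(1) < config$nondaily_prob
      }
      k <- length(f_fill) + 1L
      f_fill[k] <- fill; f_pickup[k] <- pickup; f_eff[k] <- eff
      f_tab[k] <- tablets
      f_usage[k] <- if (usage_nondaily) "non_daily" else "daily"
      f_presc[k] <- prescriber
      if (!is.na(pending_lapse)) {
        # previous supply period carried a lapse candidate; it became a real
        # lapse only if this fill's effective date falls strictly after it
        if (eff > pending_lapse) {
          inact <- c(inact, pending_lapse); ret <- c(ret, eff)
        }
        pending_lapse <- NA_real_
      }
      sdays <- round(tablets * (if (usage_nondaily) 2 else 1))
      lapse_n <- function() {
        as.numeric(sim_lapse_date(as.Date(eff, origin = "1970-01-01"), sdays))
      }
      u <- stats::runif(1)
      if (u < p1) {
        nd <- eff + sample(10:120, 1L)
        if (nd <= data_end_n) {
          notif_date[i] <- as.Date(nd, origin = "1970-01-01")
          inact <- c(inact, nd)
        } else {
          inact <- c(inact, lapse_n())
        }
        break
      } else if (u < p2) {
        inact <- c(inact, lapse_n())
        break
      } else if (u < p3) {
        lap <- lapse_n()
        nxt <- lap + sample(10:60, 1L)
        if (nxt + 30 > data_end_n) {
          inact <- c(inact, lap)
          break
        }
        pending_lapse <- lap
        fill <- nxt
      } else {
        nxt <- eff + sdays + sample(jit[1]:jit[2], 1L)
        if (nxt > data_end_n) {
          inact <- c(inact, lapse_n())
          break
        }
        # long stretched supplies (non-daily) can overrun the gap-rule
        # candidate even on schedule; carry the candidate forward
        if (sdays + max(jit) + config$pickup_delay_max >= 170) {
          pending_lapse <- lapse_n()
        }
        fill <- nxt
      }
    }
    if (length(f_fill)) {
      acc$client <- c(acc$client, rep(clients$client_id[i], length(f_fill)))
      acc$fill <- c(acc$fill, f_fill)
      acc$pickup <- c(acc$pickup, f_pickup)
      acc$eff <- c(acc$eff, f_eff)
      acc$tablets <- c(acc$tablets, f_tab)
      acc$usage <- c(acc$usage, f_usage)
      acc$prescriber <- c(acc$prescriber, f_presc)
      episodes[[i]] <- list(inact = as.Date(inact, origin = "1970-01-01"),
                            ret = as.Date(ret, origin = "1970-01-01"))
    }
  }
  disp <- tibble(
    client_id = acc$client,
    fill_date = as.Date(acc$fill, origin = "1970-01-01"),
    pickup_date = as.Date(acc$pickup, origin = "1970-01-01"),
    eff = as.Date(acc$eff, origin = "1970-01-01"),
    tablets = acc$tablets,
    usage_type = acc$usage,
    prescriber_id = acc$prescriber)
  disp$prescriber_ha_of_practice <- unname(prov_ha[disp$prescriber_id])
  disp$q <- sim_quarter_of(disp$eff)

  dispensed <- !vapply(episodes, is.null, logical(1))
  first_eff <- rep(as.Date(NA), n_clients)
  if (nrow(disp)) {
    fe <- disp %>% group_by(.data$client_id) %>%
      summarise(first_eff = min(.data$eff), .groups = "drop")
    first_eff[match(fe$client_id, clients$client_id)] <- fe$first_eff
  }
  clients$first_eff <- first_eff

  # ---- stream 3: laboratory tests ---------------------------------------
  set.seed(stream_seeds[3])
  nd <- nrow(disp)
  mk_tests <- function(p, assay) {
    take <- stats::runif(nd) < p
    # in-window offset, clamped so the test never falls past the data end
    hi <- pmin(15, as.numeric(data_end - disp$eff[take]))
    off <- -30 + floor(stats::runif(sum(take)) * (hi + 31))
    tibble(client_id = disp$client_id[take],
           test_date = disp$eff[take] + off,
           assay = assay, result = "negative")
  }
  tests <- bind_rows(
    mk_tests(config$hiv_test_prob, "hiv"),
    mk_tests(config$syphilis_test_prob, "syphilis"),
    {
      take <- stats::runif(nd) < config$out_of_window_test_prob
      off <- sample(c(-45:-31, 16:40), sum(take), replace = TRUE)
      tibble(client_id = disp$client_id[take],
             test_date = disp$eff[take] + off,
             assay = sample(ASSAYS, sum(take), replace = TRUE),
             result = "negative")
    },
    {
      idx <- which(dispensed & stats::runif(n_clients) < config$baseline_hiv_test_prob)
      tibble(client_id = clients$client_id[idx],
             test_date = clients$first_eff[idx] -
               sample(0:config$baseline_test_max_days, length(idx), replace = TRUE),
             assay = "hiv", result = "negative")
    })
  tests <- tests %>% filter(.data$test_date <= data_end,
                            .data$test_date > clients$date_of_birth[
                              match(.data$client_id, clients$client_id)])

  # ---- stream 4: incident cases -----------------------------------------
  set.seed(stream_seeds[4])
  active_on <- function(idx, d) {
    # scripted status: active iff as many returns as inactivations by d
    ep <- episodes[[idx]]
    !is.null(ep) && !is.na(clients$first_eff[idx]) && clients$first_eff[idx] <= d &&
      sum(ep$inact <= d) == sum(ep$ret <= d)
  }
  inc_client <- character(); inc_date <- numeric(); inc_assay <- character()
  q_starts <- quarter_start(qs); q_ends <- quarter_end(qs)
  for (i in which(dispensed)) {
    for (iq in seq_along(qs)) {
      if (clients$first_eff[i] > q_ends[iq]) next
      for (assay in c("syphilis", "hiv")) {
        rate <- if (assay == "syphilis") config$syphilis_incidence_qtr else config$hiv_incidence_qtr
        if (stats::runif(1) >= rate) next
        d <- q_starts[iq] + sample.int(as.integer(q_ends[iq] - q_starts[iq]) + 1L, 1L) - 1L
        if (d > data_end || !active_on(i, d)) next
        inc_client <- c(inc_client, clients$client_id[i])
        inc_date <- c(inc_date, as.numeric(d))
        inc_assay <- c(inc_assay, assay)
      }
    }
  }
  incidents <- tibble(client_id = inc_client,
                      test_date = as.Date(inc_date, origin = "1970-01-01"),
                      assay = inc_assay, result = "positive_incident")
  tests <- bind_rows(tests, incidents)

  # ---- stream 5: adverse drug reaction reports --------------------------
  set.seed(stream_seeds[5])
  adr_labels <- c("nausea", "headache", "renal function decline", "rash",
                  "fatigue", "dizziness")
  eff_by_client <- split(disp$eff, disp$client_id)
  a_client <- character(); a_date <- numeric(); a_label <- character()
  a_caus <- character(); a_disc <- logical(); a_nrep <- integer()
  for (i in which(dispensed)) {
    if (stats::runif(1) >= config$adr_prob) next
    effs <- eff_by_client[[clients$client_id[i]]]
    k <- sample.int(length(effs), 1L)
    d <- effs[k] + sample(0:20, 1L)
    if (d > data_end) d <- effs[k]
    a_client <- c(a_client, clients$client_id[i])
    a_date <- c(a_date, as.numeric(d))
    a_label <- c(a_label, sample(adr_labels, 1L))
    a_caus <- c(a_caus, if (stats::runif(1) < config$adr_unlikely_prob) "unlikely" else "possible_or_higher")
    a_disc <- c(a_disc, stats::runif(1) < config$adr_discont_prob)
    a_nrep <- c(a_nrep, 1L + (stats::runif(1) < config$adr_duplicate_prob))
  }
  adr_events <- tibble(client_id = a_client,
                       event_date = as.Date(a_date, origin = "1970-01-01"),
                       event_label = a_label, causality = a_caus,
                       resulted_in_discontinuation = a_disc, n_reports = a_nrep)
  adr_reports <- if (nrow(adr_events)) {
    rep_idx <- rep(seq_len(nrow(adr_events)), adr_events$n_reports)
    out <- adr_events[rep_idx, c("client_id", "event_date", "event_label",
                                 "causality", "resulted_in_discontinuation")]
    out$report_id <- sprintf("ADR%04d", seq_len(nrow(out)))
    out[, c("report_id", "client_id", "event_date", "event_label", "causality",
            "resulted_in_discontinuation")]
  } else empty_table("adr_reports")

  # ---- assemble the event store -----------------------------------------
  gender_history <- bind_rows(
    tibble(client_id = clients$client_id,
           effective_date = clients$authorization_date,
           gender_identity = clients$gender0),
    clients %>% filter(!is.na(.data$gender_change_date)) %>%
      transmute(client_id = .data$client_id,
                effective_date = .data$gender_change_date,
                gender_identity = .data$gender_change_to)
  ) %>% arrange(match(.data$client_id, clients$client_id), .data$effective_date) %>%
    group_by(.data$client_id) %>% mutate(seq = row_number()) %>% ungroup()

  store <- event_store(
    clients = clients %>% select("client_id", "date_of_birth", "ha_of_residence"),
    gender_history = gender_history,
    enrolments = clients %>% transmute(
      client_id = .data$client_id,
      authorization_date = .data$authorization_date,
      enrolling_provider_id = .data$primary_provider,
      risk_factors = .data$risk,
      risk_factors_unknown = .data$risk == ""),
    dispensations = disp %>% select("client_id", "prescriber_id", "fill_date",
                                    "pickup_date", "tablets", "usage_type",
                                    "prescriber_ha_of_practice"),
    lab_tests = tests %>% select("client_id", "test_date", "assay", "result"),
    adr_reports = adr_reports,
    providers = providers %>% select("provider_id", "provider_type", "ha_of_practice"),
    notifications = tibble(
      client_id = clients$client_id[!is.na(notif_date)],
      notification_date = notif_date[!is.na(notif_date)],
      kind = "formal_discontinuation")
  )

  truth <- sim_ground_truth(clients, disp, tests, adr_events, episodes,
                            providers, qs)
  list(store = store, truth = truth, quarters = qs)
}

# ---- ground-truth builder (independent bookkeeping) ----------------------
sim_ground_truth <- function(clients, disp, tests, adr_events, episodes,
                             providers, qs) {
  cells <- list()
  denoms <- list()
  add_cells <- function(q, ind, part, dimn, strata, nums) {
    if (!length(strata)) return()
    cells[[length(cells) + 1L]] <<- list(
      quarter = q, indicator = ind, part = part, dimension = dimn,
      stratum = as.character(strata), numerator = as.numeric(nums))
  }
  add_denom <- function(q, ind, part, dimn, den) {
    denoms[[length(denoms) + 1L]] <<- list(
      quarter = q, indicator = ind, part = part, dimension = dimn,
      denominator = as.numeric(den))
  }
  count_of <- function(x) {
    t <- table(x)
    list(strata = names(t), nums = as.numeric(t))
  }

  prov_type <- stats::setNames(providers$provider_type, providers$provider_id)
  prov_ha <- stats::setNames(providers$ha_of_practice, providers$provider_id)
  # per-client numeric test-date lists for brute-force window checks
  split_tests <- function(a) {
    tt <- tests[tests$assay == a, ]
    split(as.numeric(tt$test_date), tt$client_id)
  }
  hiv_dates <- split_tests("hiv")
  syph_dates <- split_tests("syphilis")
  neg_hiv <- tests[tests$assay == "hiv" & tests$result == "negative", ]
  neg_hiv_dates <- split(as.numeric(neg_hiv$test_date), neg_hiv$client_id)

  covered_by <- function(cid, eff, dates_by_client) {
    eff <- as.numeric(eff)
    vapply(seq_along(cid), function(j) {
      dd <- dates_by_client[[cid[j]]]
      !is.null(dd) && any(dd >= eff[j] - 30 & dd <= eff[j] + 15)
    }, logical(1))
  }

  ep_idx <- stats::setNames(seq_len(nrow(clients)), clients$client_id)
  active_at_truth <- function(cid, d) {
    vapply(seq_along(cid), function(j) {
      i <- ep_idx[[cid[j]]]
      ep <- episodes[[i]]
      if (is.null(ep) || is.na(clients$first_eff[i]) || clients$first_eff[i] > d[j]) {
        return(NA)
      }
      sum(ep$inact <= d[j]) == sum(ep$ret <= d[j])
    }, logical(1))
  }

  gender_at <- function(sub, qe) {
    ifelse(!is.na(sub$gender_change_date) & sub$gender_change_date <= qe,
           sub$gender_change_to, sub$gender0)
  }

  for (q in qs) {
    qe <- quarter_end(q)
    dq <- disp[disp$q == q, ]
    dq_first <- dq[order(dq$client_id, dq$eff), ]
    dq_first <- dq_first[!duplicated(dq_first$client_id), ]
    den1 <- nrow(dq_first)
    ci <- match(dq_first$client_id, clients$client_id)

    # 1 gender, 2 age, 3 HA (residence / practice)
    cc <- count_of(gender_at(clients[ci, ], qe))
    add_cells(q, "1", "", "", cc$strata, cc$nums); add_denom(q, "1", "", "", den1)
    cc <- count_of(sim_age_bin(sim_age(clients$date_of_birth[ci], dq_first$eff)))
    add_cells(q, "2", "", "", cc$strata, cc$nums); add_denom(q, "2", "", "", den1)
    cc <- count_of(clients$ha_of_residence[ci])
    add_cells(q, "3", "", "residence", cc$strata, cc$nums)
    add_denom(q, "3", "", "residence", den1)
    cc <- count_of(dq_first$prescriber_ha_of_practice)
    add_cells(q, "3", "", "practice", cc$strata, cc$nums)
    add_denom(q, "3", "", "practice", den1)

    # 4 & 5: new enrolments
    enr <- clients[clients$arrival_q == q, ]
    cc <- count_of(unname(prov_type[enr$primary_provider]))
    add_cells(q, "4", "", "", cc$strata, cc$nums); add_denom(q, "4", "", "", nrow(enr))
    cc <- count_of(enr$ha_of_residence)
    add_cells(q, "5", "", "residence", cc$strata, cc$nums)
    add_denom(q, "5", "", "residence", nrow(enr))
    cc <- count_of(unname(prov_ha[enr$primary_provider]))
    add_cells(q, "5", "", "practice", cc$strata, cc$nums)
    add_denom(q, "5", "", "practice", nrow(enr))

    # 6: first dispensations
    new_ids <- clients$client_id[!is.na(clients$first_eff) &
                                   sim_quarter_of(clients$first_eff) == q]
    nd_first <- dq_first[dq_first$client_id %in% new_ids, ]
    cc <- count_of(clients$ha_of_residence[match(nd_first$client_id, clients$client_id)])
    add_cells(q, "6", "", "residence", cc$strata, cc$nums)
    add_denom(q, "6", "", "residence", nrow(nd_first))
    cc <- count_of(nd_first$prescriber_ha_of_practice)
    add_cells(q, "6", "", "practice", cc$strata, cc$nums)
    add_denom(q, "6", "", "practice", nrow(nd_first))

    # 7: provider volume
    pairs <- unique(dq[, c("prescriber_id", "client_id")])
    vol <- table(pairs$prescriber_id)
    bins <- sim_vol_bin(as.numeric(vol))
    cc <- count_of(bins)
    add_cells(q, "7", "a", "", cc$strata, cc$nums)
    add_denom(q, "7", "a", "", length(vol))
    bin_of_prov <- stats::setNames(bins, names(vol))
    cover <- unique(data.frame(client = pairs$client_id,
                               bin = unname(bin_of_prov[pairs$prescriber_id])))
    cc <- count_of(cover$bin)
    add_cells(q, "7", "b", "", cc$strata, cc$nums)
    add_denom(q, "7", "b", "", length(unique(pairs$client_id)))

    # 8: risk factors
    f_in_q <- clients[clients$client_id %in% new_ids, ]
    sets <- strsplit(f_in_q$risk, ";", fixed = TRUE)
    nums <- vapply(RISK_FACTORS, function(f) {
      sum(vapply(sets, function(s) f %in% s, logical(1)))
    }, numeric(1))
    add_cells(q, "8", "a", "", RISK_FACTORS, unname(nums))
    add_denom(q, "8", "a", "", nrow(f_in_q))
    cum_cl <- clients[!is.na(clients$first_eff) & clients$first_eff <= qe, ]
    cc <- count_of(sim_risk_label(cum_cl$risk))
    add_cells(q, "8", "b", "", cc$strata, cc$nums)
    add_denom(q, "8", "b", "", nrow(cum_cl))

    # 9: status
    eligible <- clients[!is.na(clients$first_eff) & clients$first_eff <= qe, ]
    act <- active_at_truth(eligible$client_id, rep(qe, nrow(eligible)))
    add_cells(q, "9", "", "", c("active", "inactive"),
              c(sum(act, na.rm = TRUE), sum(!act, na.rm = TRUE)))
    add_denom(q, "9", "", "", nrow(eligible))

    # 10: usage type among active clients
    act_ids <- eligible$client_id[act %in% TRUE]
    latest <- disp[disp$client_id %in% act_ids & disp$eff <= qe, ]
    latest <- latest[order(latest$client_id, latest$eff), ]
    latest <- latest[!duplicated(latest$client_id, fromLast = TRUE), ]
    cc <- count_of(latest$usage_type)
    add_cells(q, "10", "", "", cc$strata, cc$nums)
    add_denom(q, "10", "", "", length(act_ids))

    # 11: tablet units
    ha_res_of <- clients$ha_of_residence[match(dq$client_id, clients$client_id)]
    units_res <- tapply(dq$tablets, ha_res_of, sum) / 30
    add_cells(q, "11", "", "residence", names(units_res), as.numeric(units_res))
    add_denom(q, "11", "", "residence", sum(dq$tablets) / 30)
    units_pr <- tapply(dq$tablets, dq$prescriber_ha_of_practice, sum) / 30
    add_cells(q, "11", "", "practice", names(units_pr), as.numeric(units_pr))
    add_denom(q, "11", "", "practice", sum(dq$tablets) / 30)

    # 12a / 13b: testing coverage (brute-force all-pairs window check)
    add_cells(q, "12", "a", "", "covered",
              sum(covered_by(dq$client_id, dq$eff, syph_dates)))
    add_denom(q, "12", "a", "", nrow(dq))
    add_cells(q, "13", "b", "", "covered",
              sum(covered_by(dq$client_id, dq$eff, hiv_dates)))
    add_denom(q, "13", "b", "", nrow(dq))

    # 12b: incident syphilis among active clients
    inc <- tests[tests$assay == "syphilis" & tests$result == "positive_incident" &
                   tests$test_date >= quarter_start(q) & tests$test_date <= qe, ]
    add_cells(q, "12", "b", "", "incident_clients", length(unique(inc$client_id)))

    # 13a: days from most recent negative HIV test to first dispensation
    fe <- as.numeric(cum_cl$first_eff)
    gaps <- vapply(seq_len(nrow(cum_cl)), function(j) {
      dd <- neg_hiv_dates[[cum_cl$client_id[j]]]
      dd <- dd[dd <= fe[j]]
      if (!length(dd)) NA_real_ else fe[j] - max(dd)
    }, numeric(1))
    qq <- sim_quartiles(gaps[!is.na(gaps)])
    add_cells(q, "13", "a", "",
              c("n", "median", "p25", "p75", "n_no_prior_test"),
              c(sum(!is.na(gaps)), qq[2], qq[1], qq[3], sum(is.na(gaps))))

    # 14: ADR events
    ae <- adr_events[adr_events$event_date >= quarter_start(q) &
                       adr_events$event_date <= qe, , drop = FALSE]
    kept <- ae[ae$causality != "unlikely", , drop = FALSE]
    add_cells(q, "14", "", "",
              c("events", "distinct_clients", "discontinuation_linked"),
              c(nrow(kept), length(unique(kept$client_id)),
                sum(kept$resulted_in_discontinuation)))
  }

  ns <- vapply(cells, function(x) length(x$stratum), integer(1))
  pull_chr <- function(lst, f) vapply(lst, `[[`, character(1), f)
  cells_tb <- tibble(
    quarter = rep(pull_chr(cells, "quarter"), ns),
    indicator = rep(pull_chr(cells, "indicator"), ns),
    part = rep(pull_chr(cells, "part"), ns),
    dimension = rep(pull_chr(cells, "dimension"), ns),
    stratum = unlist(lapply(cells, `[[`, "stratum"), use.names = FALSE),
    numerator = unlist(lapply(cells, `[[`, "numerator"), use.names = FALSE))
  denoms_tb <- tibble(
    quarter = pull_chr(denoms, "quarter"),
    indicator = pull_chr(denoms, "indicator"),
    part = pull_chr(denoms, "part"),
    dimension = pull_chr(denoms, "dimension"),
    denominator = vapply(denoms, `[[`, numeric(1), "denominator"))
  list(cells = cells_tb, denoms = denoms_tb)
}

#' Compare an engine-built report against simulator ground truth
#'
#' Joins the tidy report cells against the ground-truth cells and denominators
#' for the report's quarter and returns the mismatching cells (empty tibble =
#' exact agreement). Cells absent on one side are compared against zero;
#' `NA` matches `NA` (e.g. an undefined median).
#'
#' @param report a [build_quarterly_report()] result.
#' @param truth the `truth` element of [simulate_cohort()].
#' @return tibble of mismatches with engine and truth values.
#' @export
compare_report_truth <- function(report, truth) {
  tidy <- report_to_tidy(report)
  tcells <- truth$cells %>% filter(.data$quarter == report$quarter)
  tden <- truth$denoms %>% filter(.data$quarter == report$quarter)

  num_cmp <- tidy %>%
    select("indicator", "part", "dimension", "stratum", engine = "numerator") %>%
    full_join(tcells %>% select("indicator", "part", "dimension", "stratum",
                                truth = "numerator"),
              by = c("indicator", "part", "dimension", "stratum")) %>%
    mutate(engine = ifelse(is.na(.data$engine) & !is.na(.data$truth) &
                             !.data$stratum %in% c("median", "p25", "p75"),
                           0, .data$engine),
           truth = ifelse(is.na(.data$truth) & !is.na(.data$engine) &
                            !.data$stratum %in% c("median", "p25", "p75"),
                          0, .data$truth)) %>%
    filter(!(is.na(.data$engine) & is.na(.data$truth))) %>%
    filter(is.na(.data$engine) != is.na(.data$truth) |
             abs(.data$engine - .data$truth) > 1e-9) %>%
    mutate(what = "numerator")

  den_cmp <- tidy %>%
    filter(!is.na(.data$denominator)) %>%
    distinct(.data$indicator, .data$part, .data$dimension, engine = .data$denominator) %>%
    full_join(tden %>% select("indicator", "part", "dimension", truth = "denominator"),
              by = c("indicator", "part", "dimension")) %>%
    filter(is.na(.data$engine) | is.na(.data$truth) |
             abs(.data$engine - .data$truth) > 1e-9) %>%
    mutate(stratum = "(denominator)", what = "denominator")

  bind_rows(num_cmp, den_cmp)
}
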