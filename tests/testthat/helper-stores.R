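# Small construction helpers for hand-built stores, plus a cached demo
# cohort shared across test files.

mk_clients <- function(ids, dob = "1985-06-15", ha = "Vancouver Coastal",
                       gender = "cis_male", gdate = "2018-01-02") {
  n <- length(ids)
  list(
    clients = tibble::tibble(client_id = ids,
                             date_of_birth = rep(as.Date(dob), length.out = n),
                             ha_of_residence = rep(ha, length.out = n)),
    gender_history = tibble::tibble(client_id = ids,
                                    effective_date = rep(as.Date(gdate), length.out = n),
                                    gender_identity = rep(gender, length.out = n),
                                    seq = 1L))
}

mk_disp <- function(id, fill, tablets = 30L, pickup = NA, usage = "daily",
                    prescriber = "P1", ha = "Vancouver Coastal") {
  tibble::tibble(client_id = id, prescriber_id = prescriber,
                 fill_date = as.Date(fill), pickup_date = as.Date(pickup),
                 tablets = as.integer(tablets), usage_type = usage,
                 prescriber_ha_of_practice = ha)
}

mk_enrol <- function(id, auth = "2018-01-02", provider = "P1", risk = "d") {
  tibble::tibble(client_id = id, authorization_date = as.Date(auth),
                 enrolling_provider_id = provider, risk_factors = risk,
                 risk_factors_unknown = risk == "")
}

mk_providers <- function(ids = "P1", type = "family_physician",
                         ha = "Vancouver Coastal") {
  tibble::tibble(provider_id = ids,
                 provider_type = rep(type, length.out = length(ids)),
                 ha_of_practice = rep(ha, length.out = length(ids)))
}

small_sim_config <- function(...) {
  sim_config(base_arrivals = 15, n_quarters = 6, ...)
}

# cached small simulated cohort (seed fixed) reused across test files
get_demo_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(small_sim_config(), seed = 99)
    cache
  }
})

# independent day-enumeration window oracle
oracle_in_window <- function(dispense, test, lookback = 30, grace = 15) {
  vapply(seq_along(dispense), function(i) {
    days <- seq(dispense[i] - lookback, dispense[i] + grace, by = "day")
    test[i] %in% days
  }, logical(1))
}

# independent all-pairs testing-coverage count: nested loops over in-quarter
# dispensations and every test of the same client and assay
oracle_coverage_count <- function(store, quarter, assay) {
  qs <- quarter_start(quarter); qe <- quarter_end(quarter)
  dp <- store$dispensations
  eff <- ifelse(is.na(dp$pickup_date), dp$fill_date, dp$pickup_date)
  eff <- as.Date(eff, origin = "1970-01-01")
  in_q <- which(eff >= qs & eff <= qe)
  tt <- store$lab_tests[store$lab_tests$assay == assay, ]
  n_cov <- 0L
  for (i in in_q) {
    cid <- dp$client_id[i]
    tdates <- tt$test_date[tt$client_id == cid]
    hit <- FALSE
    for (td in tdates) {
      if (td >= eff[i] - 30 && td <= eff[i] + 15) { hit <- TRUE; break }
    }
    n_cov <- n_cov + hit
  }
  n_cov
}

# sort-and-index quantile oracle (linear interpolation between order stats)
oracle_quartiles <- function(x) {
  x <- sort(x); n <- length(x)
  vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }, numeric(1))
}
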