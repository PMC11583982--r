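# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

base_theta <- function(mu_m = 22, sigma_m = 4, phi1 = 0.3, phi2 = 0.15,
                       delta = 10) {
  param_vector(mu_m, sigma_m, phi1, phi2, delta)
}

# Build a cohort_histories object by hand (bypasses the simulator) so the
# summary operations can be checked against hand-computed values.
manual_cohort <- function(marriage_months, birth_month_list,
                          gestation = 9L, age_grid = 15:49) {
  structure(list(
    marriage_age = marriage_months,
    conception_ages = lapply(birth_month_list, function(b) as.integer(b) - gestation),
    birth_ages = lapply(birth_month_list, as.integer),
    frailty = rep(1, length(marriage_months)),
    theta = NULL,
    config = sim_config(n_women = length(marriage_months),
                        age_grid = age_grid, gestation = gestation)
  ), class = "cohort_histories")
}

# Build maternity_records directly from plain vectors/lists.
manual_records <- function(marriage_months, births_list,
                           cohort = rep(NA_real_, length(marriage_months)),
                           wife_death = rep(NA_real_, length(marriage_months)),
                           spouse_death = rep(NA_real_, length(marriage_months)),
                           observed_to = rep(600, length(marriage_months))) {
  n <- length(marriage_months)
  rec <- data.frame(woman_id = sprintf("w%03d", seq_len(n)),
                    cohort = cohort,
                    marriage_age_months = marriage_months,
                    wife_death_age_months = wife_death,
                    spouse_death_wife_age_months = spouse_death,
                    observed_to_age_months = observed_to,
                    stringsAsFactors = FALSE)
  rec$births <- lapply(births_list, as.numeric)
  class(rec) <- c("maternity_records", "data.frame")
  attr(rec, "errors") <- data.frame(row = integer(0), woman_id = character(0),
                                    message = character(0))
  rec
}

# Independent state-machine replay of one cohort: walks every month of every
# woman's window, maintaining the susceptibility state from the recorded
# conceptions, and fails if any recorded conception happens while married
# women are pregnant/amenorrheic, before marriage, or outside the window.
# Written as a literal month loop on purpose: it shares no code with the
# simulator's jump-ahead implementation.
replay_violations <- function(coh) {
  delta_ceil <- as.integer(ceiling(coh$theta$delta))
  gest <- coh$config$gestation
  bad <- character(0)
  for (w in seq_along(coh$marriage_age)) {
    conc <- coh$conception_ages[[w]]
    marr <- coh$marriage_age[w]
    blocked_until <- -1L # last non-susceptible month
    k <- 1L
    for (m in 0:599) {
      is_conception <- k <= length(conc) && conc[k] == m
      if (is_conception) {
        if (m <= marr) bad <- c(bad, sprintf("w%d: conception at/before marriage", w))
        if (m <= blocked_until) bad <- c(bad, sprintf("w%d: conception while non-susceptible", w))
        if (m < 120 || m >= 600) bad <- c(bad, sprintf("w%d: conception outside window", w))
        blocked_until <- m + gest + delta_ceil
        k <- k + 1L
      }
    }
    if (k <= length(conc)) bad <- c(bad, sprintf("w%d: conception beyond month 599", w))
    b <- coh$birth_ages[[w]]
    if (length(b) != length(conc) || any(b != conc + gest)) {
      bad <- c(bad, sprintf("w%d: birth not gestation months after conception", w))
    }
    if (any(b >= 600)) bad <- c(bad, sprintf("w%d: birth recorded outside window", w))
  }
  bad
}

# 1-nearest-neighbour "regressor" with the same interface as the internal
# random forest: oob prediction = y of the nearest *other* row, prediction at
# a new point = y of its nearest row. An independent oracle for the
# regression-adjustment arithmetic.
one_nn_regressor <- function(X, y, xnew) {
  d2 <- function(a, b) sum((a - b)^2)
  n <- nrow(X)
  oob <- vapply(seq_len(n), function(i) {
    d <- vapply(seq_len(n), function(j) if (j == i) Inf else d2(X[i, ], X[j, ]),
                numeric(1))
    y[which.min(d)]
  }, numeric(1))
  pred <- apply(xnew, 1, function(s) {
    y[which.min(vapply(seq_len(n), function(j) d2(s, X[j, ]), numeric(1)))]
  })
  list(oob = oob, pred = pred)
}

# Tiny deterministic observed schedule generated from known parameters.
synthetic_obs <- function(theta = base_theta(), n_women = 2000, seed = 99,
                          age_grid = 15:49) {
  natfert:::simulate_asfr(theta, sim_config(n_women, seed = seed,
                                            age_grid = age_grid))
}
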