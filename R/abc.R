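#' Uniform prior box for the five model parameters
#'
#' Defaults follow the literature-based ranges used for natural-fertility
#' populations: mean age at marriage 19--27 years, its SD 2--7 years,
#' post-partum amenorrhea 6--18 months. The fecundability coefficients are
#' sampled uniformly on a rectangle and truncated to the pairs whose implied
#' peak fecundability lies in `peak_range` (default 0.12--0.35), so the
#' stated peak range holds exactly.
#'
#' @param mu_m,sigma_m,delta Length-2 numeric `c(lower, upper)` bounds.
#' @param phi_rect Length-2 bounds of the pre-truncation rectangle for both
#'   `phi1` and `phi2`.
#' @param peak_range Admissible range for peak fecundability.
#' @return An object of class `prior_box`.
#' @export
prior_box <- function(mu_m = c(19, 27), sigma_m = c(2, 7), delta = c(6, 18),
                      phi_rect = c(0, 0.8), peak_range = c(0.12, 0.35)) {
  box <- list(mu_m = mu_m, sigma_m = sigma_m, delta = delta,
              phi_rect = phi_rect, peak_range = peak_range)
  for (nm in names(box)) {
    b <- box[[nm]]
    stopifnot(is.numeric(b), length(b) == 2L, b[1] <= b[2])
  }
  if (mu_m[1] >= mu_m[2] || sigma_m[1] >= sigma_m[2] || delta[1] > delta[2]) {
    # equal bounds allowed only for delta-like degenerate testing via phi_rect
  }
  structure(box, class = "prior_box")
}

# Bounds used for clipping RF-adjusted draws, per parameter column.
box_bounds <- function(box) {
  list(mu_m = box$mu_m, sigma_m = box$sigma_m,
       phi1 = box$phi_rect, phi2 = box$phi_rect, delta = box$delta)
}

#' Draw parameter vectors from the prior
#'
#' Independent uniforms per coordinate; `(phi1, phi2)` pairs are rejection
#' sampled from the rectangle until the implied peak fecundability falls in
#' the box's `peak_range`. Uses R's global RNG stream.
#'
#' @param box A [prior_box()].
#' @param n Number of draws.
#' @return A data.frame with columns `mu_m`, `sigma_m`, `phi1`, `phi2`,
#'   `delta`, one row per draw.
#' @export
sample_prior <- function(box, n) {
  stopifnot(inherits(box, "prior_box"), n >= 0)
  if (n == 0) {
    return(data.frame(mu_m = numeric(0), sigma_m = numeric(0),
                      phi1 = numeric(0), phi2 = numeric(0),
                      delta = numeric(0)))
  }
  runif2 <- function(b, k) stats::runif(k, b[1], b[2])
  phi1 <- numeric(n)
  phi2 <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    p1 <- runif2(box$phi_rect, length(need))
    p2 <- runif2(box$phi_rect, length(need))
    pk <- pair_peak(p1, p2)
    ok <- pk >= box$peak_range[1] & pk <= box$peak_range[2]
    phi1[need[ok]] <- p1[ok]
    phi2[need[ok]] <- p2[ok]
    need <- need[!ok]
  }
  data.frame(mu_m = runif2(box$mu_m, n), sigma_m = runif2(box$sigma_m, n),
             phi1 = phi1, phi2 = phi2, delta = runif2(box$delta, n))
}

# Vectorized peak fecundability for coefficient pairs (0 when both zero).
pair_peak <- function(phi1, phi2) {
  mapply(function(p1, p2) {
    if (p1 == 0 && p2 == 0) return(0)
    pk <- peak_fecundability(structure(list(phi1 = p1, phi2 = p2),
                                       class = "fecundability_curve"))
    pk$peak
  }, phi1, phi2)
}

#' Euclidean distance between two ASFR schedules
#'
#' Plain (unweighted) Euclidean distance between the rate vectors; the two
#' schedules must share the same age grid.
#'
#' @param sim,obs [asfr_schedule()] objects on identical age grids.
#' @return The non-negative distance.
#' @export
euclidean_distance <- function(sim, obs) {
  stopifnot(inherits(sim, "asfr_schedule"), inherits(obs, "asfr_schedule"))
  if (!identical(sim$age, obs$age)) {
    stop("age grids of the two schedules differ")
  }
  sqrt(sum((sim$rate - obs$rate)^2))
}

# Small deterministic seed derivation; keeps derived seeds in [1, 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629 * 48271 +
                as.double(i) * 1299721) %% 2147483629) + 1L
}

#' Build an ABC reference table
#'
#' Draws `n` parameter vectors from the prior, simulates a cohort for each
#' (on the observed schedule's age grid) and records the simulated ASFR
#' vector and its Euclidean distance to the observed one. Rows are seeded
#' independently from the root seed, so results do not depend on execution
#' order (embarrassingly parallel contract).
#'
#' @param obs Observed [asfr_schedule()], or `NULL` to build a table without
#'   distances (used by cross-validation, where each row in turn plays the
#'   observed role).
#' @param box A [prior_box()].
#' @param n Number of prior draws (table rows).
#' @param config A [sim_config()]; its `seed` is the root seed of the table.
#' @param progress_every Emit a message every this many rows (0 = silent).
#' @return An object of class `reference_table`: `params` (data.frame),
#'   `summaries` (n x ages matrix), `distances`, `ages`, `box`, `config`.
#' @export
build_reference_table <- function(obs, box, n, config, progress_every = 0) {
  stopifnot(inherits(box, "prior_box"), inherits(config, "sim_config"))
  if (!is.null(obs)) {
    stopifnot(inherits(obs, "asfr_schedule"))
    config$age_grid <- obs$age
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, 0L))
  params <- sample_prior(box, n)
  summaries <- matrix(NA_real_, nrow = n, ncol = length(config$age_grid))
  colnames(summaries) <- paste0("asfr_", config$age_grid)
  for (i in seq_len(n)) {
    theta <- param_vector(params$mu_m[i], params$sigma_m[i], params$phi1[i],
                          params$phi2[i], params$delta[i])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    summaries[i, ] <- simulate_asfr(theta, cfg)$rate
    if (progress_every > 0 && i %% progress_every == 0) {
      message("reference table: ", i, "/", n, " rows")
    }
  }
  distances <- if (is.null(obs)) rep(NA_real_, n)
               else sqrt(colSums((t(summaries) - obs$rate)^2))
  structure(list(params = params, summaries = summaries,
                 distances = distances, ages = config$age_grid,
                 box = box, config = config),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x$params), "rows,",
      length(x$ages), "summary ages, n_women =", x$config$n_women, "\n")
  invisible(x)
}

# Indices of the k = ceiling(frac * n) rows smallest in (distance, index)
# lexicographic order; ties at the cutoff resolved by earliest row index.
accept_indices <- function(distances, accept_fraction) {
  n <- length(distances)
  if (n == 0) stop("empty table")
  stopifnot(accept_fraction > 0, accept_fraction <= 1)
  k <- min(n, max(1L, as.integer(ceiling(accept_fraction * n))))
  sort(order(distances, seq_len(n))[seq_len(k)])
}

#' ABC rejection step
#'
#' Keeps the fraction of reference-table rows whose simulated summaries are
#' closest (Euclidean) to the observed summaries.
#'
#' @param table A [build_reference_table()] result with distances.
#' @param accept_fraction Fraction of rows to keep, in `(0, 1]`.
#' @return An object of class `abc_accepted` with the retained `params`,
#'   `summaries`, `distances` and original row `index`.
#' @export
reject <- function(table, accept_fraction) {
  stopifnot(inherits(table, "reference_table"))
  if (anyNA(table$distances)) {
    stop("reference table has no distances; rebuild with an observed schedule")
  }
  keep <- accept_indices(table$distances, accept_fraction)
  structure(list(params = table$params[keep, , drop = FALSE],
                 summaries = table$summaries[keep, , drop = FALSE],
                 distances = table$distances[keep], index = keep,
                 ages = table$ages, box = table$box),
            class = "abc_accepted")
}

# Resolve the observed summary vector for adjustment.
obs_summary <- function(obs, ages) {
  if (inherits(obs, "asfr_schedule")) {
    if (!identical(obs$age, as.integer(ages))) stop("age grids differ")
    obs$rate
  } else {
    stopifnot(is.numeric(obs), length(obs) == length(ages))
    as.numeric(obs)
  }
}

#' Random-forest regression adjustment of accepted draws
#'
#' For each parameter independently, fits a random-forest regression of the
#' parameter on the simulated ASFR vector over the accepted rows, and shifts
#' each accepted draw by the difference between the forest's prediction at
#' the observed summaries and its out-of-bag prediction at the row's own
#' summaries: `theta_adj = theta - m(s_i) + m(s_obs)`. Adjusted values are
#' clipped to the prior box.
#'
#' @param accepted An `abc_accepted` object from [reject()].
#' @param obs Observed [asfr_schedule()] (or a bare summary vector on the
#'   same grid).
#' @param ntree,mtry,min_node Forest settings; `mtry` defaults to a third of
#'   the summary dimension.
#' @param seed Integer seed for the forest's internal randomness.
#' @param min_accepted Refuse to adjust fewer rows than this (increase the
#'   table size or the acceptance fraction instead).
#' @param regressor Optional override for testing: a
#'   `function(X, y, xnew)` returning `list(oob = , pred = )`. Defaults to
#'   the in-package random forest.
#' @return An object of class `posterior_sample` with `raw` and `adjusted`
#'   parameter data.frames.
#' @export
rf_adjust <- function(accepted, obs, ntree = 500, mtry = NULL, min_node = 5,
                      seed = 1L, min_accepted = 50, regressor = NULL) {
  stopifnot(inherits(accepted, "abc_accepted"))
  n <- nrow(accepted$params)
  if (n < min_accepted) {
    stop("only ", n, " accepted draws (< ", min_accepted,
         "); increase the reference-table size or accept_fraction")
  }
  s_obs <- obs_summary(obs, accepted$ages)
  X <- accepted$summaries
  if (is.null(mtry)) mtry <- max(1L, ncol(X) %/% 3L)
  bounds <- box_bounds(accepted$box)
  adjusted <- accepted$params
  for (j in names(adjusted)) {
    y <- accepted$params[[j]]
    fit <- if (is.null(regressor)) {
      .rf_regress_cpp(X, y, matrix(s_obs, nrow = 1), as.integer(ntree),
                      as.integer(mtry), as.integer(min_node),
                      derive_seed(seed, match(j, names(adjusted))))
    } else {
      regressor(X, y, matrix(s_obs, nrow = 1))
    }
    oob <- ifelse(is.na(fit$oob), mean(y), fit$oob)
    adj <- y - oob + fit$pred[1]
    adjusted[[j]] <- pmin(pmax(adj, bounds[[j]][1]), bounds[[j]][2])
  }
  structure(list(raw = accepted$params, adjusted = adjusted,
                 distances = accepted$distances, index = accepted$index,
                 ages = accepted$ages, box = accepted$box, s_obs = s_obs),
            class = "posterior_sample")
}

#' Posterior summaries
#'
#' @param posterior A `posterior_sample` (uses the adjusted draws) or a
#'   data.frame of draws.
#' @return A data.frame with one row per parameter: `mean`, `median`,
#'   `lower` / `upper` (central 95% empirical credible interval).
#' @export
summarize_posterior <- function(posterior) {
  draws <- if (inherits(posterior, "posterior_sample")) posterior$adjusted
           else as.data.frame(posterior)
  stopifnot(nrow(draws) >= 1)
  out <- do.call(rbind, lapply(names(draws), function(j) {
    x <- draws[[j]]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = j, mean = mean(x), median = q[2],
               lower = q[1], upper = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("ABC posterior sample:", nrow(x$adjusted), "adjusted draws\n")
  print(summarize_posterior(x))
  invisible(x)
}

#' Posterior predictive ASFR envelope
#'
#' Samples parameter vectors with replacement from the adjusted posterior
#' draws, simulates a cohort for each and returns pointwise 2.5/50/97.5
#' percentile curves of the simulated rates.
#'
#' @param posterior A `posterior_sample`.
#' @param config A [sim_config()]; its seed governs both the resampling and
#'   the simulations.
#' @param n_rep Number of predictive replicates.
#' @return A data.frame with columns `age`, `lower`, `median`, `upper`.
#' @export
posterior_predictive <- function(posterior, config, n_rep = 100) {
  stopifnot(inherits(posterior, "posterior_sample"), n_rep >= 1)
  draws <- posterior$adjusted
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, 777L))
  rows <- sample.int(nrow(draws), n_rep, replace = TRUE)
  config$age_grid <- as.integer(posterior$ages)
  rates <- matrix(NA_real_, nrow = n_rep, ncol = length(config$age_grid))
  for (r in seq_len(n_rep)) {
    i <- rows[r]
    theta <- param_vector(draws$mu_m[i], draws$sigma_m[i], draws$phi1[i],
                          draws$phi2[i], draws$delta[i])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L + r)
    rates[r, ] <- simulate_asfr(theta, cfg)$rate
  }
  q <- apply(rates, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  data.frame(age = config$age_grid, lower = q[1, ], median = q[2, ],
             upper = q[3, ])
}

#' Full ABC fit: reference table, rejection, RF adjustment
#'
#' Convenience wrapper running the whole likelihood-free pipeline against an
#' observed ASFR schedule.
#'
#' @param obs Observed [asfr_schedule()].
#' @param box A [prior_box()].
#' @param n Reference-table size.
#' @param config A [sim_config()] (root seed, cohort size, heterogeneity).
#' @param accept_fraction Rejection step fraction (default 0.05).
#' @param ntree,mtry,min_node Forest settings, see [rf_adjust()].
#' @param progress_every See [build_reference_table()].
#' @return A `posterior_sample`.
#' @export
abc_fit <- function(obs, box, n, config, accept_fraction = 0.05,
                    ntree = 500, mtry = NULL, min_node = 5,
                    progress_every = 0) {
  table <- build_reference_table(obs, box, n, config,
                                 progress_every = progress_every)
  accepted <- reject(table, accept_fraction)
  rf_adjust(accepted, obs, ntree = ntree, mtry = mtry, min_node = min_node,
            seed = derive_seed(config$seed, 555L))
}

#' Heterogeneity scenario scan
#'
#' Re-estimates the model under a sequence of assumptions about the variance
#' of the Gamma frailty distribution of fecundability (`sigma2 = 0` is the
#' homogeneous baseline). All scenarios share the same root seed, so prior
#' draws and simulation noise are common across scenarios and the comparison
#' isolates the effect of the frailty assumption. For each scenario the
#' posterior-median fecundability curve is reported together with its peak
#' and the implied variance of couple-level fecundability at the peak,
#' `sigma2 * peak^2`.
#'
#' @param obs Observed [asfr_schedule()].
#' @param sigma2_list Frailty variances to scan, e.g. `c(0, 0.02, 0.04)`.
#' @param box,n,config,accept_fraction,ntree See [abc_fit()].
#' @return A list with `scan` (one data.frame row per scenario: `sigma2`,
#'   posterior medians of `phi1` and `phi2`, `peak_age`, `peak_fecundability`,
#'   `variance_at_peak`) and `posteriors` (the per-scenario
#'   `posterior_sample` objects).
#' @export
estimate_with_heterogeneity <- function(obs, sigma2_list, box, n, config,
                                        accept_fraction = 0.05, ntree = 500) {
  stopifnot(all(sigma2_list >= 0))
  posteriors <- vector("list", length(sigma2_list))
  rows <- vector("list", length(sigma2_list))
  for (k in seq_along(sigma2_list)) {
    s2 <- sigma2_list[k]
    cfg <- config
    cfg$heterogeneity <- if (s2 == 0) NULL else frailty_model(sigma2 = s2)
    post <- abc_fit(obs, box, n, cfg, accept_fraction = accept_fraction,
                    ntree = ntree)
    med <- summarize_posterior(post)
    p1 <- med$median[med$parameter == "phi1"]
    p2 <- med$median[med$parameter == "phi2"]
    pk <- peak_fecundability(fecundability_curve(p1, p2))
    posteriors[[k]] <- post
    rows[[k]] <- data.frame(sigma2 = s2, phi1_median = p1, phi2_median = p2,
                            peak_age = pk$age, peak_fecundability = pk$peak,
                            variance_at_peak = s2 * pk$peak^2)
  }
  list(scan = do.call(rbind, rows), posteriors = posteriors)
}
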