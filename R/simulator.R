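#' Model parameter vector
#'
#' Bundles the five estimands of the natural-fertility model: the mean
#' (`mu_m`, years) and standard deviation (`sigma_m`, years) of the lognormal
#' age-at-marriage distribution, the two fecundability coefficients
#' (`phi1`, `phi2`) and the mean duration of post-partum amenorrhea
#' (`delta`, months).
#'
#' @param mu_m Mean age at marriage in years, in `(10, 50)`.
#' @param sigma_m SD of age at marriage in years, `> 0`.
#' @param phi1,phi2 Fecundability coefficients (see [fecundability_curve()]).
#' @param delta Post-partum amenorrhea duration in months, `>= 0`.
#' @return An object of class `param_vector`.
#' @export
#' @examples
#' param_vector(mu_m = 21, sigma_m = 3, phi1 = 0.3, phi2 = 0.15, delta = 9)
param_vector <- function(mu_m, sigma_m, phi1, phi2, delta) {
  vals <- c(mu_m = mu_m, sigma_m = sigma_m, phi1 = phi1, phi2 = phi2,
            delta = delta)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (mu_m <= 10 || mu_m >= 50) stop("mu_m must lie in (10, 50) years")
  if (sigma_m <= 0) stop("sigma_m must be positive")
  if (delta < 0) stop("delta must be non-negative")
  fecundability_curve(phi1, phi2) # validates the curve
  structure(as.list(vals), class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  cat("Natural-fertility parameters:\n")
  cat(sprintf("  mu_m  = %.3f y   sigma_m = %.3f y\n", x$mu_m, x$sigma_m))
  cat(sprintf("  phi1  = %.3f     phi2    = %.3f\n", x$phi1, x$phi2))
  cat(sprintf("  delta = %.2f months\n", x$delta))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_women Cohort size (number of marriages simulated).
#' @param seed Integer root seed; all randomness in one simulation run
#'   (marriage ages, frailty, monthly trials) derives from it.
#' @param age_grid Integer completed ages for the ASFR summary
#'   (default `15:49`; `10:49` also supported).
#' @param gestation Gestation length in months (fixed at 9 in the model).
#' @param heterogeneity Optional [frailty_model()]; `NULL` means homogeneous
#'   fecundability.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_women, seed = 1L, age_grid = 15:49, gestation = 9L,
                       heterogeneity = NULL) {
  stopifnot(is.numeric(n_women), length(n_women) == 1L, n_women >= 1)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(is.numeric(age_grid), all(age_grid == as.integer(age_grid)),
            all(diff(age_grid) == 1L), all(age_grid >= 10 & age_grid <= 49))
  if (!is.null(heterogeneity)) stopifnot(inherits(heterogeneity, "frailty_model"))
  structure(list(n_women = as.integer(n_women), seed = as.integer(seed),
                 age_grid = as.integer(age_grid),
                 gestation = as.integer(gestation),
                 heterogeneity = heterogeneity),
            class = "sim_config")
}

#' Draw ages at marriage (months)
#'
#' Ages at marriage are lognormal, parametrized by the distribution's own
#' mean and standard deviation (`mu_m`, `sigma_m`, both in years). With
#' target mean `m = 12 mu_m` and variance `v = (12 sigma_m)^2` months, the
#' log-scale parameters are `meanlog = log(m^2 / sqrt(m^2 + v))` and
#' `sdlog = sqrt(log(1 + v / m^2))`. Draws below 120 months (age 10, the
#' start of the reproductive window) are resampled. Uses R's global RNG.
#'
#' @param mu_m,sigma_m Mean and SD of age at marriage, years.
#' @param n Number of draws.
#' @return `n` marriage ages in months (real-valued).
#' @export
sample_marriage_ages <- function(mu_m, sigma_m, n) {
  stopifnot(is.numeric(mu_m), is.numeric(sigma_m), n >= 1)
  if (mu_m <= 0 || sigma_m <= 0) stop("mu_m and sigma_m must be positive")
  m <- mu_m * 12
  v <- (sigma_m * 12)^2
  meanlog <- log(m^2 / sqrt(m^2 + v))
  sdlog <- sqrt(log(1 + v / m^2))
  out <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(out < 120)
  while (length(bad) > 0) {
    out[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[out[bad] < 120]
  }
  out
}

# Monthly fecundability lookup: phi at exact age m/12 years for month index
# m = 0, ..., 599 (zero outside the fecund window).
phi_month_table <- function(curve, horizon = 600L) {
  months <- 0:(horizon - 1L)
  phi <- numeric(horizon)
  inside <- months >= 120L
  phi[inside] <- conception_probability(months[inside] / 12, curve)
  phi
}

# Shared driver for the C++ cohort loop. Draws marriage ages and frailty
# under a seed-set R RNG, then runs per-woman monthly Bernoulli trials in
# C++ with deterministic per-woman substreams.
run_cohort <- function(theta, config, keep_histories) {
  stopifnot(inherits(theta, "param_vector"), inherits(config, "sim_config"))
  curve <- fecundability_curve(theta$phi1, theta$phi2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  marr <- sample_marriage_ages(theta$mu_m, theta$sigma_m, config$n_women)
  z <- if (is.null(config$heterogeneity)) rep(1, config$n_women)
       else sample_frailty(config$heterogeneity, config$n_women)
  res <- .sim_cohort_cpp(marr, z, phi_month_table(curve),
                         config$gestation, as.integer(ceiling(theta$delta)),
                         600L, config$seed, keep_histories)
  list(marriage = marr, frailty = z, counts = res$counts,
       conceptions = res$conceptions)
}

#' Simulate a cohort of reproductive histories
#'
#' Runs the monthly discrete-time model for `config$n_women` women from
#' marriage to age 50 (month 600). Each month a married woman who is neither
#' pregnant nor amenorrheic undergoes a Bernoulli conception trial with
#' probability `z * phi(age)` (clamped at 1); a conception at month `c`
#' produces a birth at `c + 9` and blocks conception through month
#' `c + 9 + ceiling(delta)`. Pregnancies whose birth would fall after the
#' window are censored. The first trial happens in the first whole month
#' strictly after the (real-valued) marriage age.
#'
#' @param theta A [param_vector()].
#' @param config A [sim_config()].
#' @return An object of class `cohort_histories`: a list with per-woman
#'   `marriage_age` (months), `conception_ages` / `birth_ages` (integer
#'   months, `birth_ages = conception_ages + gestation`), `frailty`, and the
#'   `theta` / `config` used.
#' @export
#' @examples
#' theta <- param_vector(21, 3, 0.25, 0.12, 9)
#' coh <- simulate_cohort(theta, sim_config(n_women = 50, seed = 1))
#' completed_fertility(coh)
simulate_cohort <- function(theta, config) {
  res <- run_cohort(theta, config, keep_histories = TRUE)
  structure(list(marriage_age = res$marriage,
                 conception_ages = res$conceptions,
                 birth_ages = lapply(res$conceptions, function(co) co + config$gestation),
                 frailty = res$frailty,
                 theta = theta, config = config),
            class = "cohort_histories")
}

#' @export
print.cohort_histories <- function(x, ...) {
  cat("Cohort of", length(x$marriage_age), "simulated reproductive histories\n")
  cat("  mean births per woman:",
      format(completed_fertility(x), digits = 4), "\n")
  invisible(x)
}

#' Age-specific fertility rate schedule
#'
#' @param ages Integer completed ages (consecutive).
#' @param rates Births per woman-year at each age.
#' @return An object of class `asfr_schedule` (a data.frame with columns
#'   `age` and `rate`).
#' @export
asfr_schedule <- function(ages, rates) {
  stopifnot(length(ages) == length(rates), all(diff(ages) == 1),
            all(rates >= 0))
  structure(data.frame(age = as.integer(ages), rate = as.numeric(rates)),
            class = c("asfr_schedule", "data.frame"))
}

#' Compute ASFRs from simulated histories
#'
#' The rate at completed age `a` is the number of births with
#' `floor(birth_month / 12) == a` divided by the number of women in the
#' cohort: every woman contributes one woman-year to every age, so summing
#' single-age rates over the full window 10--49 gives mean births per woman.
#'
#' @param histories A `cohort_histories` object from [simulate_cohort()].
#' @param age_grid Integer grid of completed ages (default from the
#'   cohort's configuration).
#' @return An [asfr_schedule()].
#' @export
compute_asfr <- function(histories, age_grid = NULL) {
  stopifnot(inherits(histories, "cohort_histories"))
  n <- length(histories$marriage_age)
  if (n == 0) stop("empty cohort")
  if (is.null(age_grid)) age_grid <- histories$config$age_grid
  births <- unlist(histories$birth_ages, use.names = FALSE)
  counts <- tabulate(match(births %/% 12L, age_grid), nbins = length(age_grid))
  asfr_schedule(age_grid, counts / n)
}

#' Mean completed fertility of a cohort
#'
#' @param histories A `cohort_histories` object.
#' @return Arithmetic mean number of recorded births per woman.
#' @export
completed_fertility <- function(histories) {
  stopifnot(inherits(histories, "cohort_histories"))
  if (length(histories$marriage_age) == 0) stop("empty cohort")
  mean(lengths(histories$birth_ages))
}

# Fast path for ABC: simulate and summarize without materializing histories.
simulate_asfr <- function(theta, config) {
  res <- run_cohort(theta, config, keep_histories = FALSE)
  counts <- res$counts # indexed by completed age 0..50
  asfr_schedule(config$age_grid, counts[config$age_grid + 1L] / config$n_women)
}
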