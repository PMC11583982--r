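#' Scale an age to the unit interval of the reproductive window
#'
#' The reproductive window is fixed at ages 10--50 years; ages are mapped
#' linearly onto `[0, 1]` via `xs = (x - 10) / 40`.
#'
#' @param x Numeric vector of ages in years, all within `[10, 50]`.
#' @return Numeric vector of scaled ages in `[0, 1]`.
#' @export
#' @examples
#' scale_age(c(10, 30, 50))
scale_age <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 10 | x > 50, na.rm = TRUE)) {
    stop("ages must lie in the reproductive window [10, 50] years")
  }
  (x - 10) / 40
}

#' Cubic Bernstein basis on the scaled age
#'
#' Evaluates the four cubic Bernstein polynomials used to parametrize the
#' age profile of fecundability:
#' `B1 = 3 xs (1 - xs)^2`, `B2 = 3 xs^2 (1 - xs)`, `B3 = (1 - xs)^3`,
#' `B4 = xs^3`. They form a partition of unity on `[0, 1]`.
#'
#' @param xs Numeric vector of scaled ages in `[0, 1]`.
#' @return A matrix with columns `B1`, `B2`, `B3`, `B4`, one row per input.
#' @export
#' @examples
#' bernstein_basis(c(0, 0.5, 1))
bernstein_basis <- function(xs) {
  stopifnot(is.numeric(xs))
  if (any(xs < 0 | xs > 1, na.rm = TRUE)) {
    stop("scaled age must lie in [0, 1]")
  }
  cbind(
    B1 = 3 * xs * (1 - xs)^2,
    B2 = 3 * xs^2 * (1 - xs),
    B3 = (1 - xs)^3,
    B4 = xs^3
  )
}

#' Two-coefficient fecundability curve
#'
#' The monthly conception probability over age is modelled as a cubic in the
#' Bernstein basis with the endpoint coefficients pinned to zero (fecundability
#' is zero at ages 10 and 50), leaving the two free coefficients `phi1`
#' (controls the level at which the curve peaks) and `phi2` (controls how
#' slowly the risk decays toward sterility).
#'
#' @param phi1,phi2 Non-negative coefficients on `B1` and `B2`, on the monthly
#'   probability scale. The implied curve must stay within `[0, 1]`.
#' @return An object of class `fecundability_curve`.
#' @export
#' @examples
#' fecundability_curve(0.3, 0.1)
fecundability_curve <- function(phi1, phi2) {
  stopifnot(is.numeric(phi1), is.numeric(phi2),
            length(phi1) == 1L, length(phi2) == 1L,
            is.finite(phi1), is.finite(phi2))
  if (phi1 < 0 || phi2 < 0) stop("phi1 and phi2 must be non-negative")
  curve <- structure(list(phi1 = phi1, phi2 = phi2),
                     class = "fecundability_curve")
  pk <- if (phi1 == 0 && phi2 == 0) list(peak = 0)
        else peak_fecundability(curve)
  if (pk$peak > 1) {
    stop("configuration error: implied fecundability exceeds 1 ",
         "(prior box too wide): peak = ", format(pk$peak))
  }
  curve
}

#' @export
print.fecundability_curve <- function(x, ...) {
  pk <- peak_fecundability(x)
  cat("Fecundability curve: phi1 =", x$phi1, ", phi2 =", x$phi2, "\n")
  cat("  peak", format(pk$peak, digits = 4), "at age",
      format(pk$age, digits = 4), "years\n")
  invisible(x)
}

#' Monthly conception probability at a given age
#'
#' Evaluates the fecundability curve `phi(x) = phi1 B1(xs) + phi2 B2(xs)`
#' at age `x` years (exact, possibly fractional age), where `xs` is the
#' scaled age. Exactly zero at the window endpoints.
#'
#' @param x Numeric vector of ages in years within `[10, 50]`.
#' @param curve A [fecundability_curve()].
#' @return Monthly conception probabilities in `[0, 1]`.
#' @export
#' @examples
#' conception_probability(30, fecundability_curve(0.3, 0.1))
conception_probability <- function(x, curve) {
  stopifnot(inherits(curve, "fecundability_curve"))
  xs <- scale_age(x)
  p <- 3 * xs * (1 - xs) * (curve$phi1 * (1 - xs) + curve$phi2 * xs)
  if (any(p > 1, na.rm = TRUE)) {
    stop("configuration error: fecundability above 1 (prior box too wide)")
  }
  p
}

#' Age and level of peak fecundability
#'
#' The curve `phi(xs) = 3 xs (1 - xs) (phi1 (1 - xs) + phi2 xs)` is a cubic
#' vanishing at both endpoints, with a unique interior maximum for admissible
#' coefficients. The maximiser solves the quadratic stationarity condition
#' `3 (phi1 - phi2) xs^2 + (2 phi2 - 4 phi1) xs + phi1 = 0`.
#'
#' @param curve A [fecundability_curve()].
#' @return A list with `age` (years), `peak` (monthly probability) and
#'   `degenerate` (`TRUE` when `phi1 = phi2 = 0`, in which case `peak = 0`
#'   and `age` is `NA` and a warning is raised).
#' @export
#' @examples
#' peak_fecundability(fecundability_curve(0.27, 0))  # peak 0.12 at age 23.33
peak_fecundability <- function(curve) {
  stopifnot(inherits(curve, "fecundability_curve"))
  p1 <- curve$phi1
  p2 <- curve$phi2
  if (p1 == 0 && p2 == 0) {
    warning("degenerate curve: phi1 = phi2 = 0, peak undefined")
    return(list(age = NA_real_, peak = 0, degenerate = TRUE))
  }
  a <- 3 * (p1 - p2)
  b <- 2 * p2 - 4 * p1
  cc <- p1
  if (a == 0) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    roots <- (-b + c(-1, 1) * sqrt(max(disc, 0))) / (2 * a)
  }
  roots <- roots[roots > 0 & roots < 1]
  phi_at <- function(xs) 3 * xs * (1 - xs) * (p1 * (1 - xs) + p2 * xs)
  vals <- phi_at(roots)
  best <- which.max(vals)
  list(age = 10 + 40 * roots[best], peak = vals[best], degenerate = FALSE)
}

#' Gamma frailty model for heterogeneous fecundability
#'
#' Couples get a multiplicative frailty `z ~ Gamma(s, s)` (shape = rate = s),
#' so `E(z) = 1` and `Var(z) = 1/s = sigma2`. `sigma2 = 0` denotes the
#' homogeneous baseline (all multipliers exactly 1).
#'
#' @param sigma2 Frailty variance, `>= 0`. Mutually exclusive with `shape`.
#' @param shape Gamma shape/rate `s > 0`; `sigma2 = 1/shape`.
#' @return An object of class `frailty_model` with fields `shape` and
#'   `sigma2` (`shape = Inf` for the homogeneous case).
#' @export
#' @examples
#' frailty_model(sigma2 = 0.04)
frailty_model <- function(sigma2 = NULL, shape = NULL) {
  if (is.null(sigma2) == is.null(shape)) {
    stop("give exactly one of sigma2 or shape")
  }
  if (!is.null(shape)) {
    stopifnot(is.numeric(shape), length(shape) == 1L)
    if (!is.finite(shape) || shape <= 0) stop("shape must be positive")
    sigma2 <- 1 / shape
  } else {
    stopifnot(is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2))
    if (sigma2 < 0) stop("sigma2 must be non-negative")
    shape <- if (sigma2 == 0) Inf else 1 / sigma2
  }
  structure(list(shape = shape, sigma2 = sigma2), class = "frailty_model")
}

#' Draw frailty multipliers
#'
#' @param model A [frailty_model()].
#' @param n Number of draws.
#' @return `n` positive multipliers with mean 1 and variance `sigma2`
#'   (all exactly 1 for the homogeneous model). Uses R's global RNG stream.
#'   Draws are inverse-CDF transforms of uniforms, so under a shared seed
#'   they are comonotone across different `sigma2` values — heterogeneity
#'   scenario scans compare like with like (common random numbers).
#' @export
sample_frailty <- function(model, n) {
  stopifnot(inherits(model, "frailty_model"), n >= 1)
  if (!is.finite(model$shape)) return(rep(1, n))
  stats::qgamma(stats::runif(n), shape = model$shape, rate = model$shape)
}

#' Couple-level monthly conception probability
#'
#' Multiplies the population curve by a couple's frailty and clamps at 1 to
#' preserve the Bernoulli-trial semantics. For admissible priors (peak
#' fecundability below 0.35) clamping only bites for extreme frailty draws.
#'
#' @param z Positive frailty multiplier (vector OK).
#' @param x Age in years.
#' @param curve A [fecundability_curve()].
#' @return `min(z * phi(x), 1)`.
#' @export
couple_fecundability <- function(z, x, curve) {
  stopifnot(is.numeric(z), all(z > 0))
  pmin(z * conception_probability(x, curve), 1)
}
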