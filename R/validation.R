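#' Leave-one-out estimate from a reference table
#'
#' Takes row `i`'s simulated rates as pseudo-observed data, runs the
#' rejection + random-forest adjustment on all remaining rows and returns
#' the per-parameter posterior means. This is the unit step of the
#' cross-validation harness.
#'
#' @param table A [build_reference_table()] result (distances not required).
#' @param i Validation row index.
#' @param accept_fraction Rejection fraction applied to the remaining rows.
#' @param ntree,mtry,min_node,min_accepted See [rf_adjust()].
#' @return A list with `truth` and `estimate` (named numeric vectors over
#'   the five parameters) and the full `posterior` (`posterior_sample`).
#' @export
leave_one_out_estimate <- function(table, i, accept_fraction = 0.05,
                                   ntree = 500, mtry = NULL, min_node = 5,
                                   min_accepted = 50) {
  stopifnot(inherits(table, "reference_table"))
  n <- nrow(table$params)
  if (n < 2) stop("reference table needs at least 2 rows")
  if (i < 1 || i > n) stop("validation index out of range")
  s_obs <- table$summaries[i, ]
  rest <- setdiff(seq_len(n), i)
  S <- table$summaries[rest, , drop = FALSE]
  d <- sqrt(colSums((t(S) - s_obs)^2))
  keep <- accept_indices(d, accept_fraction)
  accepted <- structure(list(params = table$params[rest[keep], , drop = FALSE],
                             summaries = S[keep, , drop = FALSE],
                             distances = d[keep], index = rest[keep],
                             ages = table$ages, box = table$box),
                        class = "abc_accepted")
  post <- if (nrow(accepted$params) == 1) {
    # degenerate 2-row table: the single remaining draw is the posterior
    structure(list(raw = accepted$params, adjusted = accepted$params,
                   distances = accepted$distances, index = accepted$index,
                   ages = table$ages, box = table$box, s_obs = s_obs),
              class = "posterior_sample")
  } else {
    rf_adjust(accepted, s_obs, ntree = ntree, mtry = mtry,
              min_node = min_node, seed = derive_seed(table$config$seed, i),
              min_accepted = min(min_accepted, nrow(accepted$params)))
  }
  truth <- unlist(table$params[i, ])
  estimate <- vapply(post$adjusted, mean, numeric(1))
  list(truth = truth, estimate = estimate, posterior = post)
}

#' Scaled cross-validation prediction error
#'
#' For parameter `j`, `ERR_j = sum_i (estimate_i - truth_i)^2 / Var(truth_i)`
#' with `Var` the sample variance (n - 1 denominator) of the true values
#' drawn in the experiment. Scale-free: multiplying truths and estimates by
#' a nonzero constant leaves it unchanged.
#'
#' @param truths,estimates Aligned numeric vectors (length >= 2) or
#'   data.frames/matrices with one column per parameter.
#' @return A single ERR value (vectors) or a named vector per parameter.
#' @export
#' @examples
#' prediction_error(c(1, 2, 3), c(2, 3, 4)) # 3
prediction_error <- function(truths, estimates) {
  if (is.data.frame(truths) || is.matrix(truths)) {
    truths <- as.data.frame(truths)
    estimates <- as.data.frame(estimates)
    stopifnot(identical(names(truths), names(estimates)))
    return(vapply(names(truths), function(j) {
      prediction_error(truths[[j]], estimates[[j]])
    }, numeric(1)))
  }
  stopifnot(length(truths) == length(estimates), length(truths) >= 2)
  v <- stats::var(truths)
  if (v == 0) stop("zero variance of true values; ERR undefined")
  sum((estimates - truths)^2) / v
}

#' Parameter-recovery cross-validation experiment
#'
#' For each sample-size tier, builds a reference table of `n` prior draws
#' simulated with that many women, selects `replicates` validation rows
#' (without replacement), estimates each by leave-one-out rejection + RF
#' adjustment, and reports truth-vs-estimate scatter data plus the scaled
#' prediction error per parameter.
#'
#' @param tiers Cohort sizes, default `c(161, 3235, 5000)` (the number of
#'   marriages in the three reference populations, the largest capped at
#'   5000 where sample-to-sample rate variation is already negligible).
#' @param replicates Validation replicates per tier (default 100).
#' @param n Reference-table size per tier.
#' @param box A [prior_box()].
#' @param seed Root seed.
#' @param accept_fraction,ntree See [rf_adjust()].
#' @param age_grid Summary-statistic age grid.
#' @param progress_every See [build_reference_table()].
#' @return A list of class `validation_report`: `estimates` (data.frame with
#'   tier, replicate, parameter, truth, estimate, CI bounds), `err`
#'   (data.frame tier x parameter) and the call settings.
#' @export
recovery_experiment <- function(tiers = c(161, 3235, 5000), replicates = 100,
                                n = 10000, box = prior_box(), seed = 1L,
                                accept_fraction = 0.05, ntree = 500,
                                age_grid = 15:49, progress_every = 0) {
  est_rows <- list()
  err_rows <- list()
  for (tier in tiers) {
    config <- sim_config(n_women = tier, seed = derive_seed(seed, tier),
                         age_grid = age_grid)
    table <- build_reference_table(NULL, box, n, config,
                                   progress_every = progress_every)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(seed, tier + 1L))
    rows <- sample.int(n, replicates, replace = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    truths <- matrix(NA_real_, replicates, 5)
    ests <- matrix(NA_real_, replicates, 5)
    colnames(truths) <- colnames(ests) <- names(table$params)
    for (r in seq_len(replicates)) {
      loo <- leave_one_out_estimate(table, rows[r],
                                    accept_fraction = accept_fraction,
                                    ntree = ntree)
      truths[r, ] <- loo$truth
      ests[r, ] <- loo$estimate
      ci <- summarize_posterior(loo$posterior)
      est_rows[[length(est_rows) + 1L]] <-
        data.frame(tier = tier, replicate = r, parameter = ci$parameter,
                   truth = as.numeric(loo$truth[ci$parameter]),
                   estimate = as.numeric(loo$estimate[ci$parameter]),
                   lower = ci$lower, upper = ci$upper)
    }
    err <- prediction_error(as.data.frame(truths), as.data.frame(ests))
    err_rows[[length(err_rows) + 1L]] <-
      data.frame(tier = tier, parameter = names(err), err = as.numeric(err))
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 err = do.call(rbind, err_rows),
                 settings = list(tiers = tiers, replicates = replicates,
                                 n = n, seed = seed,
                                 accept_fraction = accept_fraction,
                                 ntree = ntree)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cross-validation report:", x$settings$replicates,
      "replicates per tier\n")
  print(stats::reshape(x$err, idvar = "parameter", timevar = "tier",
                       direction = "wide"))
  invisible(x)
}
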