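# Canonical maternity-history schema (delimited text, UTF-8, header row,
# '#' comment lines allowed). One row per woman:
#   woman_id                      unique identifier
#   cohort                        woman's birth year (NA if unknown)
#   marriage_age_months           real-valued age at marriage, months
#   wife_death_age_months         wife's age at death, months (NA if alive /
#                                 beyond observation)
#   spouse_death_wife_age_months  wife's age when the spouse died (NA)
#   observed_to_age_months        wife's age at end of observation
#   child_birth_ages_months       ';'-separated birth ages in months (may be
#                                 empty)
# Source registers with bespoke layouts are mapped to this schema by
# user-supplied adapters; ages are stored in months throughout.

required_history_columns <- c(
  "woman_id", "cohort", "marriage_age_months", "wife_death_age_months",
  "spouse_death_wife_age_months", "observed_to_age_months",
  "child_birth_ages_months"
)

#' Read maternity histories from a delimited text file
#'
#' Parses the canonical maternity-history schema (see the column dictionary
#' in the package source / vignette). Malformed rows are collected in an
#' error report attached as attribute `"errors"` rather than silently
#' dropped; missing required columns are a hard error.
#'
#' @param path Path to a CSV file with a header row (`#` comments allowed).
#' @return An object of class `maternity_records`: a data.frame with the
#'   schema columns plus a parsed `births` list-column (numeric months).
#' @export
read_histories <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(required_history_columns, names(raw))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "))
  }
  as_records(raw)
}

# Validate raw character rows into maternity_records, collecting row-level
# problems instead of failing.
as_records <- function(raw) {
  num <- function(x) suppressWarnings(as.numeric(x))
  parse_births <- function(s) {
    if (is.na(s) || s == "") return(numeric(0))
    num(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  n <- nrow(raw)
  births <- lapply(raw$child_birth_ages_months, parse_births)
  rec <- data.frame(
    woman_id = raw$woman_id,
    cohort = num(raw$cohort),
    marriage_age_months = num(raw$marriage_age_months),
    wife_death_age_months = num(raw$wife_death_age_months),
    spouse_death_wife_age_months = num(raw$spouse_death_wife_age_months),
    observed_to_age_months = num(raw$observed_to_age_months),
    stringsAsFactors = FALSE
  )
  errors <- list()
  bad <- logical(n)
  for (i in seq_len(n)) {
    msg <- character(0)
    b <- births[[i]]
    if (is.na(rec$marriage_age_months[i])) msg <- c(msg, "unparseable marriage age")
    if (anyNA(b)) msg <- c(msg, "unparseable child birth age")
    if (!anyNA(b) && length(b) > 0) {
      if (is.unsorted(b)) msg <- c(msg, "births not sorted")
      if (any(b < 0 | b > 1200)) msg <- c(msg, "birth age outside [0, 1200] months")
      if (!is.na(rec$marriage_age_months[i]) &&
          any(b < rec$marriage_age_months[i])) {
        msg <- c(msg, "birth before marriage")
      }
    }
    if (length(msg) > 0) {
      bad[i] <- TRUE
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, woman_id = raw$woman_id[i],
                   message = paste(msg, collapse = "; "))
    }
  }
  rec$births <- births
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("maternity_records", "data.frame")
  attr(out, "errors") <- if (length(errors) > 0) do.call(rbind, errors)
                         else data.frame(row = integer(0),
                                         woman_id = character(0),
                                         message = character(0))
  out
}

#' Sample definition for observed-data filtering
#'
#' @param cohort_range Length-2 numeric range of the woman's birth year
#'   (inclusive), or `NULL` for no cohort restriction.
#' @return An object of class `sample_definition`.
#' @export
sample_definition <- function(cohort_range = NULL) {
  if (!is.null(cohort_range)) {
    stopifnot(is.numeric(cohort_range), length(cohort_range) == 2L,
              cohort_range[1] <= cohort_range[2])
  }
  structure(list(cohort_range = cohort_range), class = "sample_definition")
}

#' Restrict to intact marriages within a cohort range
#'
#' Keeps women observed to age 50 whose marriage was not interrupted by
#' either spouse's death before the wife reached age 50, and whose birth
#' cohort falls in the sample definition's range. The intactness and cohort
#' filters commute.
#'
#' @param records A `maternity_records` object.
#' @param sample_def A [sample_definition()].
#' @return The filtered `maternity_records`.
#' @export
filter_intact <- function(records, sample_def = sample_definition()) {
  stopifnot(inherits(records, "maternity_records"),
            inherits(sample_def, "sample_definition"))
  to50 <- 600
  keep <- records$observed_to_age_months >= to50 &
    (is.na(records$wife_death_age_months) |
       records$wife_death_age_months >= to50) &
    (is.na(records$spouse_death_wife_age_months) |
       records$spouse_death_wife_age_months >= to50)
  keep[is.na(keep)] <- FALSE
  if (!is.null(sample_def$cohort_range)) {
    inco <- !is.na(records$cohort) &
      records$cohort >= sample_def$cohort_range[1] &
      records$cohort <= sample_def$cohort_range[2]
    keep <- keep & inco
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}

#' Observed ASFR schedule from maternity records
#'
#' Same convention as [compute_asfr()] on simulated cohorts: the rate at
#' completed age `a` is the number of recorded births at that age divided by
#' the number of women in the (filtered) sample, so observed and simulated
#' schedules are directly comparable.
#'
#' @param records A `maternity_records` object (typically after
#'   [filter_intact()]).
#' @param age_grid Integer completed ages (default `15:49`).
#' @return An [asfr_schedule()].
#' @export
observed_asfr <- function(records, age_grid = 15:49) {
  stopifnot(inherits(records, "maternity_records"))
  n <- nrow(records)
  if (n == 0) stop("empty sample")
  births <- unlist(records$births, use.names = FALSE)
  counts <- tabulate(match(floor(births / 12), age_grid),
                     nbins = length(age_grid))
  asfr_schedule(age_grid, counts / n)
}

#' Lower-bound estimate of mean post-partum amenorrhea
#'
#' Mean interval between first and second births (women with at least two
#' births) minus the mean interval between marriage and first birth (women
#' with at least one birth), in months. Because non-susceptible periods
#' lengthen with age and parity, this difference is a lower bound for mean
#' amenorrhea duration over the reproductive life course.
#'
#' @param records A `maternity_records` object.
#' @return The estimate in months.
#' @export
amenorrhea_lower_bound <- function(records) {
  stopifnot(inherits(records, "maternity_records"))
  first <- vapply(seq_len(nrow(records)), function(i) {
    b <- records$births[[i]]
    if (length(b) >= 1) b[1] - records$marriage_age_months[i] else NA_real_
  }, numeric(1))
  second <- vapply(records$births, function(b) {
    if (length(b) >= 2) b[2] - b[1] else NA_real_
  }, numeric(1))
  if (all(is.na(first)) || all(is.na(second))) {
    stop("no records with enough births to estimate amenorrhea")
  }
  mean(second, na.rm = TRUE) - mean(first, na.rm = TRUE)
}

#' Descriptive statistics of a maternity-history sample
#'
#' @param records A `maternity_records` object.
#' @return A list: `n_marriages`, `n_births`, `completed_fertility` (mean
#'   births per woman), `mean_marriage_age` and `sd_marriage_age` (years;
#'   the SD is `NA` for a single record).
#' @export
descriptives <- function(records) {
  stopifnot(inherits(records, "maternity_records"))
  n <- nrow(records)
  counts <- lengths(records$births)
  marr_y <- records$marriage_age_months / 12
  list(n_marriages = n, n_births = sum(counts),
       completed_fertility = if (n > 0) mean(counts) else NA_real_,
       mean_marriage_age = if (n > 0) mean(marr_y) else NA_real_,
       sd_marriage_age = if (n > 1) stats::sd(marr_y) else NA_real_)
}

#' Convert simulated histories to the canonical record schema
#'
#' Simulated marriages are intact by construction (the model has no
#' mortality): wife and spouse death fields are `NA` and observation runs to
#' age 50, so [filter_intact()] keeps every row.
#'
#' @param histories A `cohort_histories` object.
#' @param cohort Birth-year value recorded for every woman (default `NA`).
#' @return A `maternity_records` object.
#' @export
histories_to_records <- function(histories, cohort = NA_real_) {
  stopifnot(inherits(histories, "cohort_histories"))
  n <- length(histories$marriage_age)
  rec <- data.frame(
    woman_id = sprintf("w%05d", seq_len(n)),
    cohort = rep(as.numeric(cohort), n),
    marriage_age_months = histories$marriage_age,
    wife_death_age_months = NA_real_,
    spouse_death_wife_age_months = NA_real_,
    observed_to_age_months = rep(600, n),
    stringsAsFactors = FALSE
  )
  rec$births <- lapply(histories$birth_ages, as.numeric)
  class(rec) <- c("maternity_records", "data.frame")
  attr(rec, "errors") <- data.frame(row = integer(0), woman_id = character(0),
                                    message = character(0))
  rec
}

#' Write maternity histories to the canonical delimited-text schema
#'
#' Accepts either simulated `cohort_histories` or `maternity_records`. The
#' file starts with `#` header comments embedding the package version and
#' any seed/configuration metadata, followed by a CSV header row. A
#' write-then-[read_histories()] round trip reproduces the records.
#'
#' @param x A `cohort_histories` or `maternity_records` object.
#' @param path Output file path.
#' @param metadata Named character vector added to the header comments.
#' @return `path`, invisibly.
#' @export
write_histories <- function(x, path, metadata = character(0)) {
  if (inherits(x, "cohort_histories")) {
    metadata <- c(seed = as.character(x$config$seed), metadata)
    x <- histories_to_records(x)
  }
  stopifnot(inherits(x, "maternity_records"))
  num2str <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  flat <- x
  for (col in c("cohort", "marriage_age_months", "wife_death_age_months",
                "spouse_death_wife_age_months", "observed_to_age_months")) {
    flat[[col]] <- num2str(x[[col]])
  }
  flat$child_birth_ages_months <-
    vapply(x$births, function(b) paste(num2str(b), collapse = ";"),
           character(1))
  flat$child_birth_ages_months[lengths(x$births) == 0] <- ""
  flat$births <- NULL
  header <- c(
    paste0("# natfert ", as.character(utils::packageVersion("natfert")),
           " maternity-history file"),
    if (length(metadata) > 0) paste0("# ", names(metadata), "=", metadata)
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(flat)[, required_history_columns],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ASFR schedule as two-column delimited text
#'
#' @param schedule An [asfr_schedule()].
#' @param path Output path.
#' @param metadata Named character vector embedded as `#` header comments.
#' @return `path`, invisibly.
#' @export
write_asfr <- function(schedule, path, metadata = character(0)) {
  stopifnot(inherits(schedule, "asfr_schedule"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# natfert ",
                      as.character(utils::packageVersion("natfert")),
                      " ASFR schedule"),
               if (length(metadata) > 0)
                 paste0("# ", names(metadata), "=", metadata)), con)
  utils::write.csv(as.data.frame(schedule), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a two-column ASFR schedule
#'
#' @param path Path to a delimited text file with columns `age` and `rate`
#'   (`#` comments allowed).
#' @return An [asfr_schedule()].
#' @export
read_asfr <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "rate") %in% names(df))) {
    stop("ASFR file must have columns 'age' and 'rate'")
  }
  asfr_schedule(df$age, df$rate)
}
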