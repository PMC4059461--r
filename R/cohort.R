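#' Competing-risks cohort
#'
#' Container for right-censored competing-risks data: one row per subject
#' with the observed time `Ti = min(Ti_event, Ci)`, the observed event code
#' `Di` (0 = censored, 1 = event of interest, 2 = competing event) and an
#' optional table of baseline covariates. Analyses of the competing event
#' are obtained by passing `cause = 2` to the estimators, which relabels the
#' two causes; event codes greater than 2 are rejected — merging several
#' competing causes into code 2 is the caller's responsibility.
#'
#' @param time positive, finite observed times.
#' @param event event codes, all in `{0, 1, 2}`.
#' @param covariates optional data.frame or matrix with one row per subject
#'   and finite numeric entries.
#' @param id optional subject labels.
#' @return an object of class `cr_cohort` with elements `time`, `event`,
#'   `covariates` (a data.frame, possibly with zero columns) and `id`.
#' @examples
#' cr_cohort(time = c(1, 2, 3), event = c(1, 0, 2),
#'           covariates = data.frame(x = c(0.5, -1, 2)))
#' @export
cr_cohort <- function(time, event, covariates = NULL, id = NULL) {
  n <- length(time)
  if (n < 2L) crc_validation_error("a cohort needs at least 2 subjects")
  if (length(event) != n) crc_validation_error("time and event lengths differ")
  time <- as.numeric(time)
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    crc_validation_error(sprintf("non-positive or non-finite time at row %d", bad[1]))
  event <- as.integer(event)
  bad <- which(is.na(event) | !(event %in% 0:2))
  if (length(bad))
    crc_validation_error(sprintf("event code outside {0,1,2} at row %d", bad[1]))
  covariates <- validate_covariates(covariates, n)
  if (!is.null(id) && length(id) != n)
    crc_validation_error("id length differs from cohort size")
  structure(list(time = time, event = event, covariates = covariates,
                 id = id),
            class = "cr_cohort")
}

validate_covariates <- function(covariates, n) {
  if (is.null(covariates))
    return(as.data.frame(matrix(numeric(0), nrow = n, ncol = 0)))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n)
    crc_validation_error("covariate table row count differs from cohort size")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) crc_validation_error(sprintf("covariate '%s' is not numeric", nm))
    bad <- which(!is.finite(v))
    if (length(bad))
      crc_validation_error(sprintf("missing/non-finite covariate '%s' at row %d", nm, bad[1]))
  }
  covariates
}

#' Uncensored competing-risks sample
#'
#' Fully observed competing-risks data: event times `T` and causes
#' `D` in `{1, 2}` (no censoring), as produced by the simulation generator
#' before censoring is applied.
#'
#' @param time positive, finite event times.
#' @param cause causes, all in `{1, 2}`.
#' @inheritParams cr_cohort
#' @return an object of class `cr_sample`.
#' @export
cr_sample <- function(time, cause, covariates = NULL, id = NULL) {
  if (any(cause == 0L))
    crc_validation_error("cr_sample must not contain censored observations (code 0)")
  x <- cr_cohort(time, cause, covariates, id)
  class(x) <- c("cr_sample", "cr_cohort")
  x
}

# Treat any cohort-like object as a cohort; a cr_sample is a cohort with no
# zeros.
as_cohort <- function(x) {
  if (inherits(x, "cr_cohort")) return(x)
  crc_validation_error("expected a cr_cohort / cr_sample object")
}

cohort_size <- function(cohort) length(cohort$time)

#' Predicted risks at a horizon
#'
#' Predictions `M(t, X_i)` ordering subjects by predicted risk of the event
#' of interest by horizon `t`; higher values mean higher predicted risk.
#' Estimator functions also accept a bare numeric vector together with their
#' own `t` argument.
#'
#' @param values finite numeric predictions, one per subject.
#' @param horizon positive prediction horizon `t`.
#' @return an object of class `risk_predictions`.
#' @export
risk_predictions <- function(values, horizon) {
  if (!is.numeric(values) || any(!is.finite(values)))
    crc_validation_error("prediction values must be finite numerics")
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    crc_validation_error("horizon must be a single positive number")
  structure(list(values = as.numeric(values), horizon = as.numeric(horizon)),
            class = "risk_predictions")
}

# Resolve predictions argument against a cohort and horizon.
resolve_predictions <- function(predictions, cohort, t) {
  if (inherits(predictions, "risk_predictions")) {
    if (!missing(t) && !is.null(t) && !isTRUE(all.equal(predictions$horizon, t)))
      crc_validation_error("prediction horizon differs from requested t")
    predictions <- predictions$values
  }
  predictions <- as.numeric(predictions)
  if (length(predictions) != cohort_size(cohort))
    crc_validation_error("prediction length differs from cohort size")
  if (any(!is.finite(predictions)))
    crc_validation_error("prediction values must be finite")
  predictions
}

#' Read a cohort from a delimited text file
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param time_col,event_col column names holding observed time and event
#'   code.
#' @param covariate_cols names of covariate columns; default all remaining
#'   numeric columns.
#' @param id_col optional subject-id column.
#' @param delim field delimiter; `NULL` infers `"\t"` vs `","` from the
#'   header line.
#' @return a [cr_cohort()] with rows in file order.
#' @export
read_cohort <- function(path, time_col = "time", event_col = "event",
                        covariate_cols = NULL, id_col = NULL, delim = NULL) {
  if (!file.exists(path)) crc_config_error(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (col in c(time_col, event_col, covariate_cols, id_col))
    if (!col %in% names(df))
      crc_config_error(sprintf("column '%s' not present in %s", col, path))
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df), c(time_col, event_col, id_col))
  covs <- if (length(covariate_cols)) df[covariate_cols] else NULL
  cr_cohort(time = df[[time_col]], event = df[[event_col]],
            covariates = covs,
            id = if (!is.null(id_col)) df[[id_col]] else NULL)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: writing then reading reproduces the times,
#' event codes and covariates exactly (times are printed at full precision).
#'
#' @param cohort a [cr_cohort()].
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  cohort <- as_cohort(cohort)
  df <- data.frame(time = cohort$time, event = cohort$event)
  if (ncol(cohort$covariates)) df <- cbind(df, cohort$covariates)
  if (!is.null(cohort$id)) df$id <- cohort$id
  old <- options(digits = 17)
  on.exit(options(old))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pairwise comparability indicators
#'
#' For every ordered pair `(i, j)` of subjects, the indicators driving the
#' concordance estimators: `A[i, j] = 1{Ti < Tj}` (subject i observed to
#' fail strictly first), `B[i, j] = 1{Ti >= Tj and Dj = 2}` (subject j had a
#' competing event no later than i's time), and the truncated cause-1 event
#' indicator `N1[i] = 1{Ti <= t, Di = 1}`. Diagonal pairs contribute nothing
#' downstream: `A[i, i] = 0` and `B[i, i] * N1[i] = 0` since codes 1 and 2
#' are exclusive.
#'
#' @param cohort a [cr_cohort()].
#' @param t positive truncation horizon.
#' @param cause event of interest (1 or 2); cause 2 relabels the codes.
#' @return list with `n x n` 0/1 matrices `A`, `B` and vector `N1`.
#' @export
comparability_indicators <- function(cohort, t, cause = 1) {
  cohort <- as_cohort(cohort)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    crc_validation_error("t must be a single positive number")
  ev <- relabel_cause(cohort$event, cause)
  time <- cohort$time
  A <- outer(time, time, "<") * 1
  B <- outer(time, time, ">=") * rep(as.numeric(ev == 2L), each = length(time))
  N1 <- as.numeric(time <= t & ev == 1L)
  list(A = A, B = B, N1 = N1)
}

# cause = 2 analyses reuse the cause-1 code path by swapping codes 1 and 2.
relabel_cause <- function(event, cause) {
  if (!cause %in% c(1, 2)) crc_validation_error("cause must be 1 or 2")
  if (cause == 2) event <- c(0L, 2L, 1L)[event + 1L]
  event
}

#' @export
print.cr_cohort <- function(x, ...) {
  n <- cohort_size(x)
  tab <- tabulate(x$event + 1L, nbins = 3L)
  cat(sprintf("<cr_cohort> %d subjects: %d censored, %d cause-1, %d cause-2\n",
              n, tab[1], tab[2], tab[3]))
  cat(sprintf("  follow-up range [%.4g, %.4g], %d covariate(s)%s\n",
              min(x$time), max(x$time), ncol(x$covariates),
              if (ncol(x$covariates)) paste0(": ", paste(names(x$covariates), collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
print.cr_sample <- function(x, ...) {
  n <- cohort_size(x)
  cat(sprintf("<cr_sample> %d subjects (uncensored): %d cause-1, %d cause-2\n",
              n, sum(x$event == 1L), sum(x$event == 2L)))
  invisible(x)
}
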