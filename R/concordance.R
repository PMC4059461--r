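#' Concordance estimates
#'
#' All concordance estimators return a `cr_concordance` object holding the
#' point estimate (the ratio of the weighted concordant pair sum to the
#' weighted evaluable pair sum), the horizon, the cause analysed, the raw
#' numerator/denominator, the count of evaluable ordered pairs and the tie
#' handling used. Standard errors and confidence intervals are attached by
#' the inference functions.
#'
#' @name cr_concordance
NULL

new_cr_concordance <- function(value, horizon, cause, estimator, numerator,
                               denominator, n_pairs, tie_handling, n) {
  structure(list(value = value, horizon = horizon, cause = cause,
                 estimator = estimator, numerator = numerator,
                 denominator = denominator, n_pairs = n_pairs,
                 tie_handling = tie_handling, n = n,
                 se = NULL, ci = NULL),
            class = "cr_concordance")
}

tie_weight <- function(tie_handling = c("strict", "half_weight")) {
  tie_handling <- match.arg(tie_handling)
  c(strict = 0, half_weight = 0.5)[[tie_handling]]
}

#' Exact truncated concordance on uncensored data
#'
#' The truncated cause-specific concordance computed directly from its
#' definition on fully observed competing-risks data: among ordered pairs
#' `(i, j)` with `Di = 1`, `Ti <= t` and (`Ti < Tj` or `Dj = 2`), the
#' proportion whose predictions satisfy `Mi > Mj` (prediction ties count
#' 1/2 under `half_weight`, nothing under `strict`).
#'
#' @param sample a [cr_sample()] (no censored observations).
#' @param predictions numeric predictions (higher = higher predicted risk of
#'   the event of interest by `t`) or a [risk_predictions()].
#' @param t positive truncation horizon.
#' @param cause event of interest, 1 (default) or 2.
#' @param tie_handling `"strict"` (definition as written) or
#'   `"half_weight"`.
#' @return a `cr_concordance` object.
#' @examples
#' s <- cr_sample(c(1, 2, 3), c(1, 2, 1))
#' concordance_exact_uncensored(s, c(0.9, 0.5, 0.4), t = 3)  # 2/3
#' @export
concordance_exact_uncensored <- function(sample, predictions, t, cause = 1,
                                         tie_handling = "strict") {
  sample <- as_cohort(sample)
  if (any(sample$event == 0L))
    crc_validation_error("sample contains censored observations; use concordance_naive or concordance_ipcw")
  est <- concordance_naive(sample, predictions, t, cause, tie_handling)
  est$estimator <- "exact_uncensored"
  est
}

#' Naive (Harrell-type) concordance estimator
#'
#' Proportion of definitely concordant pairs among evaluable pairs — pairs
#' whose ordering can be decided from the observed, possibly censored data.
#' On fully uncensored data it equals [concordance_exact_uncensored()]; under
#' censoring it ignores non-evaluable pairs without correction and is
#' asymptotically biased.
#'
#' @param cohort a [cr_cohort()].
#' @inheritParams concordance_exact_uncensored
#' @return a `cr_concordance` object.
#' @export
concordance_naive <- function(cohort, predictions, t, cause = 1,
                              tie_handling = "strict") {
  cohort <- as_cohort(cohort)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    crc_validation_error("t must be a single positive number")
  M <- resolve_predictions(predictions, cohort, t)
  ev <- relabel_cause(cohort$event, cause)
  s <- pair_sums_unweighted(cohort$time, ev, M, t, tie_weight(tie_handling))
  if (s$den <= 0)
    crc_undefined_estimate("no evaluable pairs at this horizon; consider a larger t")
  new_cr_concordance(s$num / s$den, t, cause, "naive", s$num, s$den,
                     s$n_pairs, tie_handling, cohort_size(cohort))
}

#' IPCW pair weights
#'
#' The inverse-probability-of-censoring weights attached to the two kinds of
#' evaluable pairs: `W1[i, j] = G(Ti- | Xi) G(Ti | Xj)` (pairs ordered by an
#' observed earlier failure of i) and `W2[i, j] = G(Ti- | Xi) G(Tj- | Xj)`
#' (pairs ordered by j's competing event). Note the asymmetry: `W1`
#' evaluates subject j's censoring survival at `Ti` (right limit), `W2` at
#' `Tj-` (left limit).
#'
#' Dense `n x n` matrices are returned; this auditable representation is
#' intended for cohorts up to a few thousand subjects (the estimators
#' themselves stream the same formula pairwise).
#'
#' @param cohort a [cr_cohort()].
#' @param censoring_model a fitted [censoring_model] (reverse Kaplan-Meier
#'   or Cox).
#' @param weight_floor positivity floor; weights below it trigger a warning.
#' @param truncate_weights if `TRUE`, weights below the floor are raised to
#'   it.
#' @return list with matrices `W1` and `W2` (entries in `(0, 1]` up to the
#'   floor behaviour; all exactly 1 under no censoring).
#' @export
compute_pair_weights <- function(cohort, censoring_model, weight_floor = 0.01,
                                 truncate_weights = FALSE) {
  cohort <- as_cohort(cohort)
  time <- cohort$time
  Hm <- cens_cumhaz_at(censoring_model, time, "left")
  Hr <- cens_cumhaz_at(censoring_model, time, "right")
  elp <- cens_explp(censoring_model, as.matrix(cohort$covariates))
  g_minus <- exp(-Hm * elp)                 # G(Ti- | Xi)
  W1 <- g_minus * exp(-outer(Hr, elp))      # row i: G(Ti-|Xi) G(Ti|Xj)
  W2 <- outer(g_minus, g_minus)             # G(Ti-|Xi) G(Tj-|Xj)
  n_below <- sum(W1 < weight_floor) + sum(W2 < weight_floor)
  if (n_below > 0) {
    warning(sprintf("%d pair weight(s) below the floor %.3g%s", n_below,
                    weight_floor,
                    if (truncate_weights) "; truncated at the floor" else ""),
            call. = FALSE)
    if (truncate_weights) {
      W1 <- pmax(W1, weight_floor)
      W2 <- pmax(W2, weight_floor)
    }
  }
  list(W1 = W1, W2 = W2)
}

#' IPCW concordance estimator
#'
#' Inverse-probability-of-censoring-weighted estimator of the truncated
#' cause-specific concordance: each evaluable pair enters the concordant and
#' evaluable sums with weight `1/W1[i, j]` (pairs evaluable through an
#' observed earlier failure) or `1/W2[i, j]` (pairs evaluable through a
#' competing event), removing the censoring-induced bias of the naive
#' estimator whenever the censoring working model is correctly specified.
#' On uncensored data all weights equal 1 and the estimate coincides with
#' [concordance_exact_uncensored()].
#'
#' @inheritParams concordance_naive
#' @param censoring_model a fitted [censoring_model]; default refits a
#'   marginal reverse Kaplan-Meier on `cohort`.
#' @param weight_floor,truncate_weights positivity guard, see
#'   [compute_pair_weights()].
#' @return a `cr_concordance` object with estimator `"ipcw_km"` or
#'   `"ipcw_cox"` according to the censoring model.
#' @export
concordance_ipcw <- function(cohort, predictions, t, cause = 1,
                             censoring_model = NULL,
                             tie_handling = "strict",
                             weight_floor = 0.01, truncate_weights = FALSE) {
  cohort <- as_cohort(cohort)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    crc_validation_error("t must be a single positive number")
  M <- resolve_predictions(predictions, cohort, t)
  if (is.null(censoring_model)) censoring_model <- fit_reverse_km(cohort)
  ev <- relabel_cause(cohort$event, cause)
  elp <- cens_explp(censoring_model, as.matrix(cohort$covariates))
  Hm <- cens_cumhaz_at(censoring_model, cohort$time, "left")
  Hr <- cens_cumhaz_at(censoring_model, cohort$time, "right")
  s <- pair_sums_ipcw(cohort$time, ev, M, t, tie_weight(tie_handling),
                      Hm, Hr, elp, weight_floor, truncate_weights)
  if (s$n_below_floor > 0)
    warning(sprintf("%d pair weight(s) below the floor %.3g%s",
                    as.integer(s$n_below_floor), weight_floor,
                    if (truncate_weights) "; truncated at the floor" else ""),
            call. = FALSE)
  # positivity enters through the weights the estimator actually uses: a
  # zero weight on an evaluable pair makes the sums non-finite
  if (!is.finite(s$den) || !is.finite(s$num))
    crc_precondition_error("estimated censoring survival reaches 0 at an evaluated pair; positivity fails, choose a smaller t")
  if (s$den <= 0)
    crc_undefined_estimate("no evaluable pairs at this horizon; consider a larger t")
  estimator <- if (censoring_model$kind == "cox") "ipcw_cox" else "ipcw_km"
  new_cr_concordance(s$num / s$den, t, cause, estimator, s$num, s$den,
                     s$n_pairs, tie_handling, cohort_size(cohort))
}

# Dense-matrix reference implementation of the weighted ratio, kept for
# auditability and dual-route testing against the streaming kernel.
concordance_ipcw_dense <- function(cohort, predictions, t, cause = 1,
                                   censoring_model = NULL,
                                   tie_handling = "strict") {
  cohort <- as_cohort(cohort)
  M <- resolve_predictions(predictions, cohort, t)
  if (is.null(censoring_model)) censoring_model <- fit_reverse_km(cohort)
  ind <- comparability_indicators(cohort, t, cause)
  w <- suppressWarnings(compute_pair_weights(cohort, censoring_model,
                                             weight_floor = 0))
  Q <- outer(M, M, ">") + tie_weight(tie_handling) * outer(M, M, "==")
  diag(Q) <- 0
  # guard inactive pairs whose weight is 0 (G already 0 there): 0/0 -> 0
  K <- ifelse(ind$A > 0, ind$A / w$W1, 0) + ifelse(ind$B > 0, ind$B / w$W2, 0)
  num <- sum(K * Q * ind$N1)
  den <- sum(K * ind$N1)
  if (den <= 0) crc_undefined_estimate("no evaluable pairs at this horizon")
  num / den
}

#' @export
print.cr_concordance <- function(x, ...) {
  cat(sprintf("<cr_concordance> C%d(t = %.4g) = %.4f  [%s, ties: %s]\n",
              x$cause, x$horizon, x$value, x$estimator, x$tie_handling))
  cat(sprintf("  %g evaluable ordered pairs from n = %d subjects\n",
              x$n_pairs, x$n))
  if (!is.null(x$se))
    cat(sprintf("  se = %.4f", x$se),
        if (!is.null(x$ci))
          sprintf(", %g%% CI [%.4f, %.4f] (%s)", 100 * (x$ci_level %||% 0.95),
                  x$ci[1], x$ci[2], x$ci_method %||% "")
        else "", "\n", sep = "")
  invisible(x)
}
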