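#' Working models for the censoring distribution
#'
#' IPCW estimation needs an estimate of `G(t | x) = P(C > t | X = x)`, the
#' conditional probability of remaining uncensored. Two working models are
#' supported: a marginal reverse Kaplan-Meier estimate (censoring
#' independent of everything) fitted by [fit_reverse_km()], and a Cox
#' proportional-hazards model for the censoring hazard with Breslow baseline
#' fitted by [fit_cox_censoring()]. Both yield right-continuous step
#' functions evaluable with left limits via [censoring_survival_at()].
#'
#' @name censoring_model
NULL

new_censoring_survival <- function(kind, jump_times, values, gamma = NULL,
                                   covariate_names = NULL, max_time, n) {
  structure(list(kind = kind, jump_times = jump_times, values = values,
                 gamma = gamma, covariate_names = covariate_names,
                 max_time = max_time, n = n),
            class = "censoring_survival")
}

#' Marginal reverse Kaplan-Meier censoring model
#'
#' Product-limit estimator of `G(t) = P(C > t)` treating censoring (event
#' code 0) as the event and the competing-risks events (codes 1, 2) as
#' censorings of the reversed problem. At a timestamp shared by a failure
#' and a censoring, the censoring is processed after the failure, so both
#' subjects sit in the censoring risk set and `G(Ti-)` excludes censorings
#' at `Ti` — the convention matching `G(t-) = P(C >= t)`.
#'
#' @param cohort a [cr_cohort()].
#' @return a `censoring_survival` object of kind `"marginal_km"`. A cohort
#'   with no censored subjects yields `G == 1`.
#' @examples
#' coh <- cr_cohort(c(1, 2, 3), c(1, 0, 2))
#' fit_reverse_km(coh)  # G drops to 0.5 at t = 2
#' @export
fit_reverse_km <- function(cohort) {
  cohort <- as_cohort(cohort)
  sf <- survival::survfit(survival::Surv(cohort$time, cohort$event == 0L) ~ 1,
                          se.fit = FALSE)
  keep <- sf$n.event > 0
  new_censoring_survival("marginal_km",
                         jump_times = sf$time[keep],
                         values = sf$surv[keep],
                         max_time = max(cohort$time),
                         n = cohort_size(cohort))
}

#' Cox proportional-hazards censoring model
#'
#' Fits the censoring hazard `lambda_c(t | x) = lambda_0(t) exp(gamma' x)`
#' by maximum partial likelihood (Breslow tie handling) with event = code 0,
#' and computes the Breslow cumulative baseline hazard, giving
#' `G(t | x) = exp(-Gamma0(t) exp(gamma' x))`. With zero covariate columns
#' the model reduces to `exp(-)` of the Nelson-Aalen estimate of the
#' censoring hazard.
#'
#' @param cohort a [cr_cohort()]; covariate columns must be non-constant.
#' @return a `censoring_survival` object of kind `"cox"` carrying the
#'   coefficient vector and the baseline cumulative-hazard step function.
#' @export
fit_cox_censoring <- function(cohort) {
  cohort <- as_cohort(cohort)
  X <- as.matrix(cohort$covariates)
  p <- ncol(X)
  if (!any(cohort$event == 0L))   # nothing censored: G is identically 1
    return(new_censoring_survival("cox", numeric(0), numeric(0),
                                  gamma = rep(0, p),
                                  covariate_names = colnames(X),
                                  max_time = max(cohort$time),
                                  n = cohort_size(cohort)))
  if (p > 0 && any(apply(X, 2, function(v) diff(range(v)) == 0)))
    crc_fit_error("constant covariate column: censoring Cox model is degenerate")
  if (p > 0) {
    fit <- tryCatch(
      survival::coxph(survival::Surv(cohort$time, cohort$event == 0L) ~ X,
                      ties = "breslow"),
      error = function(e) crc_fit_error(paste("censoring Cox fit failed:",
                                              conditionMessage(e))),
      warning = function(w) crc_fit_error(paste("censoring Cox fit unstable:",
                                                conditionMessage(w)))
    )
    gamma <- unname(coef(fit))
    if (any(!is.finite(gamma)) || any(abs(gamma) > 15))
      crc_fit_error("censoring Cox fit did not converge (possible separation)")
    lp <- drop(X %*% gamma)
  } else {
    gamma <- numeric(0)
    lp <- rep(0, cohort_size(cohort))
  }
  bh <- breslow_baseline(cohort$time, cohort$event == 0L, exp(lp))
  new_censoring_survival("cox",
                         jump_times = bh$time, values = bh$cumhaz,
                         gamma = gamma, covariate_names = colnames(X),
                         max_time = max(cohort$time),
                         n = cohort_size(cohort))
}

# Breslow cumulative baseline hazard for event indicator `status` given
# per-subject relative risks exp(lp). Risk set at u is {time >= u}.
breslow_baseline <- function(time, status, rr) {
  ord <- order(time)
  time_o <- time[ord]; status_o <- status[ord]; rr_o <- rr[ord]
  # total risk mass of {time >= u} for u at each sorted time
  denom_at <- rev(cumsum(rev(rr_o)))
  ev_times <- unique(time_o[status_o])
  if (!length(ev_times))
    return(list(time = numeric(0), cumhaz = numeric(0)))
  idx <- match(ev_times, time_o)  # first position of each tied block
  d <- vapply(ev_times, function(u) sum(status_o & time_o == u), numeric(1))
  list(time = ev_times, cumhaz = cumsum(d / denom_at[idx]))
}

# Cumulative censoring hazard -log G at arbitrary times (baseline scale for
# "cox", marginal scale for "marginal_km").
cens_cumhaz_at <- function(model, times, side = c("right", "left")) {
  side <- match.arg(side)
  if (model$kind == "marginal_km") {
    g <- step_eval(times, model$jump_times, model$values, init = 1, side = side)
    -log(g)
  } else {
    step_eval(times, model$jump_times, model$values, init = 0, side = side)
  }
}

cens_explp <- function(model, X) {
  if (model$kind == "marginal_km") return(rep(1, nrow(X)))
  p <- length(model$gamma)
  if (p == 0) return(rep(1, nrow(X)))
  X <- as.matrix(X)
  if (ncol(X) != p)
    crc_validation_error("covariate columns do not match the censoring model")
  exp(drop(X %*% model$gamma))
}

#' Evaluate a fitted censoring model
#'
#' Evaluates `G(t | x)` (right-continuous) or the left limit `G(t- | x)` —
#' the value of the step function immediately before `t` — at a vector of
#' times. Evaluations beyond the largest observed follow-up use the last
#' value (flat extension) with a warning.
#'
#' @param model a fitted `censoring_survival`.
#' @param times nonnegative evaluation times.
#' @param x covariate row (numeric vector) for Cox models; ignored by the
#'   marginal model.
#' @param side `"right"` for `G(t | x)`, `"left"` for `G(t- | x)`.
#' @return numeric vector of survival probabilities in `(0, 1]` (possibly 0
#'   beyond the last censoring time when the largest observation is
#'   censored).
#' @export
censoring_survival_at <- function(model, times, x = NULL,
                                  side = c("right", "left")) {
  side <- match.arg(side)
  if (any(times < 0)) crc_validation_error("evaluation times must be >= 0")
  if (any(times > model$max_time))
    warning("censoring survival evaluated beyond the largest observed time; ",
            "using flat extension", call. = FALSE)
  H <- cens_cumhaz_at(model, times, side)
  if (model$kind == "cox" && length(model$gamma)) {
    if (is.null(x)) crc_validation_error("x is required for a Cox censoring model")
    H <- H * cens_explp(model, matrix(as.numeric(x), nrow = 1))
  }
  exp(-H)
}

#' Serialize a censoring model to JSON
#'
#' Jump times, values and coefficients in a plain JSON object, for
#' reproducibility records.
#'
#' @param model a `censoring_survival`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
censoring_model_json <- function(model, path = NULL) {
  obj <- list(kind = model$kind, jump_times = model$jump_times,
              values = model$values, gamma = model$gamma,
              covariate_names = model$covariate_names,
              max_time = model$max_time, n = model$n)
  if (is.null(path))
    jsonlite::toJSON(obj, digits = NA, null = "null")
  else {
    jsonlite::write_json(obj, path, digits = NA, null = "null")
    invisible(path)
  }
}

#' @export
print.censoring_survival <- function(x, ...) {
  cat(sprintf("<censoring_survival> kind = %s, %d jump(s), fitted on n = %d\n",
              x$kind, length(x$jump_times), x$n))
  if (x$kind == "cox" && length(x$gamma))
    cat("  gamma:", paste(sprintf("%s = %.4f",
                                  x$covariate_names %||% paste0("x", seq_along(x$gamma)),
                                  x$gamma), collapse = ", "), "\n")
  invisible(x)
}
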