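#' Time-dependent AUC for competing-risks data
#'
#' Discrimination of case/control status at a fixed horizon `t`: the
#' (IPCW-weighted) probability that a randomly drawn case carries a higher
#' prediction than a randomly drawn control. Cases are, by default,
#' cumulative: subjects with an observed event of the analysed cause by `t`
#' (`Ti <= t`, `Di = cause`); with `case_definition = "incident"` only
#' subjects failing exactly at `t` are cases, the definition under which the
#' truncated concordance is a weighted average of AUCs over event times.
#' Two control definitions are supported: `"event_free"` (`Ti > t`) and
#' `"event_free_or_competing"` (`Ti > t` or a competing event), the latter
#' matching the comparability rule of the concordance index.
#'
#' Under censoring, case and competing-control observations are weighted by
#' `1/G(Ti- | Xi)` and event-free controls by `1/G(t | Xj)` under the
#' supplied censoring working model; on uncensored data all weights are 1.
#'
#' @inheritParams concordance_ipcw
#' @param control_definition `"event_free_or_competing"` (default) or
#'   `"event_free"`.
#' @param case_definition `"cumulative"` (default) or `"incident"`.
#' @return a single number in `[0, 1]`.
#' @export
timedep_auc <- function(cohort, predictions, t, cause = 1,
                        control_definition = c("event_free_or_competing",
                                               "event_free"),
                        censoring_model = NULL,
                        tie_handling = "strict",
                        case_definition = c("cumulative", "incident")) {
  control_definition <- match.arg(control_definition)
  case_definition <- match.arg(case_definition)
  cohort <- as_cohort(cohort)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    crc_validation_error("t must be a single positive number")
  M <- resolve_predictions(predictions, cohort, t)
  ev <- relabel_cause(cohort$event, cause)
  time <- cohort$time

  cases <- if (case_definition == "cumulative") ev == 1L & time <= t
           else ev == 1L & time == t
  controls_free <- time > t
  controls_comp <- if (control_definition == "event_free_or_competing")
    ev == 2L & time <= t else rep(FALSE, length(time))
  controls <- controls_free | controls_comp
  if (!any(cases) || !any(controls))
    crc_undefined_estimate("no cases or no controls at this horizon")

  if (any(cohort$event == 0L)) {
    if (is.null(censoring_model)) censoring_model <- fit_reverse_km(cohort)
    elp <- cens_explp(censoring_model, as.matrix(cohort$covariates))
    Hm <- cens_cumhaz_at(censoring_model, time, "left")
    Ht <- cens_cumhaz_at(censoring_model, t, "right")
    w <- rep(0, length(time))
    w[cases] <- 1 / exp(-Hm[cases] * elp[cases])
    w[controls_free] <- 1 / exp(-Ht * elp[controls_free])
    w[controls_comp] <- 1 / exp(-Hm[controls_comp] * elp[controls_comp])
    if (any(!is.finite(w[cases | controls])))
      crc_precondition_error("censoring survival reaches 0 before t; positivity fails")
  } else {
    w <- rep(1, length(time))
  }

  mi <- M[cases]; mj <- M[controls]
  wi <- w[cases]; wj <- w[controls]
  conc <- outer(mi, mj, ">") + tie_weight(tie_handling) * outer(mi, mj, "==")
  sum((wi %o% wj) * conc) / sum(wi %o% wj)
}
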