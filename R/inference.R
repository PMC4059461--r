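#' Asymptotic standard error for the KM-weighted IPCW concordance
#'
#' Influence-function-based (plug-in) estimate of the asymptotic variance of
#' the IPCW concordance under independent censoring, i.e. with marginal
#' reverse Kaplan-Meier weights. The estimated per-subject influence
#' contribution has two parts: the projection of the weighted pair sums
#' (a V-statistic of order 2) and the propagation of the estimated
#' Kaplan-Meier censoring weights through their martingale representation.
#' The standard error is `sqrt(sum(IF_i^2)) / n` and the confidence interval
#' is the Wald interval clipped to `[0, 1]`.
#'
#' The estimator is defined only for the marginal-KM working model; for
#' Cox-weighted or naive estimators use [bootstrap_ci()].
#'
#' @inheritParams concordance_naive
#' @param level confidence level.
#' @param estimator must be `"ipcw_km"`.
#' @return a `cr_concordance` object (the KM-IPCW estimate) with `se`,
#'   `ci`, `ci_level` and `ci_method = "asymptotic_wald"` filled in.
#' @export
asymptotic_se_km <- function(cohort, predictions, t, cause = 1,
                             tie_handling = "strict", level = 0.95,
                             estimator = "ipcw_km") {
  if (!identical(estimator, "ipcw_km"))
    crc_unsupported_method("asymptotic variance is available for the marginal-KM IPCW estimator only; use bootstrap_ci() for naive or Cox-weighted estimators")
  cohort <- as_cohort(cohort)
  n <- cohort_size(cohort)
  M <- resolve_predictions(predictions, cohort, t)
  model <- fit_reverse_km(cohort)
  est <- concordance_ipcw(cohort, M, t, cause, censoring_model = model,
                          tie_handling = tie_handling, weight_floor = 0)

  ev <- relabel_cause(cohort$event, cause)
  time <- cohort$time
  n1 <- as.numeric(time <= t & ev == 1L)
  tw <- tie_weight(tie_handling)
  Q <- outer(M, M, ">") * 1
  if (tw > 0) { Q <- Q + tw * outer(M, M, "=="); diag(Q) <- 0 }

  # marginal-KM weights are column-constant: W1[i, j] = G(Ti-) G(Ti),
  # W2[i, j] = G(Ti-) G(Tj-), so the weighted kernels are row/column
  # rescalings of the comparability indicators
  gm <- exp(-cens_cumhaz_at(model, time, "left"))    # G(Ti-)
  gr <- exp(-cens_cumhaz_at(model, time, "right"))   # G(Ti)
  # entries with n1_i = 0 (or competing events past the support of G) never
  # enter the sums; zero them before 0/0 can arise
  u1 <- ifelse(n1 > 0, n1 / (gm * gr), 0)
  ua <- ifelse(n1 > 0, n1 / gm, 0)
  ub <- ifelse(ev == 2L & gm > 0, 1 / gm, 0)
  KA <- outer(time, time, "<") * u1                  # rows scaled
  KB <- outer(time, time, ">=") * outer(ua, ub)
  h <- (KA + KB) * Q            # numerator kernel
  g <- KA + KB                  # denominator kernel
  V <- sum(h) / n^2
  W <- sum(g) / n^2
  C <- V / W

  # V-statistic projections
  PV <- (rowSums(h) + colSums(h)) / n - 2 * V
  PW <- (rowSums(g) + colSums(g)) / n - 2 * W

  # KM weight propagation: relative influence of subject k on G at s is
  # -L_k(s), L_k(s) = 1{Tk <= s, Dk = 0}/H(Tk) - J(min(s, Tk)) with
  # H(u) = P(Tobs >= u) and J accumulating dLambda_c(u)/H(u). Only products
  # of the L matrices with fixed vectors are needed; they reduce to sorted
  # prefix sums (km_influence_products), so no n x n influence matrix is
  # formed.
  L <- km_influence_products(cohort)
  ra_h <- rowSums(KA * Q); rb_h <- rowSums(KB * Q); cb_h <- colSums(KB * Q)
  ra_g <- rowSums(KA);     rb_g <- rowSums(KB);     cb_g <- colSums(KB)
  DV <- (L$minus(ra_h + rb_h + cb_h) + L$right(ra_h)) / n^2
  DW <- (L$minus(ra_g + rb_g + cb_g) + L$right(ra_g)) / n^2

  IF <- (PV + DV - C * (PW + DW)) / W
  se <- sqrt(sum(IF^2)) / n
  z <- qnorm(1 - (1 - level) / 2)
  est$se <- se
  est$ci <- c(max(0, est$value - z * se), min(1, est$value + z * se))
  est$ci_level <- level
  est$ci_method <- "asymptotic_wald"
  est
}

# Fast products v -> L v of the Kaplan-Meier relative-influence matrices
# Lright[k, i] = L_k(Ti) and Lminus[k, i] = L_k(Ti-) with a fixed vector.
# Writing L_k(s) = 1{Tk <= s}(ck - J(Tk)) - 1{s < Tk} J(s-or-s^-), the
# products decompose into prefix/suffix sums over the time ordering and
# cost O(n log n) instead of O(n^2) storage.
km_influence_products <- function(cohort) {
  time <- cohort$time
  cens <- cohort$event == 0L
  n <- length(time)
  sorted_time <- sort(time)
  H_at <- function(u) 1 - findInterval(u, sorted_time, left.open = TRUE) / n
  uc <- sort(unique(time[cens]))
  if (length(uc)) {
    dc <- as.numeric(table(match(time[cens], uc)))
    Jstep <- cumsum(dc / (n * H_at(uc)^2))
  } else {
    Jstep <- numeric(0)
  }
  Jr_s <- step_eval(time, uc, Jstep, init = 0, side = "right")  # J(Ti)
  Jl_s <- step_eval(time, uc, Jstep, init = 0, side = "left")   # J(Ti-)
  ck <- ifelse(cens, 1 / H_at(time), 0)
  coefk <- ck - Jr_s                      # ck - J(Tk)
  ord <- order(time)
  c_lt <- findInterval(time, sorted_time, left.open = TRUE)  # #{Ti < Tk}
  c_le <- findInterval(time, sorted_time)                    # #{Ti <= Tk}
  prefix <- function(v) c(0, cumsum(v[ord]))
  list(
    right = function(v) {
      pv <- prefix(v); pjv <- prefix(Jr_s * v)
      coefk * (pv[n + 1L] - pv[c_lt + 1L]) - pjv[c_lt + 1L]
    },
    minus = function(v) {
      pv <- prefix(v); pjv <- prefix(Jl_s * v)
      coefk * (pv[n + 1L] - pv[c_le + 1L]) - pjv[c_le + 1L]
    }
  )
}

# Dense-matrix construction of the same influence matrices; reference
# implementation kept for testing km_influence_products at small n.
km_relative_influence <- function(cohort) {
  time <- cohort$time
  cens <- cohort$event == 0L
  n <- length(time)
  sorted_time <- sort(time)
  # H(u) = P(Tobs >= u) = 1 - #{Tobs < u}/n
  H_at <- function(u) 1 - findInterval(u, sorted_time, left.open = TRUE) / n
  uc <- sort(unique(time[cens]))
  if (length(uc)) {
    dc <- as.numeric(table(match(time[cens], uc)))
    Huc <- H_at(uc)
    Jstep <- cumsum(dc / (n * Huc^2))
  } else {
    Jstep <- numeric(0)
  }
  Jr <- function(s) step_eval(s, uc, Jstep, init = 0, side = "right")
  Jl <- function(s) step_eval(s, uc, Jstep, init = 0, side = "left")
  ck <- ifelse(cens, 1 / H_at(time), 0)
  JrT <- Jr(time)          # J(Tk)
  Jr_s <- Jr(time)         # J at eval points (same grid)
  Jl_s <- Jl(time)
  le <- outer(time, time, "<=")   # [k, i]: Tk <= Ti
  lt <- outer(time, time, "<")    # [k, i]: Tk <  Ti
  Lright <- le * ck - (le * JrT + (!le) * rep(Jr_s, each = n))
  Lminus <- lt * ck - (lt * JrT + (!lt) * rep(Jl_s, each = n))
  list(Lright = Lright, Lminus = Lminus)
}

# Exact leave-one-out (jackknife) standard error; independent check of the
# influence-function formula at moderate n.
jackknife_se <- function(cohort, predictions, t, cause = 1,
                         tie_handling = "strict",
                         estimator = c("ipcw_km", "naive", "ipcw_cox")) {
  estimator <- match.arg(estimator)
  cohort <- as_cohort(cohort)
  M <- resolve_predictions(predictions, cohort, t)
  n <- cohort_size(cohort)
  fit_one <- function(idx) {
    sub <- cr_cohort(cohort$time[idx], cohort$event[idx],
                     cohort$covariates[idx, , drop = FALSE])
    switch(estimator,
           naive = concordance_naive(sub, M[idx], t, cause, tie_handling),
           ipcw_km = concordance_ipcw(sub, M[idx], t, cause,
                                      censoring_model = fit_reverse_km(sub),
                                      tie_handling = tie_handling,
                                      weight_floor = 0),
           ipcw_cox = concordance_ipcw(sub, M[idx], t, cause,
                                       censoring_model = fit_cox_censoring(sub),
                                       tie_handling = tie_handling,
                                       weight_floor = 0))$value
  }
  loo <- vapply(seq_len(n), function(k) fit_one(setdiff(seq_len(n), k)),
                numeric(1))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (rows) with replacement, refits the censoring working
#' model inside each resample so that its sampling variability is
#' propagated, recomputes the chosen estimator, and returns the percentile
#' interval and the standard deviation of the resampled estimates. A
#' resample with no evaluable pairs is redrawn, up to a retry cap of 100
#' redraws in total; redraws are counted in the result.
#'
#' @inheritParams concordance_naive
#' @param estimator `"ipcw_km"`, `"ipcw_cox"` or `"naive"`.
#' @param n_boot number of bootstrap resamples; must be at least
#'   `2 / (1 - level)` so the percentile at that level is estimable.
#' @param level confidence level.
#' @param seed integer seed making the interval reproducible; the caller's
#'   RNG state is restored afterwards.
#' @return a `cr_concordance` object (the full-sample estimate) with `se`,
#'   `ci`, `ci_level`, `ci_method = "percentile_bootstrap"`, `n_boot` and
#'   `n_redraws` filled in.
#' @export
bootstrap_ci <- function(cohort, predictions, t, cause = 1,
                         estimator = c("ipcw_km", "ipcw_cox", "naive"),
                         n_boot = 500, level = 0.95, seed = NULL,
                         tie_handling = "strict") {
  estimator <- match.arg(estimator)
  cohort <- as_cohort(cohort)
  if (n_boot < 2 / (1 - level))
    crc_precondition_error(sprintf("n_boot must be at least %g for level %g",
                                   ceiling(2 / (1 - level)), level))
  M <- resolve_predictions(predictions, cohort, t)
  n <- cohort_size(cohort)
  point <- estimate_once(cohort, M, t, cause, estimator, tie_handling)

  boot_one <- function() {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- cr_cohort(cohort$time[idx], cohort$event[idx],
                     cohort$covariates[idx, , drop = FALSE])
    estimate_once(sub, M[idx], t, cause, estimator, tie_handling)$value
  }
  run <- function() {
    vals <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        v <- tryCatch(boot_one(), crcindex_error = function(e) NA_real_)
        if (!is.na(v)) break
        redraws <- redraws + 1L
        if (redraws > 100L)
          crc_fit_error("more than 100 degenerate bootstrap resamples")
      }
      vals[b] <- v
    }
    list(vals = vals, redraws = redraws)
  }
  res <- with_seed(seed, run())
  alpha <- 1 - level
  ci <- unname(quantile(res$vals, c(alpha / 2, 1 - alpha / 2)))
  if (point$value < ci[1] || point$value > ci[2])
    warning("percentile interval does not contain the point estimate ",
            "(degenerate resamples)", call. = FALSE)
  point$se <- sd(res$vals)
  point$ci <- ci
  point$ci_level <- level
  point$ci_method <- "percentile_bootstrap"
  point$n_boot <- n_boot
  point$n_redraws <- res$redraws
  point$seed <- seed
  point
}

# Single estimator evaluation used by the bootstrap and study loops; the
# raw estimator is computed without weight flooring.
estimate_once <- function(cohort, M, t, cause, estimator, tie_handling) {
  switch(estimator,
         naive = concordance_naive(cohort, M, t, cause, tie_handling),
         ipcw_km = concordance_ipcw(cohort, M, t, cause,
                                    censoring_model = fit_reverse_km(cohort),
                                    tie_handling = tie_handling,
                                    weight_floor = 0),
         ipcw_cox = concordance_ipcw(cohort, M, t, cause,
                                     censoring_model = fit_cox_censoring(cohort),
                                     tie_handling = tie_handling,
                                     weight_floor = 0))
}
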