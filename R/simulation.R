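#' Cause-specific hazards simulation scenario
#'
#' Generator parameters for competing-risks data with a single standard
#' normal marker `X` and constant (exponential) cause-specific hazards
#' `lambda_1(t | X) = lambda01 exp(beta1 X)` and
#' `lambda_2(t | X) = lambda02 exp(beta2 X)`; censoring times follow a third
#' Cox-exponential model `lambda_c(t | X) = lambda0_cens exp(gamma1 X)`.
#' Two named presets are shipped: `CR1` (`lambda01 = 1`, `lambda02 = 2`,
#' `beta1 = beta2 = 1`) and `CR2` (`lambda01 = 1`, `lambda02 = 0.5`,
#' `beta1 = 2`, `beta2 = -1`).
#'
#' @param preset `"CR1"`, `"CR2"`, or `NULL` for explicit parameters.
#' @param lambda01,lambda02 positive baseline cause-specific hazards.
#' @param beta1,beta2 cause-specific log hazard ratios of the marker.
#' @param gamma1 censoring log hazard ratio (0 = independent censoring).
#' @param lambda0_cens baseline censoring hazard; 0 disables censoring.
#' @return an object of class `sim_scenario`.
#' @examples
#' sim_scenario("CR1")
#' sim_scenario(lambda01 = 1, lambda02 = 0.5, beta1 = 2, beta2 = -1)
#' @export
sim_scenario <- function(preset = NULL, lambda01 = NULL, lambda02 = NULL,
                         beta1 = NULL, beta2 = NULL, gamma1 = 0,
                         lambda0_cens = 0) {
  presets <- list(
    CR1 = list(lambda01 = 1, lambda02 = 2, beta1 = 1, beta2 = 1),
    CR2 = list(lambda01 = 1, lambda02 = 0.5, beta1 = 2, beta2 = -1)
  )
  if (!is.null(preset)) {
    if (!preset %in% names(presets))
      crc_config_error(sprintf("unknown preset '%s'", preset))
    p <- presets[[preset]]
    lambda01 <- lambda01 %||% p$lambda01
    lambda02 <- lambda02 %||% p$lambda02
    beta1 <- beta1 %||% p$beta1
    beta2 <- beta2 %||% p$beta2
  }
  if (is.null(lambda01) || is.null(lambda02) || is.null(beta1) || is.null(beta2))
    crc_config_error("lambda01, lambda02, beta1 and beta2 must all be set")
  if (lambda01 <= 0 || lambda02 <= 0)
    crc_validation_error("baseline hazards must be positive")
  if (lambda0_cens < 0)
    crc_validation_error("lambda0_cens must be nonnegative")
  structure(list(preset = preset, lambda01 = lambda01, lambda02 = lambda02,
                 beta1 = beta1, beta2 = beta2, gamma1 = gamma1,
                 lambda0_cens = lambda0_cens),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario>%s lambda01 = %g, lambda02 = %g, beta1 = %g, beta2 = %g\n",
              if (!is.null(x$preset)) paste0(" [", x$preset, "]") else "",
              x$lambda01, x$lambda02, x$beta1, x$beta2))
  cat(sprintf("  censoring: lambda0_cens = %g, gamma1 = %g\n",
              x$lambda0_cens, x$gamma1))
  invisible(x)
}

# cause-specific rates at marker value x
scenario_rates <- function(scenario, x) {
  list(l1 = scenario$lambda01 * exp(scenario$beta1 * x),
       l2 = scenario$lambda02 * exp(scenario$beta2 * x))
}

#' Simulate uncensored competing-risks data
#'
#' Draws `X ~ N(0, 1)` and latent exponential times
#' `T1 ~ Exp(lambda01 exp(beta1 X))`, `T2 ~ Exp(lambda02 exp(beta2 X))`,
#' sets `T = min(T1, T2)` and `D = 1` iff `T1 < T2`, else 2. The marker,
#' cause-1 and cause-2 streams use separate substream seeds derived from
#' `seed`, so each component is independently reproducible.
#'
#' @param scenario a [sim_scenario()].
#' @param n sample size (>= 2).
#' @param seed optional integer seed; `NULL` draws from the current stream.
#' @return a [cr_sample()] with the marker as covariate column `x`.
#' @export
simulate_uncensored <- function(scenario, n, seed = NULL) {
  draw <- function(key, fn) {
    if (is.null(seed)) fn() else with_seed(derive_seed(seed, key), fn())
  }
  x <- draw(1L, function() rnorm(n))
  r <- scenario_rates(scenario, x)
  t1 <- draw(2L, function() rexp(n)) / r$l1
  t2 <- draw(3L, function() rexp(n)) / r$l2
  cr_sample(time = pmin(t1, t2), cause = ifelse(t1 < t2, 1L, 2L),
            covariates = data.frame(x = x))
}

#' Apply random right-censoring to an uncensored sample
#'
#' Draws `C ~ Exp(lambda0_cens exp(gamma1 X))` and returns the censored
#' cohort with `Tobs = min(T, C)` and event code 0 when `C < T`. With
#' `lambda0_cens = 0` the cohort equals the sample (no censoring).
#'
#' @param sample a [cr_sample()] whose first covariate column is the marker.
#' @param scenario a [sim_scenario()] providing `lambda0_cens` and `gamma1`.
#' @param seed optional integer seed for the censoring stream.
#' @return a [cr_cohort()].
#' @export
apply_censoring <- function(sample, scenario, seed = NULL) {
  sample <- as_cohort(sample)
  n <- cohort_size(sample)
  if (scenario$lambda0_cens == 0)
    return(cr_cohort(sample$time, sample$event, sample$covariates, sample$id))
  if (!ncol(sample$covariates))
    crc_validation_error("sample has no covariate column to drive covariate-dependent censoring")
  x <- sample$covariates[[1]]
  rate <- scenario$lambda0_cens * exp(scenario$gamma1 * x)
  cens <- if (is.null(seed)) rexp(n) / rate
          else with_seed(derive_seed(seed, 4L), rexp(n)) / rate
  obs <- pmin(sample$time, cens)
  ev <- ifelse(sample$time <= cens, sample$event, 0L)
  cr_cohort(obs, ev, sample$covariates, sample$id)
}

# Gauss-Hermite rule transformed for expectations over a standard normal:
# E f(X) ~ sum(w * f(z)).
gh_rule <- function(order = 64) {
  gh <- pracma::gaussHermite(order)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Quantile of the marginal event-time distribution
#'
#' Solves `P(T <= t) = p` for the uncensored event time
#' `T = min(T1, T2)`. The quadrature method evaluates
#' `P(T > t) = E_X exp(-(lambda1(X) + lambda2(X)) t)` by Gauss-Hermite
#' integration and root-finds; the MC method takes the empirical quantile
#' of a simulated sample.
#'
#' @param scenario a [sim_scenario()].
#' @param p probability in (0, 1).
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param mc_size sample size for the MC method.
#' @param seed seed for the MC method.
#' @param gh_order Gauss-Hermite order.
#' @return the quantile `t`.
#' @export
marginal_quantile <- function(scenario, p, method = c("quadrature", "mc"),
                              mc_size = 100000, seed = NULL, gh_order = 64) {
  method <- match.arg(method)
  if (p <= 0 || p >= 1) crc_validation_error("p must be in (0, 1)")
  if (method == "mc") {
    s <- simulate_uncensored(scenario, mc_size, seed)
    return(unname(quantile(s$time, p)))
  }
  gh <- gh_rule(gh_order)
  r <- scenario_rates(scenario, gh$z)
  rt <- r$l1 + r$l2
  surv <- function(t) sum(gh$w * exp(-rt * t))
  upper <- 1
  while (surv(upper) > 1 - p && upper < 1e8) upper <- upper * 2
  uniroot(function(t) surv(t) - (1 - p), c(0, upper), tol = 1e-12)$root
}

#' Calibrate the baseline censoring hazard to a target censoring rate
#'
#' Finds `lambda0_cens` such that the expected proportion of right-censored
#' observations among those observed before `t`, `P(D = 0 | Tobs < t)`,
#' equals `target_fraction`. The default method bisects on
#' `log lambda0_cens` against a Monte Carlo estimate that reuses one set of
#' latent draws across bisection steps (common random numbers), making the
#' objective monotone; `method = "quadrature"` root-finds on the
#' Gauss-Hermite evaluation of the same conditional probability.
#'
#' @param scenario a [sim_scenario()] (its own `lambda0_cens` is ignored).
#' @param t horizon defining "observed before t".
#' @param target_fraction target in `[0, 1)`; 0 returns 0.
#' @param mc_size Monte Carlo size for the default method.
#' @param seed seed for the Monte Carlo draws.
#' @param tol tolerance on the achieved fraction.
#' @param method `"mc"` (default) or `"quadrature"`.
#' @param gh_order Gauss-Hermite order for the quadrature method.
#' @return the calibrated `lambda0_cens`.
#' @export
calibrate_censoring_rate <- function(scenario, t, target_fraction,
                                     mc_size = 200000, seed = NULL,
                                     tol = 0.005, method = c("mc", "quadrature"),
                                     gh_order = 64) {
  method <- match.arg(method)
  if (t <= 0) crc_validation_error("t must be positive")
  if (target_fraction < 0 || target_fraction >= 1)
    crc_validation_error("target_fraction must be in [0, 1)")
  if (target_fraction == 0) return(0)

  if (method == "quadrature") {
    gh <- gh_rule(gh_order)
    r <- scenario_rates(scenario, gh$z)
    rt <- r$l1 + r$l2
    ecg <- exp(scenario$gamma1 * gh$z)
    frac <- function(l0) {
      lc <- l0 * ecg
      num <- sum(gh$w * lc / (lc + rt) * (1 - exp(-(lc + rt) * t)))
      den <- sum(gh$w * (1 - exp(-(lc + rt) * t)))
      num / den
    }
  } else {
    s <- simulate_uncensored(scenario, mc_size,
                             if (is.null(seed)) NULL else derive_seed(seed, 11L))
    x <- s$covariates$x
    e_cens <- if (is.null(seed)) rexp(mc_size)
              else with_seed(derive_seed(seed, 12L), rexp(mc_size))
    base_cens <- e_cens / exp(scenario$gamma1 * x)  # C = base_cens / l0
    frac <- function(l0) {
      cens_time <- base_cens / l0
      before <- pmin(s$time, cens_time) < t
      sum(cens_time < s$time & before) / sum(before)
    }
  }

  lo <- 1e-8; hi <- 1
  expand <- 0
  while (frac(hi) < target_fraction) {
    hi <- hi * 4
    if ((expand <- expand + 1) > 30)
      crc_fit_error("target censoring fraction unattainable (bracket expansion cap)")
  }
  while (frac(lo) > target_fraction) {
    lo <- lo / 4
    if ((expand <- expand + 1) > 60)
      crc_fit_error("target censoring fraction unattainable (bracket expansion cap)")
  }
  for (iter in 1:200) {
    mid <- sqrt(lo * hi)
    f <- frac(mid)
    if (abs(f - target_fraction) <= tol && iter > 4) return(mid)
    if (f < target_fraction) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) return(mid)
  }
  mid
}

#' True truncated concordance of a scenario
#'
#' The population value of the truncated cause-1 concordance for the
#' generator's marker (`M(t, X) = X`), computed either by Monte Carlo
#' (generate a large uncensored sample and apply
#' [concordance_exact_uncensored()]) or by quadrature. The quadrature route
#' uses the closed-form inner time integral for exponential cause-specific
#' hazards, `int_0^t (1 - F1(s | xj)) dF1(s | xi)`, and evaluates the outer
#' expectation over the pair of markers on the probability scale
#' `(u, v) = (Phi(xi), Phi(xj))` with tensor Gauss-Legendre rules — the
#' denominator over the unit square, the numerator over the triangle
#' `v < u` where the ordering indicator equals 1, so no discontinuity is
#' ever quadratured across and convergence is fast in the rule order.
#'
#' @param scenario a [sim_scenario()].
#' @param t truncation horizon.
#' @param method `"quadrature"` (default) or `"monte_carlo"`.
#' @param mc_size Monte Carlo sample size (default 100000).
#' @param seed seed for the Monte Carlo method.
#' @param quad_order Gauss-Legendre order per axis.
#' @return an object of class `true_concordance` with elements `value`,
#'   `horizon`, `method` and the size/order used.
#' @export
true_concordance <- function(scenario, t, method = c("quadrature", "monte_carlo"),
                             mc_size = 100000, seed = NULL, quad_order = 150) {
  method <- match.arg(method)
  if (t <= 0) crc_validation_error("t must be positive")
  if (method == "monte_carlo") {
    s <- simulate_uncensored(scenario, mc_size,
                             if (is.null(seed)) NULL else derive_seed(seed, 7L))
    value <- concordance_exact_uncensored(s, s$covariates$x, t)$value
    out <- list(value = value, horizon = t, method = "monte_carlo",
                mc_size = mc_size)
  } else {
    # inner(i, j) = l1_i [ (1 - p1_j)(1 - e^{-r_i t})/r_i
    #                      + p1_j (1 - e^{-(r_i + r_j) t})/(r_i + r_j) ]
    inner_fun <- function(xi, xj) {
      ri <- scenario_rates(scenario, xi)
      rj <- scenario_rates(scenario, xj)
      rti <- ri$l1 + ri$l2
      rtj <- rj$l1 + rj$l2
      p1j <- rj$l1 / rtj
      term1 <- outer((1 - exp(-rti * t)) / rti, 1 - p1j)
      rsum <- outer(rti, rtj, "+")
      term2 <- (1 - exp(-rsum * t)) / rsum * rep(p1j, each = length(xi))
      ri$l1 * (term1 + term2)
    }
    g <- pracma::gaussLegendre(quad_order, 0, 1)
    x <- qnorm(g$x)
    den <- sum(outer(g$w, g$w) * inner_fun(x, x))
    num <- 0
    for (k in seq_along(g$x)) {     # v in (0, u_k): scaled inner rule
      v <- g$x[k] * g$x
      num <- num + g$w[k] * sum(g$x[k] * g$w * inner_fun(x[k], qnorm(v)))
    }
    if (!is.finite(num / den))
      crc_fit_error("quadrature for the true concordance did not converge")
    out <- list(value = num / den, horizon = t, method = "quadrature",
                quad_order = quad_order)
  }
  structure(out, class = "true_concordance")
}

#' @export
print.true_concordance <- function(x, ...) {
  cat(sprintf("<true_concordance> C1(t = %.4g) = %.4f  [%s]\n",
              x$horizon, x$value, x$method))
  invisible(x)
}
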