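# Independent brute-force oracles used across the test files. They share no
# code with the package: the reverse Kaplan-Meier is hand-rolled from the
# product-limit definition and all pair sums are explicit double loops.

# Product-limit estimate of G(t) = P(C > t) treating code 0 as the event.
# Returns a function g(t, side) evaluating the step function.
oracle_reverse_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- 1
  jumps <- numeric(0)
  vals <- numeric(0)
  for (u in ut) {
    at_risk <- sum(time >= u)
    d <- sum(time == u & event == 0)
    if (d > 0) {
      surv <- surv * (1 - d / at_risk)
      jumps <- c(jumps, u)
      vals <- c(vals, surv)
    }
  }
  function(t, side = "right") {
    keep <- if (side == "right") jumps <= t else jumps < t
    if (!any(keep)) 1 else vals[max(which(keep))]
  }
}

# Exact / naive truncated concordance by full enumeration of ordered pairs.
oracle_concordance <- function(time, event, M, t, tie_w = 0) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] > t) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (!(time[i] < time[j] || event[j] == 2)) next
      den <- den + 1
      if (M[i] > M[j]) num <- num + 1
      else if (M[i] == M[j]) num <- num + tie_w
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# IPCW concordance with marginal reverse-KM weights by full enumeration:
# W1 = G(Ti-) G(Ti), W2 = G(Ti-) G(Tj-).
oracle_ipcw_km <- function(time, event, M, t, tie_w = 0) {
  g <- oracle_reverse_km(time, event)
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] > t) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (time[i] < time[j]) {
        w <- g(time[i], "left") * g(time[i], "right")
      } else if (event[j] == 2) {
        w <- g(time[i], "left") * g(time[j], "left")
      } else next
      den <- den + 1 / w
      if (M[i] > M[j]) num <- num + 1 / w
      else if (M[i] == M[j]) num <- num + tie_w / w
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Small random competing-risks cohorts (possibly censored) for property
# tests; continuous times, so ties have probability zero.
random_cohort <- function(n, cens_prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- rexp(n, rate = 1)
  event <- ifelse(runif(n) < cens_prob, 0L, sample(1:2, n, replace = TRUE))
  if (!any(event == 1L)) event[sample(n, 1)] <- 1L  # keep at least one case
  x <- rnorm(n)
  list(cohort = cr_cohort(time, event, data.frame(x = x)),
       M = x + 0.2 * rnorm(n))
}
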