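test_that("exact uncensored concordance matches hand enumeration", {
  s <- cr_sample(c(1, 2, 3), c(1, 2, 1))
  est <- concordance_exact_uncensored(s, c(0.9, 0.5, 0.4), t = 3)
  # comparable ordered pairs (1,2), (1,3), (3,2); concordant (1,2), (1,3)
  expect_equal(est$value, 2 / 3)
  expect_equal(est$n_pairs, 3)
  # all predictions tied: half-weighting gives exactly 1/2
  expect_equal(concordance_exact_uncensored(s, c(1, 1, 1), t = 3,
                                            tie_handling = "half_weight")$value, 0.5)
  # and strict tie handling counts ties as non-concordant
  expect_equal(concordance_exact_uncensored(s, c(1, 1, 1), t = 3)$value, 0)
  # perfectly anti-concordant marker
  expect_equal(concordance_exact_uncensored(s, c(-0.9, -0.5, -0.4), t = 3)$value,
               1 / 3)
  expect_equal(concordance_exact_uncensored(
    cr_sample(c(1, 2, 3), c(1, 1, 1)), c(1, 2, 3), t = 3)$value, 0)
  expect_error(concordance_exact_uncensored(s, c(1, 2, 3), t = 0.1),
               class = "crcindex_undefined_estimate")
})

test_that("naive estimator keeps censored subjects evaluable as later pair members", {
  coh <- cr_cohort(c(1, 2, 3), c(1, 0, 2))
  est <- concordance_naive(coh, c(0.9, 0.5, 0.4), t = 3)
  expect_equal(est$value, 1)
  expect_equal(est$n_pairs, 2)  # (1,2) and (1,3), both through A
})

test_that("estimators agree with brute-force oracles on random cohorts", {
  for (seed in 1:8) {
    rc <- random_cohort(20, cens_prob = 0.35, seed = seed)
    t <- quantile(rc$cohort$time, 0.7)
    o_naive <- oracle_concordance(rc$cohort$time, rc$cohort$event, rc$M, t)
    o_ipcw <- oracle_ipcw_km(rc$cohort$time, rc$cohort$event, rc$M, t)
    expect_equal(concordance_naive(rc$cohort, rc$M, t)$value, o_naive)
    expect_equal(concordance_ipcw(rc$cohort, rc$M, t, weight_floor = 0)$value,
                 o_ipcw, tolerance = 1e-12)
    # streaming kernel and dense matrix reference agree exactly
    expect_equal(concordance_ipcw(rc$cohort, rc$M, t, weight_floor = 0)$value,
                 crcindex:::concordance_ipcw_dense(rc$cohort, rc$M, t),
                 tolerance = 1e-14)
  }
})

test_that("five-subject IPCW example reproduces the enumerated weighted ratio", {
  coh <- cr_cohort(c(0.5, 1, 1.5, 2, 3), c(1, 0, 2, 1, 2))
  M <- c(0.9, 0.7, 0.8, 0.2, 0.6)
  est <- concordance_ipcw(coh, M, t = 2.5)
  expect_equal(est$value, 9 / 17, tolerance = 1e-14)  # frozen oracle value
  expect_equal(concordance_naive(coh, M, t = 2.5)$value, 2 / 3)
})

test_that("pair weights match the hand-computed two-point KM products", {
  coh <- cr_cohort(c(1, 2, 3, 4), c(1, 0, 1, 2))
  w <- compute_pair_weights(coh, fit_reverse_km(coh))
  # single censoring at 2, risk set {2,3,4}: G = 2/3 from t = 2 on
  expect_equal(w$W1[1, ], rep(1, 4))            # G(1-) G(1) = 1
  expect_equal(w$W1[3, ], rep(4 / 9, 4))        # G(3-) G(3) = (2/3)^2
  expect_equal(w$W2[3, 1], 2 / 3)               # G(3-) G(1-) = 2/3 * 1
  expect_equal(w$W2[4, 3], 4 / 9)               # G(4-) G(3-)
  # uncensored cohort: all weights exactly one
  coh0 <- cr_cohort(c(1, 2, 3), c(1, 2, 1))
  w0 <- compute_pair_weights(coh0, fit_reverse_km(coh0))
  expect_true(all(w0$W1 == 1) && all(w0$W2 == 1))
  # marginal KM weights W1 are constant across j
  expect_true(all(apply(w$W1, 1, function(r) diff(range(r)) == 0)))
})

test_that("weight floor warns and optionally truncates", {
  set.seed(99)
  n <- 60
  tm <- rexp(n)
  ev <- ifelse(runif(n) < 0.6, 0L, 1L)  # heavy censoring drives G low
  ev[which.max(tm)] <- 1L
  coh <- cr_cohort(tm, ev)
  mod <- fit_reverse_km(coh)
  expect_warning(compute_pair_weights(coh, mod, weight_floor = 0.5),
                 "below the floor")
  w <- suppressWarnings(compute_pair_weights(coh, mod, weight_floor = 0.5,
                                             truncate_weights = TRUE))
  expect_gte(min(w$W1), 0.5)
})

test_that("IPCW estimator stays defined up to the largest observation", {
  # largest observation censored: G-hat reaches 0 there, but every weight
  # the estimator evaluates sits at an observed case time where G-hat > 0,
  # so truncating at (or beyond, by flat extension) max follow-up works
  coh <- cr_cohort(c(1, 2, 3), c(1, 1, 0))
  est <- concordance_ipcw(coh, c(3, 2, 1), t = 3)
  expect_equal(est$value, oracle_ipcw_km(coh$time, coh$event, c(3, 2, 1), 3))
  expect_error(concordance_ipcw(coh, c(3, 2, 1), t = 0.5),
               class = "crcindex_undefined_estimate")
})

test_that("concordance is a rank statistic and flips under sign reversal", {
  for (seed in 1:4) {
    rc <- random_cohort(25, seed = seed)
    t <- quantile(rc$cohort$time, 0.75)
    base <- concordance_ipcw(rc$cohort, rc$M, t, weight_floor = 0)$value
    # strictly increasing transform leaves the estimate unchanged
    expect_equal(concordance_ipcw(rc$cohort, exp(3 * rc$M) + 1, t,
                                  weight_floor = 0)$value, base)
    # sign flip maps v to 1 - v on tie-free predictions
    expect_equal(concordance_ipcw(rc$cohort, -rc$M, t,
                                  weight_floor = 0)$value, 1 - base)
    naive <- concordance_naive(rc$cohort, rc$M, t)$value
    expect_equal(concordance_naive(rc$cohort, rank(rc$M), t)$value, naive)
  }
})

test_that("comparable pairs grow with the truncation horizon on uncensored data", {
  set.seed(5)
  s <- cr_sample(rexp(40), sample(1:2, 40, TRUE), data.frame(x = rnorm(40)))
  qs <- quantile(s$time, c(0.3, 0.5, 0.8, 1))
  np <- vapply(qs, function(t)
    concordance_exact_uncensored(s, s$covariates$x, t)$n_pairs, numeric(1))
  expect_true(all(diff(np) >= 0))
})

test_that("cause-2 analysis equals cause-1 after relabelling", {
  for (seed in 1:4) {
    rc <- random_cohort(30, seed = seed)
    t <- quantile(rc$cohort$time, 0.75)
    swapped <- cr_cohort(rc$cohort$time,
                         crcindex:::relabel_cause(rc$cohort$event, 2),
                         rc$cohort$covariates)
    expect_identical(concordance_ipcw(rc$cohort, -rc$M, t, cause = 2,
                                      weight_floor = 0)$value,
                     concordance_ipcw(swapped, -rc$M, t, cause = 1,
                                      weight_floor = 0)$value)
    expect_identical(concordance_naive(rc$cohort, rc$M, t, cause = 2)$value,
                     concordance_naive(swapped, rc$M, t, cause = 1)$value)
  }
})

test_that("survival special case agrees with the survival package concordance", {
  # with no competing events and no truncation, the naive estimator reduces
  # to Harrell's C as computed by survival::concordance
  set.seed(11)
  n <- 80
  tm <- rexp(n)
  ev <- rbinom(n, 1, 0.7)
  if (!any(ev == 1)) ev[1] <- 1
  x <- rnorm(n)
  coh <- cr_cohort(tm, as.integer(ev))
  ours <- concordance_naive(coh, x, t = max(tm) + 1)$value
  theirs <- survival::concordance(survival::Surv(tm, ev) ~ x, reverse = TRUE)
  expect_equal(ours, unname(theirs$concordance), tolerance = 1e-12)
})
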