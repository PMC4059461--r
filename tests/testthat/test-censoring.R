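test_that("reverse Kaplan-Meier reproduces the hand product-limit", {
  coh <- cr_cohort(c(1, 2, 3), c(1, 0, 2))
  g <- fit_reverse_km(coh)
  # single censoring at t = 2 with risk set {2, 3}: G drops to 1/2
  expect_equal(censoring_survival_at(g, c(0.5, 1.9)), c(1, 1))
  expect_equal(censoring_survival_at(g, c(2, 2.5, 3)), c(0.5, 0.5, 0.5))
  expect_equal(censoring_survival_at(g, 2, side = "left"), 1)
  expect_equal(censoring_survival_at(g, 0), 1)
  expect_equal(censoring_survival_at(g, 0, side = "left"), 1)
  # between jumps both sides agree
  expect_equal(censoring_survival_at(g, 2.5, side = "left"),
               censoring_survival_at(g, 2.5, side = "right"))
  # no censoring at all: G identically 1
  g1 <- fit_reverse_km(cr_cohort(c(1, 2, 3), c(1, 2, 1)))
  expect_equal(censoring_survival_at(g1, c(0.5, 3)), c(1, 1))
  # beyond follow-up: flat extension with a warning
  expect_warning(v <- censoring_survival_at(g, 10), "flat extension")
  expect_equal(v, 0.5)
})

test_that("reverse KM agrees with the independent product-limit oracle", {
  for (seed in 1:4) {
    rc <- random_cohort(40, cens_prob = 0.4, seed = seed)
    g <- fit_reverse_km(rc$cohort)
    og <- oracle_reverse_km(rc$cohort$time, rc$cohort$event)
    at <- sort(rc$cohort$time)
    expect_equal(censoring_survival_at(g, at),
                 vapply(at, og, numeric(1)), tolerance = 1e-12)
    expect_equal(censoring_survival_at(g, at, side = "left"),
                 vapply(at, function(u) og(u, "left"), numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("reverse KM converges to the true exponential censoring survival", {
  scen <- sim_scenario("CR1", lambda0_cens = 1.2)
  s <- simulate_uncensored(scen, 5000, seed = 42)
  coh <- apply_censoring(s, scen, 42)
  g <- fit_reverse_km(coh)
  grid <- seq(0.01, quantile(s$time, 0.9), length.out = 60)
  err <- abs(censoring_survival_at(g, grid) - exp(-1.2 * grid))
  expect_lt(max(err), 0.03)
})

test_that("Cox censoring model recovers known coefficients", {
  # censoring independent of the covariate: gamma-hat near 0
  scen0 <- sim_scenario("CR1", gamma1 = 0, lambda0_cens = 1)
  s0 <- simulate_uncensored(scen0, 2000, seed = 7)
  coh0 <- apply_censoring(s0, scen0, 7)
  f0 <- fit_cox_censoring(coh0)
  expect_lt(abs(f0$gamma), 0.1)
  # gamma1 = 1 recovered within 0.15
  scen1 <- sim_scenario("CR1", gamma1 = 1, lambda0_cens = 1)
  s1 <- simulate_uncensored(scen1, 2000, seed = 8)
  coh1 <- apply_censoring(s1, scen1, 8)
  f1 <- fit_cox_censoring(coh1)
  expect_lt(abs(f1$gamma - 1), 0.15)
  # G(t | x) nonincreasing in t at fixed x
  grid <- seq(0, max(coh1$time), length.out = 50)
  for (x in c(-1, 0, 1.5))
    expect_true(all(diff(censoring_survival_at(f1, grid, x = x)) <= 1e-12))
  expect_error(fit_cox_censoring(cr_cohort(c(1, 2, 3), c(1, 0, 2),
                                           data.frame(x = c(1, 1, 1)))),
               class = "crcindex_fit_error")
})

test_that("covariate-free Cox model matches reverse KM closely", {
  scen <- sim_scenario("CR1", lambda0_cens = 1)
  s <- simulate_uncensored(scen, 200, seed = 3)
  coh0 <- apply_censoring(s, scen, 3)
  coh <- cr_cohort(coh0$time, coh0$event)  # drop covariates: p = 0
  km <- fit_reverse_km(coh)
  na <- fit_cox_censoring(coh)             # exp(-Nelson-Aalen)
  # the two estimators only drift apart where the risk set is tiny
  at <- km$jump_times[km$jump_times <= quantile(coh$time, 0.9)]
  expect_lt(max(abs(censoring_survival_at(km, at) -
                    censoring_survival_at(na, at))), 0.02)
})

test_that("fitted censoring models serialize to JSON", {
  coh <- cr_cohort(c(1, 2, 3, 4), c(1, 0, 2, 0), data.frame(x = c(0, 1, -1, 2)))
  js <- jsonlite::fromJSON(censoring_model_json(fit_cox_censoring(coh)))
  expect_equal(js$kind, "cox")
  expect_length(js$gamma, 1)
  js2 <- jsonlite::fromJSON(censoring_model_json(fit_reverse_km(coh)))
  expect_equal(js2$kind, "marginal_km")
  expect_equal(length(js2$jump_times), length(js2$values))
})
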