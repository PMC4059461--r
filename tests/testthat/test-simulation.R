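test_that("scenario presets carry the study parameters", {
  s1 <- sim_scenario("CR1")
  expect_equal(unlist(s1[c("lambda01", "lambda02", "beta1", "beta2")]),
               c(lambda01 = 1, lambda02 = 2, beta1 = 1, beta2 = 1))
  s2 <- sim_scenario("CR2")
  expect_equal(unlist(s2[c("lambda01", "lambda02", "beta1", "beta2")]),
               c(lambda01 = 1, lambda02 = 0.5, beta1 = 2, beta2 = -1))
  expect_error(sim_scenario("CR9"), class = "crcindex_config_error")
  expect_error(sim_scenario(lambda01 = 1), class = "crcindex_config_error")
})

test_that("generator reproduces closed-form cause fractions and means", {
  # CR1: lambda1/(lambda1+lambda2) = 1/3 for every X
  s <- simulate_uncensored(sim_scenario("CR1"), 100000, seed = 1)
  expect_lt(abs(mean(s$event == 1L) - 1 / 3), 0.005)
  # beta1 = beta2 = 0: T ~ Exp(3), mean 1/3
  s0 <- simulate_uncensored(sim_scenario(lambda01 = 1, lambda02 = 2,
                                         beta1 = 0, beta2 = 0), 100000, seed = 2)
  expect_lt(abs(mean(s0$time) - 1 / 3), 0.01)
  # determinism and substream independence
  a <- simulate_uncensored(sim_scenario("CR1"), 50, seed = 7)
  b <- simulate_uncensored(sim_scenario("CR1"), 50, seed = 7)
  expect_identical(a$time, b$time)
  expect_identical(a$event, b$event)
})

test_that("censoring mechanism behaves at its limits and depends on X as set", {
  scen <- sim_scenario("CR1")
  s <- simulate_uncensored(scen, 500, seed = 3)
  expect_identical(apply_censoring(s, scen, 3)$event, s$event)  # rate 0
  scen$lambda0_cens <- 5000
  expect_gt(mean(apply_censoring(s, scen, 3)$event == 0L), 0.97)
  # gamma1 = 1 with hazards flat in X: censoring concentrates on large X
  # (P(censored | X) = e^X / (e^X + 3), increasing); under CR1 itself the
  # event hazards scale identically and the fraction is constant in X
  scen2 <- sim_scenario(lambda01 = 1, lambda02 = 2, beta1 = 0, beta2 = 0,
                        gamma1 = 1, lambda0_cens = 1)
  s2 <- simulate_uncensored(scen2, 10000, seed = 4)
  coh2 <- apply_censoring(s2, scen2, 4)
  expect_gt(cor(coh2$covariates$x, as.numeric(coh2$event == 0L)), 0.05)
})

test_that("marginal quantiles match closed forms and MC agrees with quadrature", {
  flat <- sim_scenario(lambda01 = 1, lambda02 = 2, beta1 = 0, beta2 = 0)
  expect_equal(marginal_quantile(flat, 0.75), -log(0.25) / 3, tolerance = 1e-8)
  cr1 <- sim_scenario("CR1")
  q_quad <- marginal_quantile(cr1, 0.75)
  q_mc <- marginal_quantile(cr1, 0.75, method = "mc", seed = 5)
  expect_lt(abs(q_quad - q_mc), 0.005)
  expect_lt(marginal_quantile(cr1, 0.5), q_quad)
})

test_that("censoring-rate calibration hits its target and is monotone", {
  scen <- sim_scenario("CR1")
  t <- marginal_quantile(scen, 0.75)
  expect_equal(calibrate_censoring_rate(scen, t, 0), 0)
  l25 <- calibrate_censoring_rate(scen, t, 0.25, seed = 6)
  l75 <- calibrate_censoring_rate(scen, t, 0.75, seed = 6)
  expect_gt(l75, l25)
  # re-simulate with a fresh seed: achieved fraction within 0.01
  scen$lambda0_cens <- l25
  s <- simulate_uncensored(scen, 200000, seed = 77)
  coh <- apply_censoring(s, scen, 77)
  before <- coh$time < t
  achieved <- mean(coh$event[before] == 0L)
  expect_lt(abs(achieved - 0.25), 0.01)
  # quadrature route agrees with the MC route
  l25q <- calibrate_censoring_rate(scen, t, 0.25, method = "quadrature")
  expect_lt(abs(l25q / l25 - 1), 0.05)
})

test_that("true concordance: exchangeable null, scale equivariance, MC agreement", {
  # marker unrelated to either hazard: C1 = 1/2 exactly
  null_scen <- sim_scenario(lambda01 = 1, lambda02 = 2, beta1 = 0, beta2 = 0)
  expect_equal(true_concordance(null_scen, 0.5)$value, 0.5, tolerance = 1e-10)
  # rescaling time units rescales t but not the concordance
  cr1 <- sim_scenario("CR1")
  cr1_fast <- sim_scenario(lambda01 = 10, lambda02 = 20, beta1 = 1, beta2 = 1)
  expect_equal(true_concordance(cr1, 0.6)$value,
               true_concordance(cr1_fast, 0.06)$value, tolerance = 1e-10)
  # quadrature order is converged
  q75 <- marginal_quantile(cr1, 0.75)
  expect_equal(true_concordance(cr1, q75, quad_order = 150)$value,
               true_concordance(cr1, q75, quad_order = 250)$value,
               tolerance = 1e-6)
  # Monte Carlo route within 3 MC standard errors of quadrature, both presets
  for (preset in c("CR1", "CR2")) {
    scen <- sim_scenario(preset)
    t <- marginal_quantile(scen, 0.75)
    truth <- true_concordance(scen, t)$value
    reps <- sapply(1:5, function(k)
      true_concordance(scen, t, "monte_carlo", mc_size = 20000, seed = k)$value)
    se <- sd(reps) / sqrt(5)
    expect_lt(abs(mean(reps) - truth), 3 * se + 1e-4)
  }
})
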