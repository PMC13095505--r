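test_that("conditional toxicity probabilities match hand calculations", {
  p <- tox_params(-3, 1.1)
  expect_equal(round(tox_prob_conditional(0, p, 0), 3), 0.047)
  expect_equal(round(tox_prob_conditional(1, p, 0), 3), 0.501)
  expect_equal(tox_prob_conditional(0.3, tox_params(0, -30), 0), 0.5)
  # strictly increasing in dose and in frailty
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(tox_prob_conditional(x, p, 0)) > 0))
  expect_gt(tox_prob_conditional(0.5, p, 1), tox_prob_conditional(0.5, p, 0))
})

test_that("change-point efficacy matches the elicited curve and hinge rule", {
  p <- eff_params(-1, 1.1, -5, -0.1, tau = 0.8)
  expect_equal(round(eff_prob_conditional(0, p, 0), 3), 0.269)
  expect_equal(round(eff_prob_conditional(1, p, 0), 3), 0.712)
  curve <- eff_prob_conditional(default_grid()$std_doses, p, 0)
  expect_equal(round(curve, 3), c(0.269, 0.401, 0.546, 0.683, 0.792, 0.712))
  # below the change point the hinge coefficient is inert
  p2 <- eff_params(-1, 1.1, 99, -0.1, tau = 0.8)
  x <- c(0, 0.3, 0.6, 0.8)
  expect_equal(eff_prob_conditional(x, p2, 0),
               eff_prob_conditional(x, eff_params(-1, 1.1, 0, -0.1, 0.8), 0))
})

test_that("frailty-averaged marginals are exact in degenerate cases", {
  pars <- default_truth()
  # zero frailty equals the conditional
  expect_equal(marginal_prob(0.4, pars, frailty_spec(0), "T"),
               tox_prob_conditional(0.4, pars$tox, 0))
  # symmetric frailty about a zero linear predictor gives exactly 1/2
  sym <- stage_params(tox_params(0, -30), eff_params(0, -30, 0, 0, 0.8))
  for (s in c(0.5, 2))
    expect_equal(marginal_prob(0, sym, frailty_spec(s), "T"), 0.5,
                 tolerance = 1e-12)
  expect_equal(marginal_prob(0, sym, frailty_spec(1.5, "student_t", df = 5),
                             "E"), 0.5, tolerance = 1e-6)
})

test_that("quadrature marginals agree with brute-force Monte Carlo", {
  p <- stage_params(tox_params(-3, 1.1), eff_params(-1, 1.1, -5, -0.1, 0.8))
  fr <- frailty_spec(1)
  set.seed(42)
  eps <- rnorm(1e6, 0, 1)
  for (x in c(0.2, 0.4)) {
    mc <- tox_prob_conditional(x, p$tox, eps)
    se <- sd(mc) / sqrt(length(mc))
    expect_lt(abs(marginal_prob(x, p, fr, "T") - mean(mc)), 3 * se + 1e-6)
  }
})

test_that("joint probabilities normalize, marginalize, and correlate", {
  set.seed(7)
  grid_x <- c(0, 0.3, 0.7, 1)
  worst_sum <- 0; worst_margT <- 0; worst_margE <- 0
  for (i in 1:1000) {
    pars <- stage_params(tox_params(rnorm(1, -2, 2), rnorm(1, 0.5, 1)),
                         eff_params(rnorm(1, -1, 2), rnorm(1, 0.5, 1),
                                    rnorm(1, -2, 2), rnorm(1, 0, 1),
                                    tau = runif(1, 0, 1.4)))
    fr <- frailty_spec(runif(1, 0, 2.5))
    x <- sample(grid_x, 1)
    js <- sapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                 function(y) joint_prob(x, pars, fr, y))
    worst_sum <- max(worst_sum, abs(sum(js) - 1))
    worst_margT <- max(worst_margT,
                       abs(js[2] + js[4] - marginal_prob(x, pars, fr, "T")))
    worst_margE <- max(worst_margE,
                       abs(js[3] + js[4] - marginal_prob(x, pars, fr, "E")))
  }
  expect_lt(worst_sum, 1e-8)
  expect_lt(worst_margT, 1e-10)
  expect_lt(worst_margE, 1e-10)
})

test_that("shared frailty induces positive outcome association", {
  pars <- default_truth()
  fr <- frailty_spec(2)
  for (x in c(0, 0.5, 1)) {
    p11 <- joint_prob(x, pars, fr, c(1, 1))
    expect_gte(p11, marginal_prob(x, pars, fr, "T") *
                 marginal_prob(x, pars, fr, "E") - 1e-12)
  }
  # and with no frailty the joint factorizes exactly
  expect_equal(joint_prob(0.5, pars, frailty_spec(0), c(1, 1)),
               marginal_prob(0.5, pars, frailty_spec(0), "T") *
                 marginal_prob(0.5, pars, frailty_spec(0), "E"),
               tolerance = 1e-12)
  # MC oracle for the correlated case
  set.seed(11)
  eps <- rnorm(2e5, 0, 2)
  pT <- tox_prob_conditional(0.5, pars$tox, eps)
  pE <- eff_prob_conditional(0.5, pars$eff, eps)
  mc <- mean(pT * pE)
  se <- sd(pT * pE) / sqrt(length(eps))
  expect_lt(abs(joint_prob(0.5, pars, fr, c(1, 1)) - mc), 3 * se + 1e-6)
})

test_that("marginal toxicity is nondecreasing in dose for random settings", {
  set.seed(3)
  x <- seq(0, 1, length.out = 41)
  for (i in 1:30) {
    pars <- stage_params(tox_params(rnorm(1, -2, 3), rnorm(1, 0, 1.5)),
                         eff_params(0, 0, 0, 0, 0.8))
    fr <- frailty_spec(runif(1, 0, 3))
    expect_true(all(diff(marginal_prob(x, pars, fr, "T")) >= -1e-12))
  }
})

test_that("model mean utility equals the four-term enumeration", {
  set.seed(9)
  u <- utility_table()
  for (i in 1:20) {
    pars <- stage_params(tox_params(rnorm(1, -2, 2), rnorm(1, 0, 1)),
                         eff_params(rnorm(1, -1, 2), rnorm(1, 0.5, 1),
                                    rnorm(1, -2, 1), rnorm(1, 0, 1),
                                    tau = runif(1, 0.2, 1.2)))
    fr <- frailty_spec(runif(1, 0, 2))
    x <- runif(1)
    manual <- u$u10 * joint_prob(x, pars, fr, c(1, 0)) +
      u$u00 * joint_prob(x, pars, fr, c(0, 0)) +
      u$u11 * joint_prob(x, pars, fr, c(1, 1)) +
      u$u01 * joint_prob(x, pars, fr, c(0, 1))
    expect_equal(model_mean_utility(x, pars, fr, u), manual,
                 tolerance = 1e-10)
  }
  # best-outcome limit
  best <- stage_params(tox_params(-50, -10), eff_params(50, -10, 0, 0, 0.8))
  expect_equal(model_mean_utility(0.5, best, frailty_spec(0)), 100,
               tolerance = 1e-6)
})

test_that("with no frailty the model utility reduces to the independence formula", {
  pars <- default_truth()
  fr <- frailty_spec(0)
  for (x in c(0, 0.4, 1)) {
    piT <- marginal_prob(x, pars, fr, "T")
    piE <- marginal_prob(x, pars, fr, "E")
    expect_equal(model_mean_utility(x, pars, fr), true_mean_utility(piT, piE),
                 tolerance = 1e-8)
  }
})

test_that("true mean utility reproduces tabulated values and rejects bad input", {
  expect_equal(round(true_mean_utility(0.06, 0.41), 1), 62.2)
  expect_equal(round(true_mean_utility(0.01, 0.02), 1), 40.8)
  expect_equal(round(true_mean_utility(0.17, 0.56), 1), 66.8)
  expect_equal(true_mean_utility(0, 1), 100)
  expect_error(true_mean_utility(1.2, 0.5), "0, 1")
  expect_error(utility_table(u00 = 0), "strictly between")
  expect_error(utility_table(u10 = 5), "anchors")
})

test_that("invalid joint outcome labels and quadrature orders are rejected", {
  pars <- default_truth()
  expect_error(joint_prob(0.5, pars, frailty_spec(1), c(2, 0)), "pair")
  expect_error(marginal_prob(0.5, pars, frailty_spec(1), "T", order = 1),
               "order")
})
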