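test_that("with no data the posterior matches the prior", {
  f <- fit_model(trial_data(J = 6), slab_prior(), default_grid(),
                 settings = fast_mcmc(seed = 1, keep = 4000, warmup = 500))
  d <- f$diagnostics
  prior_mean <- c(-3, 1.1, -1, 1.1, -5, -0.1)
  prior_var <- c(25, 4, 6, 2, 3, 2)
  cols <- c("b0[1]", "b1[1]", "g0[1]", "g1[1]", "g2[1]", "g3[1]")
  for (i in seq_along(cols)) {
    mcse <- d$mcse[d$param == cols[i]]
    expect_lt(abs(mean(f$draws[, cols[i]]) - prior_mean[i]), 3 * mcse)
    expect_lt(abs(var(f$draws[, cols[i]]) / prior_var[i] - 1), 0.10)
  }
  # truncated-normal change point: compare with analytic truncated moments
  lo <- pnorm(0, 0.8, 1); hi <- pnorm(1.5, 0.8, 1)
  tn_mean <- 0.8 + (dnorm(-0.8) - dnorm(0.7)) / (hi - lo)
  expect_lt(abs(mean(f$draws[, "tau[1]"]) - tn_mean),
            4 * d$mcse[d$param == "tau[1]"])
})

test_that("the sampler's likelihood equals the quadrature joint probabilities", {
  g <- default_grid()
  r <- pracma::gaussHermite(40)
  set.seed(13)
  for (i in 1:100) {
    th <- c(rnorm(1, -2, 2), rnorm(1, 0.5, 1), rnorm(1, -1, 2),
            rnorm(1, 0.5, 1), rnorm(1, -2, 1), rnorm(1, 0, 1),
            runif(1, 0.1, 1.4))
    sig <- runif(1, 0, 2)
    cnt <- as.integer(rmultinom(1, 30, rep(1, 6 * 4)))
    ll_cpp <- bar12:::cpp_stage_loglik(cnt, g$std_doses, th, sig,
                                       r$x, r$w / sqrt(pi))
    pars <- stage_params(tox_params(th[1], th[2]),
                         eff_params(th[3], th[4], th[5], th[6], th[7]))
    fr <- frailty_spec(sig)
    ll_r <- 0
    for (j in 1:6) for (cell in 0:3) {
      n_jc <- cnt[(j - 1) * 4 + cell + 1]
      if (n_jc == 0) next
      y <- c(cell %% 2, cell %/% 2)
      ll_r <- ll_r + n_jc * log(joint_prob(g$std_doses[j], pars, fr, y))
    }
    expect_equal(ll_cpp, ll_r, tolerance = 1e-8)
  }
})

test_that("the posterior recovers single-stage parameters from model data", {
  set.seed(31)
  truth <- default_truth()
  d <- simulate_model_data(truth, sigma_eps = 0.8, n = 600)
  # convergence flags at light settings are expected and warn-and-proceed
  f <- suppressWarnings(
    fit_model(d, slab_prior(), default_grid(),
              settings = fast_mcmc(seed = 32, keep = 1500, warmup = 500)))
  m <- posterior_marginals(f, 1)
  fr <- frailty_spec(0.8)
  x <- default_grid()$std_doses
  truthT <- marginal_prob(x, truth, fr, "T")
  truthE <- marginal_prob(x, truth, fr, "E")
  # fitted marginal curves track the truth at every dose
  expect_lt(max(abs(colMeans(m$piT) - truthT)), 0.12)
  expect_lt(max(abs(colMeans(m$piE) - truthE)), 0.12)
})

test_that("exceedance and utility summaries behave on controlled posteriors", {
  f <- synthetic_fit(point_mass_draws(0.25, 0.5))
  expect_equal(posterior_exceedance(f, 1, 1, "T", threshold = 0), 1)
  expect_equal(posterior_exceedance(f, 1, 1, "T", threshold = 1), 0)
  expect_equal(posterior_exceedance(f, 1, 1, "T", threshold = 0.30), 0)
  # Beta-distributed probability: closed-form tail
  set.seed(8)
  p <- rbeta(4000, 2, 6)
  f2 <- synthetic_fit(point_mass_draws(p, rep(0.5, 4000), n = 4000))
  expect_equal(posterior_exceedance(f2, 1, 1, "T", threshold = 0.3),
               1 - pbeta(0.3, 2, 6), tolerance = 0.03)
  # point-mass utility at dose 1 reproduces the tabulated 62.2
  f3 <- synthetic_fit(point_mass_draws(0.06, 0.41))
  expect_equal(round(posterior_mean_utility(f3, 1, 1), 1), 62.2)
  # two-draw posterior averages the per-draw utilities
  f4 <- synthetic_fit(point_mass_draws(c(0.06, 0.2), c(0.41, 0.6), n = 2))
  u1 <- true_mean_utility(0.06, 0.41); u2 <- true_mean_utility(0.2, 0.6)
  expect_equal(posterior_mean_utility(f4, 1, 1), (u1 + u2) / 2,
               tolerance = 1e-8)
})

test_that("identical seeds reproduce fits exactly", {
  d <- trial_data(rep(1:3, each = 4), rep(1, 12), rbinom(12, 1, 0.2),
                  rbinom(12, 1, 0.4), J = 6)
  f1 <- fit_model(d, slab_prior(), default_grid(), settings = fast_mcmc(99))
  f2 <- fit_model(d, slab_prior(), default_grid(), settings = fast_mcmc(99))
  expect_identical(f1$draws, f2$draws)
})

test_that("borrowing-weight degeneracies collapse the mixture as intended", {
  # with spike == slab, forcing omega to 1 or to 0 yields the same model:
  # stage-2 parameters draw from the slab either way
  set.seed(51)
  d <- trial_data(rep(c(2, 4), each = 6), rep(1:2, each = 6),
                  rbinom(12, 1, 0.15), rbinom(12, 1, 0.45), J = 6)
  sp <- bar12:::slab_as_spike(slab_prior())
  f1 <- suppressWarnings(
    fit_model(d, slab_prior(), default_grid(), spikes = list(sp),
              settings = fast_mcmc(60, keep = 2000, warmup = 400),
              omega_fix = c(T = 1, E = 1)))
  f0 <- suppressWarnings(
    fit_model(d, slab_prior(), default_grid(), spikes = list(sp),
              settings = fast_mcmc(61, keep = 2000, warmup = 400),
              omega_fix = c(T = 0, E = 0)))
  cols <- paste0(c("b0", "g0", "g1"), "[2]")
  for (cc in cols) {
    se <- sqrt(f1$diagnostics$mcse[f1$diagnostics$param == cc]^2 +
                 f0$diagnostics$mcse[f0$diagnostics$param == cc]^2)
    expect_lt(abs(mean(f1$draws[, cc]) - mean(f0$draws[, cc])), 4 * se)
  }
})

test_that("split R-hat and ESS diagnostics flag what they should", {
  set.seed(12)
  good <- cbind(a = rnorm(4000), b = rnorm(4000))
  chain <- rep(1:2, each = 2000)
  dg <- mcmc_diagnostics(good, chain)
  expect_true(all(dg$rhat < 1.01))
  expect_false(any(dg$flag))
  # two chains stuck at different fixed points
  bad <- cbind(a = c(rnorm(2000, 0, 0.1), rnorm(2000, 5, 0.1)))
  db <- mcmc_diagnostics(bad, chain)
  expect_gt(db$rhat[1], 1.5)
  expect_true(db$flag[1])
  # AR(1) draws: ESS within 20% of n(1-rho)/(1+rho)
  rho <- 0.7
  ar <- replicate(2, as.numeric(arima.sim(list(ar = rho), 20000)))
  da <- mcmc_diagnostics(cbind(a = c(ar)), rep(1:2, each = 20000))
  expect_lt(abs(da$ess[1] / (40000 * (1 - rho) / (1 + rho)) - 1), 0.2)
  expect_warning(mcmc_diagnostics(good, rep(1, 4000)), "single chain")
})
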