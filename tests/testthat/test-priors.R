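test_that("plug-in prior curves reproduce the elicited probabilities", {
  g <- default_grid()
  expect_equal(round(plug_in_prior_curve(slab_prior(), g, "T"), 3),
               c(0.047, 0.083, 0.142, 0.232, 0.355, 0.501))
  expect_equal(round(plug_in_prior_curve(slab_prior(), g, "E"), 3),
               c(0.269, 0.401, 0.546, 0.683, 0.792, 0.712))
  # curves depend on the prior means only, not the dispersions
  wide <- slab_prior(tox_var = c(400, 50), eff_var = c(90, 30, 40, 30))
  expect_equal(plug_in_prior_curve(wide, g, "T"),
               plug_in_prior_curve(slab_prior(), g, "T"))
  expect_equal(plug_in_prior_curve(wide, g, "E"),
               plug_in_prior_curve(slab_prior(), g, "E"))
})

test_that("the plug-in change point is the prior location, not the truncated mean", {
  g <- default_grid()
  # discriminating check: tau = 0.8 reproduces 0.712 at the top dose;
  # the truncated-normal mean of tau does not
  s <- slab_prior()
  expect_equal(round(plug_in_prior_curve(s, g, "E")[6], 3), 0.712)
  lo <- pnorm(0, 0.8, 1); hi <- pnorm(1.5, 0.8, 1)
  tn_mean <- 0.8 + (dnorm((0 - 0.8) / 1) - dnorm((1.5 - 0.8) / 1)) /
    (hi - lo)
  alt <- eff_prob_conditional(1, eff_params(-1, 1.1, -5, -0.1, tau = tn_mean))
  expect_false(round(alt, 3) == 0.712)
})

test_that("beta moment matching recovers the ESS identity", {
  expect_equal(beta_ess(0.5, 1 / 12), 2)       # Uniform(0,1) = Beta(1,1)
  expect_equal(beta_ess(0.5, 0.05), 4)
  set.seed(4)
  for (i in 1:50) {
    m <- runif(1, 0.05, 0.95)
    v <- runif(1, 1e-4, 0.9 * m * (1 - m))
    expect_equal(beta_ess(m, v), m * (1 - m) / v - 1)
  }
  expect_identical(beta_ess(0.3, 0), Inf)
})

test_that("default priors satisfy both calibration criteria at every dose", {
  g <- default_grid()
  for (oc in c("T", "E")) {
    rep <- prior_ess(slab_prior(), g, oc, n_draws = 2e4, seed = 10)
    expect_true(all(rep$ess >= 0 & rep$ess <= 2))
    expect_true(all(rep$mass > 0.70))
  }
})

test_that("boundary mass decreases as the prior dispersion grows", {
  g <- default_grid()
  tight <- prior_mass_check(slab_prior(), g, "T", n_draws = 2e4, seed = 5)
  loose <- prior_mass_check(slab_prior(tox_var = c(100, 16)), g, "T",
                            n_draws = 2e4, seed = 5)
  expect_true(all(loose < tight))
  # a near-point-mass prior has everything in the interior
  pm <- prior_mass_check(slab_prior(tox_var = c(1e-4, 1e-4),
                                    frailty_scale = 1e-6),
                         g, "T", n_draws = 2e4, seed = 5,
                         method = "empirical")
  expect_equal(pm, rep(1, 6))
})

test_that("calibration is idempotent and repairs over-tight priors", {
  g <- default_grid()
  cal <- calibrate_slab(slab_prior(), g, n_draws = 1e4, seed = 2)
  expect_true(cal$feasible)
  expect_identical(cal$scale, 1)
  # shrink the variances a hundredfold: ESS blows past 2, scale must grow
  tight <- slab_prior(tox_var = c(25, 4) / 100, eff_var = c(6, 2, 3, 2) / 100,
                      tau_scale = 0.1)
  cal2 <- calibrate_slab(tight, g, n_draws = 1e4, seed = 2)
  expect_gt(cal2$scale, 1)
  expect_true(all(cal2$tox$ess <= 2 + 1e-9))
  expect_true(all(cal2$eff$ess <= 2 + 1e-9))
})

test_that("spike construction recovers a known posterior normal", {
  set.seed(21)
  mu_t <- c(-2, 0.5)
  S_t <- matrix(c(1, -0.6, -0.6, 0.8), 2)
  mu_e <- c(-1, 0.8, -3, -0.2, 0.7)
  A <- matrix(rnorm(25, sd = 0.4), 5)
  S_e <- crossprod(A) + diag(0.2, 5)
  n <- 1e5
  Dt <- MASS::mvrnorm(n, mu_t, S_t)
  De <- MASS::mvrnorm(n, mu_e, S_e)
  draws <- cbind(Dt, De)
  colnames(draws) <- c("b0[1]", "b1[1]", "g0[1]", "g1[1]", "g2[1]",
                       "g3[1]", "tau[1]")
  sp <- build_spike_slab(draws, slab_prior())
  expect_equal(sp$spike_tox_mean, mu_t, tolerance = 0.02)
  expect_equal(unclass(sp$spike_tox_cov), S_t, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(sp$spike_eff_mean, mu_e, tolerance = 0.02)
  expect_equal(unclass(sp$spike_eff_cov), S_e, tolerance = 0.1,
               ignore_attr = TRUE)
  expect_identical(sp$weight_a, 1)   # Beta(1,1): prior borrowing weight 1/2
})

test_that("degenerate draws produce a floored spike covariance", {
  draws <- matrix(rep(c(-2, 0.5, -1, 0.8, -3, -0.2, 0.7), each = 50), 50)
  colnames(draws) <- c("b0[1]", "b1[1]", "g0[1]", "g1[1]", "g2[1]",
                       "g3[1]", "tau[1]")
  sp <- build_spike_slab(draws, slab_prior())
  ev <- eigen(sp$spike_tox_cov, symmetric = TRUE)$values
  expect_true(all(ev >= 1e-9))
  expect_error(build_spike_slab(draws[0, , drop = FALSE], slab_prior()),
               "empty")
})
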