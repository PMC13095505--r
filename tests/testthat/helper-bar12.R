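# Shared fixtures: light sampler settings and synthetic fit objects.

fast_mcmc <- function(seed = 1L, keep = 500L, warmup = 300L, chains = 2L,
                      gh_order = 20L) {
  mcmc_settings(chains = chains, warmup = warmup, keep = keep,
                gh_order = gh_order, seed = seed)
}

# A minimal bar12_fit carrying externally supplied draws, for decision-rule
# tests that need full control of the posterior.
synthetic_fit <- function(draws, grid = default_grid(), n_stages = 1L,
                          gh_order = 20L) {
  chain <- rep(1:2, length.out = nrow(draws))
  structure(list(draws = draws, chain = chain, accept = NULL,
                 diagnostics = NULL, converged = TRUE,
                 n_stages = n_stages, grid = grid,
                 settings = mcmc_settings(chains = 2L, warmup = 0L,
                                          keep = 250L, gh_order = gh_order),
                 n_obs = 0L),
            class = "bar12_fit")
}

# Draws matrix for a single-stage model where every draw puts the marginal
# probabilities at dose 1 (x = 0) exactly at (piT, piE): b0 = qlogis(piT),
# g0 = qlogis(piE), flat curves, no frailty.
point_mass_draws <- function(piT, piE, n = 400L) {
  stopifnot(length(piT) == length(piE))
  idx <- rep(seq_along(piT), length.out = n)
  cbind(`b0[1]` = qlogis(piT)[idx], `b1[1]` = -30, `g0[1]` = qlogis(piE)[idx],
        `g1[1]` = -30, `g2[1]` = 0, `g3[1]` = 0, `tau[1]` = 0.8,
        sigma_eps = 0)
}

# Simulate patients from the model itself (shared normal frailty).
simulate_model_data <- function(truth, sigma_eps, n, grid = default_grid(),
                                stage = 1L) {
  doses <- rep_len(seq_len(grid$J), n)
  eps <- rnorm(n, 0, sigma_eps)
  x <- grid$std_doses[doses]
  pT <- tox_prob_conditional(x, truth$tox, eps)
  pE <- eff_prob_conditional(x, truth$eff, eps)
  trial_data(doses, rep(stage, n), rbinom(n, 1, pT), rbinom(n, 1, pE),
             J = grid$J)
}

default_truth <- function() {
  stage_params(tox_params(-2.5, 0.8),
               eff_params(-0.5, 0.7, -3, -0.5, tau = 0.6))
}
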