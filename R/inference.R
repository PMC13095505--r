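#' MCMC sampler settings
#'
#' Settings for the adaptive component-wise random-walk Metropolis sampler.
#' Three presets are provided: `"default"` (4 chains x 2,500 kept draws,
#' the working setting for interactive fits and operating-characteristics
#' runs at moderate scale), `"oc"` (2 chains x 500 kept draws with a
#' 20-node frailty quadrature, the light preset used inside large
#' simulation sweeps), and `"final"` (4 chains x 10,000 kept draws, for
#' reporting a real trial analysis).
#'
#' @param chains Number of chains (at least 2 for convergence diagnostics).
#' @param warmup Adaptation iterations discarded per chain.
#' @param keep Post-warmup draws kept per chain (at least 500).
#' @param gh_order Gauss-Hermite order for the frailty-marginalized
#'   likelihood.
#' @param seed Optional RNG seed applied just before sampling.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(chains = 4L, warmup = 1000L, keep = 2500L,
                          gh_order = 40L, seed = NULL) {
  stopifnot(chains >= 1, warmup >= 0, keep >= 100, gh_order >= 2)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 keep = as.integer(keep), gh_order = as.integer(gh_order),
                 seed = seed),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @param preset One of `"default"`, `"oc"`, `"final"`.
#' @export
mcmc_preset <- function(preset = c("default", "oc", "final")) {
  switch(match.arg(preset),
         default = mcmc_settings(),
         oc = mcmc_settings(chains = 2L, warmup = 300L, keep = 500L,
                            gh_order = 20L),
         final = mcmc_settings(chains = 4L, warmup = 2000L, keep = 10000L))
}

#' Column names of the draws matrix for a K-stage model
#' @noRd
draw_colnames <- function(K) {
  nm <- c(t(outer(seq_len(K), c("b0", "b1", "g0", "g1", "g2", "g3", "tau"),
                  function(k, p) paste0(p, "[", k, "]"))))
  c(nm, "sigma_eps", if (K >= 2) c("omega_T", "omega_E"))
}

#' Flatten prior objects into the sampler's prior list
#' @noRd
prior_list <- function(slab, spikes, omega_fix, spike_dynamic = TRUE) {
  list(slab_tox_mean = slab$tox_mean, slab_tox_sd = sqrt(slab$tox_var),
       slab_eff_mean = slab$eff_mean, slab_eff_sd = sqrt(slab$eff_var),
       tau_loc = slab$tau_loc, tau_sd = slab$tau_scale,
       tau_lo = slab$tau_bounds[1], tau_hi = slab$tau_bounds[2],
       phi = slab$frailty_scale,
       frailty_on_var = identical(slab$frailty_prior %||% "sd", "var"),
       weight_a = if (length(spikes)) spikes[[1]]$weight_a else 1,
       weight_b = if (length(spikes)) spikes[[1]]$weight_b else 1,
       omega_fix_T = omega_fix[["T"]], omega_fix_E = omega_fix[["E"]],
       spike_dynamic = spike_dynamic,
       spikes = lapply(spikes, function(s)
         list(tox_mean = s$spike_tox_mean, tox_cov = s$spike_tox_cov,
              eff_mean = s$spike_eff_mean, eff_cov = s$spike_eff_cov)))
}

#' Fit the stage-wise dose-response model
#'
#' Samples the joint posterior of all stage parameter blocks, the shared
#' frailty SD, and (for multi-stage models) the per-outcome borrowing
#' weights, given the accumulated trial data.  The patient frailty is
#' marginalized analytically inside the likelihood by Gauss-Hermite
#' quadrature, so the sampler state carries no per-patient latent
#' variables.  Stage-1 parameters get the slab prior; stage-k (k >= 2)
#' parameters get the spike-and-slab mixture with the mixture indicator
#' marginalized analytically, keeping the posterior density smooth.
#'
#' @param data A [trial_data()] object (may be empty, in which case the
#'   posterior equals the prior).
#' @param slab A [slab_prior()].
#' @param grid A [dose_grid()].
#' @param spikes `NULL` for a single-stage model, else a list of
#'   [spike_slab_prior()] objects for stages `2..K` (in order).
#' @param settings An [mcmc_settings()] object.
#' @param omega_fix Named numeric vector `c(T = ., E = .)`; `NA` (default)
#'   samples the borrowing weight, a value in `[0, 1]` fixes it (used for
#'   degeneracy checks).
#' @param spike_dynamic If `TRUE` (default) the informative spike is the
#'   autoregressive conditional `N(theta_{k-1}, Sigma_{k-1})` with the
#'   *current* previous-stage parameters as its mean and the tweak-time
#'   posterior covariance frozen; `FALSE` freezes the mean as well
#'   (a fully empirical spike).  The conditional form preserves posterior
#'   ridges -- e.g. after a toxicity-free stage the (intercept, slope)
#'   posterior is a ridge, and pinning the spike at its centre would
#'   misrepresent what was learned.
#' @param n_stages Number of stages in the model; defaults to
#'   `length(spikes) + 1`.
#' @return A `bar12_fit` object: `draws` (matrix, one named column per
#'   parameter, natural scale), `chain`, `diagnostics`, `converged` (no
#'   split R-hat above 1.05), `accept`, plus the inputs needed by
#'   posterior summaries.  Non-convergence produces a warning, not an
#'   error: a running trial cannot pause, so decisions proceed and the
#'   flag is logged.
#' @export
fit_model <- function(data, slab, grid, spikes = NULL,
                      settings = mcmc_settings(),
                      omega_fix = c(T = NA_real_, E = NA_real_),
                      spike_dynamic = TRUE, n_stages = NULL) {
  if (is.null(n_stages)) n_stages <- length(spikes) + 1L
  K <- as.integer(n_stages)
  if (length(spikes) != K - 1L)
    stop("spikes must be supplied for stages 2..K exactly", call. = FALSE)
  if (nrow(data$records) && max(data$records$stage) > K)
    stop("data contain stages beyond the model", call. = FALSE)
  if (!is.null(settings$seed)) set.seed(settings$seed)

  cnt <- count_array(data, K)
  r <- gh_rule(settings$gh_order)
  P <- 7L * K + 1L + if (K >= 2) 2L else 0L
  init <- matrix(0, settings$chains, P)
  for (ch in seq_len(settings$chains)) {
    v <- numeric(P)
    for (k in seq_len(K)) {
      v[7 * (k - 1) + 1:2] <- slab$tox_mean + 0.3 * rnorm(2)
      v[7 * (k - 1) + 3:6] <- slab$eff_mean + 0.3 * rnorm(4)
      v[7 * (k - 1) + 7] <- min(max(slab$tau_loc + 0.05 * rnorm(1),
                                    slab$tau_bounds[1] + 0.01),
                                slab$tau_bounds[2] - 0.01)
    }
    v[7 * K + 1] <- log(0.5) + 0.3 * rnorm(1)
    if (K >= 2) v[7 * K + 2:3] <- 0.5 * rnorm(2)
    init[ch, ] <- v
  }
  res <- cpp_mh_sample(cnt, K, grid$std_doses,
                       prior_list(slab, spikes, omega_fix, spike_dynamic),
                       init,
                       settings$chains, settings$warmup, settings$keep,
                       r$x, r$w / sqrt(pi))
  draws <- res$draws
  colnames(draws) <- draw_colnames(K)
  diag <- mcmc_diagnostics(draws, res$chain)
  converged <- !any(diag$rhat > 1.05, na.rm = TRUE)
  if (!converged)
    warning("possible non-convergence: max split R-hat = ",
            format(max(diag$rhat, na.rm = TRUE), digits = 4), call. = FALSE)
  structure(list(draws = draws, chain = res$chain, accept = res$accept,
                 diagnostics = diag, converged = converged,
                 n_stages = K, grid = grid, settings = settings,
                 slab = slab, spikes = spikes, omega_fix = omega_fix,
                 n_obs = nrow(data$records)),
            class = "bar12_fit")
}

#' @export
print.bar12_fit <- function(x, ...) {
  cat("Stage-wise dose-response model fit: ", x$n_stages, " stage(s), ",
      x$n_obs, " patients, ", nrow(x$draws), " draws (",
      x$settings$chains, " chains)\n", sep = "")
  cat("Converged:", x$converged,
      "| max R-hat:", format(suppressWarnings(max(x$diagnostics$rhat,
                                                  na.rm = TRUE)),
                             digits = 4), "\n")
  invisible(x)
}

#' Per-draw dose summaries for one stage
#'
#' For each posterior draw and each dose, the unconditional (frailty-
#' integrated, using that draw's `sigma_eps`) marginal toxicity and
#' efficacy probabilities and the model mean utility.
#'
#' @param fit A [fit_model()] result.
#' @param stage Stage whose parameter block to use.
#' @param u A [utility_table()].
#' @param order Quadrature order (defaults to the fit's setting).
#' @param frailty `"integrate"` averages each draw's conditional
#'   probabilities over that draw's frailty distribution (quadrature);
#'   `"condition"` evaluates them at the population-typical patient
#'   `eps = 0` (the scale on which prior probability curves are elicited
#'   and reported).
#' @return List of three draws-by-doses matrices: `piT`, `piE`, `utility`.
#' @export
posterior_marginals <- function(fit, stage = fit$n_stages,
                                u = utility_table(), order = NULL,
                                frailty = c("integrate", "condition")) {
  frailty <- match.arg(frailty)
  cols <- paste0(c("b0", "b1", "g0", "g1", "g2", "g3", "tau"),
                 "[", stage, "]")
  if (!all(cols %in% colnames(fit$draws)))
    stop("stage ", stage, " not in fitted model", call. = FALSE)
  r <- gh_rule(if (is.null(order)) fit$settings$gh_order else order)
  sig <- if (frailty == "condition") rep(0, nrow(fit$draws))
  else fit$draws[, "sigma_eps"]
  cpp_dose_summaries(fit$draws[, cols, drop = FALSE], sig,
                     fit$grid$std_doses,
                     c(u$u10, u$u00, u$u11, u$u01),
                     r$x, r$w / sqrt(pi))
}

#' Posterior exceedance probability of a dose's outcome rate
#'
#' Fraction of posterior draws whose unconditional marginal outcome
#' probability at the dose exceeds `threshold` -- the quantity gating
#' dose acceptability.
#'
#' @inheritParams posterior_marginals
#' @param dose Dose level (index).
#' @param outcome `"T"` or `"E"`.
#' @param threshold Probability threshold.
#' @param marginals Optional precomputed [posterior_marginals()] result.
#' @return A probability.
#' @export
posterior_exceedance <- function(fit, dose, stage = fit$n_stages,
                                 outcome = c("T", "E"), threshold,
                                 marginals = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(marginals)) marginals <- posterior_marginals(fit, stage)
  p <- if (outcome == "T") marginals$piT else marginals$piE
  mean(p[, dose] > threshold)
}

#' Posterior mean utility of doses
#'
#' Average over posterior draws of the model mean utility at each dose --
#' the design's dose-ranking criterion.
#'
#' @inheritParams posterior_exceedance
#' @param dose Dose level(s); `NULL` returns all doses.
#' @param u A [utility_table()].
#' @return Numeric vector of posterior mean utilities.
#' @export
posterior_mean_utility <- function(fit, dose = NULL, stage = fit$n_stages,
                                   u = utility_table(), marginals = NULL) {
  if (is.null(marginals)) marginals <- posterior_marginals(fit, stage, u)
  mu <- colMeans(marginals$utility)
  if (is.null(dose)) mu else mu[dose]
}
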