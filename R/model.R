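#' Toxicity model parameters
#'
#' Parameters of the stage-specific dose-toxicity model
#' \deqn{\mathrm{logit}\, \pi^T(x, \epsilon) = \beta_0 + e^{\beta_1} x + \epsilon.}
#' The slope enters as \eqn{e^{\beta_1}} so toxicity is structurally
#' monotone increasing in dose.
#'
#' @param beta0 Baseline toxicity log-odds at `x = 0`.
#' @param beta1 Log of the dose slope.
#' @return A `tox_params` object.
#' @export
tox_params <- function(beta0, beta1) {
  stopifnot(is.finite(beta0), is.finite(beta1))
  structure(list(beta0 = beta0, beta1 = beta1), class = "tox_params")
}

#' Efficacy model parameters
#'
#' Parameters of the stage-specific change-point dose-efficacy model
#' \deqn{\mathrm{logit}\, \pi^E(x, \epsilon) = \gamma_0 + e^{\gamma_1} x +
#'   \gamma_2 (x - \tau)_+ + \gamma_3 x^2 + \epsilon,}
#' where \eqn{(u)_+ = \max(u, 0)}.  The hinge term allows efficacy to
#' plateau or decline beyond a threshold dose \eqn{\tau}; the quadratic term
#' adds curvature for saturation or unimodal patterns.
#'
#' @param gamma0 Baseline efficacy log-odds.
#' @param gamma1 Log of the linear dose slope.
#' @param gamma2 Change in slope beyond the change point.
#' @param gamma3 Quadratic coefficient.
#' @param tau Change-point dose, inside `tau_bounds`.
#' @param tau_bounds Truncation interval for `tau` (default `c(0, 1.5)`).
#' @return An `eff_params` object.
#' @export
eff_params <- function(gamma0, gamma1, gamma2, gamma3, tau,
                       tau_bounds = c(0, 1.5)) {
  stopifnot(is.finite(gamma0), is.finite(gamma1), is.finite(gamma2),
            is.finite(gamma3), is.finite(tau))
  if (tau < tau_bounds[1L] || tau > tau_bounds[2L])
    stop("tau must lie inside its truncation interval", call. = FALSE)
  structure(list(gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 gamma3 = gamma3, tau = tau, tau_bounds = tau_bounds),
            class = "eff_params")
}

#' Stage parameter bundle
#'
#' @param tox A [tox_params()] object.
#' @param eff An [eff_params()] object.
#' @param stage Stage index (1 = original manufacturing process).
#' @return A `stage_params` object.
#' @export
stage_params <- function(tox, eff, stage = 1L) {
  stopifnot(inherits(tox, "tox_params"), inherits(eff, "eff_params"),
            stage >= 1)
  structure(list(tox = tox, eff = eff, stage = as.integer(stage)),
            class = "stage_params")
}

#' Patient frailty specification
#'
#' The patient-level frailty \eqn{\epsilon_i} is shared by the toxicity and
#' efficacy linear predictors, inducing positive within-patient association
#' between the two outcomes.  The default is \eqn{N(0, \sigma_\epsilon^2)};
#' a scaled Student-t alternative with heavier tails is available for
#' sensitivity analyses (scale parameterized so `sigma_eps` is the scale,
#' not the SD).
#'
#' @param sigma_eps Nonnegative frailty scale.
#' @param family `"normal"` or `"student_t"`.
#' @param df Degrees of freedom (> 2), used only for `"student_t"`.
#' @return A `frailty_spec` object.
#' @export
frailty_spec <- function(sigma_eps = 0, family = c("normal", "student_t"),
                         df = 5) {
  family <- match.arg(family)
  if (!is.finite(sigma_eps) || sigma_eps < 0)
    stop("sigma_eps must be a nonnegative real", call. = FALSE)
  if (family == "student_t" && df <= 2)
    stop("student_t frailty requires df > 2", call. = FALSE)
  structure(list(sigma_eps = sigma_eps, family = family, df = df),
            class = "frailty_spec")
}

## quadrature rules, memoized per order --------------------------------------

.quad_cache <- new.env(parent = emptyenv())

#' Gauss-Hermite rule (physicists' weight) of a given order
#' @noRd
gh_rule <- function(order = 40L) {
  if (order < 2) stop("quadrature order must be at least 2", call. = FALSE)
  key <- paste0("gh", order)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussHermite(order)
  .quad_cache[[key]]
}

#' Gauss-Legendre rule on (0, 1)
#' @noRd
gl_rule <- function(order = 40L) {
  if (order < 2) stop("quadrature order must be at least 2", call. = FALSE)
  key <- paste0("gl", order)
  if (is.null(.quad_cache[[key]])) {
    r <- pracma::gaussLegendre(order, 0, 1)
    .quad_cache[[key]] <- list(x = r$x, w = r$w)
  }
  .quad_cache[[key]]
}

#' Frailty nodes and weights for numerical integration
#'
#' Returns nodes `eps` and weights `w` (summing to 1) such that
#' `sum(w * f(eps))` approximates `E[f(eps)]` under the frailty
#' distribution.  Normal frailty uses Gauss-Hermite quadrature; Student-t
#' frailty uses a fixed-node Gauss-Legendre rule on the probability scale
#' through the t quantile function.
#'
#' @param frailty A [frailty_spec()].
#' @param order Number of quadrature nodes (default 40).
#' @return List with numeric vectors `eps` and `w`.
#' @export
frailty_quadrature <- function(frailty, order = 40L) {
  if (frailty$sigma_eps == 0)
    return(list(eps = 0, w = 1))
  if (frailty$family == "normal") {
    r <- gh_rule(order)
    list(eps = sqrt(2) * frailty$sigma_eps * r$x, w = r$w / sqrt(pi))
  } else {
    r <- gl_rule(order)
    list(eps = frailty$sigma_eps * stats::qt(r$x, df = frailty$df), w = r$w)
  }
}

## conditional probabilities --------------------------------------------------

#' Conditional toxicity probability
#'
#' Inverse-logit of \eqn{\beta_0 + e^{\beta_1} x + \epsilon}; strictly
#' increasing in both the dose and the frailty.
#'
#' @param x Standardized dose (vectorized).
#' @param p A [tox_params()] object.
#' @param eps Frailty value (vectorized, recycled against `x`).
#' @return Toxicity probability.
#' @export
tox_prob_conditional <- function(x, p, eps = 0) {
  plogis(p$beta0 + exp(p$beta1) * x + eps)
}

#' Conditional efficacy probability
#'
#' Inverse-logit of \eqn{\gamma_0 + e^{\gamma_1} x + \gamma_2 (x - \tau)_+ +
#' \gamma_3 x^2 + \epsilon}.  The hinge term is exactly zero for
#' \eqn{x \le \tau}.
#'
#' @inheritParams tox_prob_conditional
#' @param p An [eff_params()] object.
#' @return Efficacy probability.
#' @export
eff_prob_conditional <- function(x, p, eps = 0) {
  plogis(p$gamma0 + exp(p$gamma1) * x + p$gamma2 * pmax(x - p$tau, 0) +
           p$gamma3 * x^2 + eps)
}

#' Unconditional (frailty-averaged) marginal outcome probability
#'
#' Integrates the conditional toxicity or efficacy probability over the
#' frailty distribution by fixed-order quadrature.  Deterministic given its
#' inputs.
#'
#' @param x Standardized dose (vectorized).
#' @param params A [stage_params()] object.
#' @param frailty A [frailty_spec()].
#' @param outcome `"T"` or `"E"`.
#' @param order Quadrature order (default 40).
#' @return Marginal probability, same length as `x`.
#' @export
marginal_prob <- function(x, params, frailty, outcome = c("T", "E"),
                          order = 40L) {
  outcome <- match.arg(outcome)
  q <- frailty_quadrature(frailty, order)
  p <- if (outcome == "T") params$tox else params$eff
  f <- if (outcome == "T") tox_prob_conditional else eff_prob_conditional
  out <- numeric(length(x))
  for (i in seq_along(q$eps))
    out <- out + q$w[i] * f(x, p, q$eps[i])
  out
}

#' Unconditional joint outcome probability
#'
#' Probability of the joint outcome pair `y = c(yT, yE)` at standardized
#' dose `x`, integrating the product of the two conditional Bernoulli
#' probabilities over the shared frailty.  The shared frailty induces
#' positive association: for `sigma_eps > 0`,
#' `P(1,1) >= P(T=1) * P(E=1)`.
#'
#' @inheritParams marginal_prob
#' @param y Integer pair, each element 0 or 1 (`c(yT, yE)`).
#' @return Joint probability, same length as `x`.
#' @export
joint_prob <- function(x, params, frailty, y, order = 40L) {
  if (length(y) != 2L || !all(y %in% c(0, 1)))
    stop("y must be a pair of 0/1 outcome indicators c(yT, yE)", call. = FALSE)
  q <- frailty_quadrature(frailty, order)
  out <- numeric(length(x))
  for (i in seq_along(q$eps)) {
    pT <- tox_prob_conditional(x, params$tox, q$eps[i])
    pE <- eff_prob_conditional(x, params$eff, q$eps[i])
    tt <- if (y[1] == 1) pT else 1 - pT
    ee <- if (y[2] == 1) pE else 1 - pE
    out <- out + q$w[i] * tt * ee
  }
  out
}

#' Model-based mean utility of a dose
#'
#' Utility-weighted sum of the four unconditional joint outcome
#' probabilities,
#' \deqn{\bar U(x) = \sum_{y_T} \sum_{y_E} U(y_T, y_E) \Pr(Y_T = y_T,
#'   Y_E = y_E \mid x).}
#'
#' @inheritParams marginal_prob
#' @param u A [utility_table()].
#' @return Mean utility, bounded by the utility anchors.
#' @export
model_mean_utility <- function(x, params, frailty, u = utility_table(),
                               order = 40L) {
  u$u10 * joint_prob(x, params, frailty, c(1, 0), order) +
    u$u00 * joint_prob(x, params, frailty, c(0, 0), order) +
    u$u11 * joint_prob(x, params, frailty, c(1, 1), order) +
    u$u01 * joint_prob(x, params, frailty, c(0, 1), order)
}
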