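#' Dose acceptability screening
#'
#' A dose is *acceptable* given the current posterior when it passes both
#' strict screening inequalities:
#' \deqn{\Pr(\pi^T(x) > \bar\pi_T \mid D) < c_T \quad\text{and}\quad
#'       \Pr(\pi^E(x) > \underline\pi_E \mid D) > c_E.}
#' Doses found unacceptable during a stage are not reconsidered within that
#' stage (pass them via `blacklist`); after a manufacturing tweak every
#' dose is re-evaluated, because the tweak may have changed its safety or
#' efficacy.  An empty result signals trial termination.
#'
#' The toxicity condition is screened at every dose: the toxicity model is
#' structurally monotone in dose, so posterior borrowing to untried doses
#' is reliable.  The efficacy condition, by contrast, rides on a
#' deliberately flexible (change-point, possibly unimodal) curve, so
#' extrapolated futility at doses without any data in the evaluated stage
#' is not trusted: the trial engine passes such doses via
#' `futility_exempt`, and they are screened for toxicity only.  With the
#' default empty exemption set, both conditions apply to every dose.
#'
#' @param fit A [fit_model()] result.
#' @param stage Stage whose parameter block to screen under.
#' @param config A [design_config()].
#' @param blacklist Dose levels already excluded in this stage.
#' @param futility_exempt Dose levels exempt from the efficacy condition
#'   (doses without data in the evaluated stage).
#' @param marginals Optional precomputed [posterior_marginals()] result.
#' @return Integer vector of acceptable dose levels (possibly empty).
#' @export
admissible_set <- function(fit, stage = fit$n_stages, config,
                           blacklist = integer(),
                           futility_exempt = integer(), marginals = NULL) {
  if (is.null(marginals)) marginals <- posterior_marginals(fit, stage,
                                                           config$utility)
  J <- ncol(marginals$piT)
  excT <- colMeans(marginals$piT > config$pi_bar_T)
  excE <- colMeans(marginals$piE > config$pi_low_E)
  ok <- excT < config$c_T & (excE > config$c_E |
                               seq_len(J) %in% futility_exempt)
  setdiff(which(ok), blacklist)
}

#' Greedy dose selection with the no-skip rule
#'
#' Selects the admissible dose with the highest posterior mean utility,
#' subject to the constraint that an untried dose may not be skipped when
#' escalating: doses more than one level above the highest dose ever tried
#' are not assignable, so escalation proceeds one untried level at a time.
#' Ties break toward the lower dose.  Returns `NA` (terminate) when no
#' admissible dose is assignable.
#'
#' @param admissible Integer vector of acceptable dose levels.
#' @param utilities Numeric vector of posterior mean utilities, one per
#'   grid dose level.
#' @param highest_tried Highest dose level tried so far (0 if none).
#' @return Selected dose level, or `NA_integer_` to terminate.
#' @export
select_next_dose <- function(admissible, utilities, highest_tried) {
  eligible <- admissible[admissible <= highest_tried + 1L]
  if (!length(eligible)) return(NA_integer_)
  u <- utilities[eligible]
  eligible[which.max(u)]          # which.max takes the first (lowest dose) tie
}

#' Candidate set for adaptive randomization
#'
#' The `L` admissible doses with the highest posterior mean utilities,
#' in descending utility order (ties toward the lower dose).  Refreshed at
#' every decision point as the utilities change.
#'
#' @inheritParams select_next_dose
#' @param L Candidate-set size.
#' @return Integer vector of up to `L` dose levels, best first.
#' @export
candidate_set <- function(admissible, utilities, L) {
  if (!length(admissible)) return(integer())
  ord <- admissible[order(-utilities[admissible], admissible)]
  head(ord, min(L, length(ord)))
}

#' Adaptive-randomization probabilities
#'
#' Power-weighted allocation probabilities over the candidate set:
#' \deqn{p_\ell = \frac{u_\ell^{\kappa}}{\sum_{l} u_l^{\kappa}}.}
#' `kappa = 0` gives equal randomization; large `kappa` concentrates on
#' the highest-utility candidate.  Candidates with zero utility receive
#' exactly zero probability when `kappa > 0`; if every candidate has zero
#' utility the fallback is uniform, with a warning.
#'
#' @param utilities Posterior mean utilities of the candidates (>= 0).
#' @param kappa Nonnegative tuning power.
#' @return Probability vector summing to 1.
#' @export
ar_probabilities <- function(utilities, kappa = 1) {
  stopifnot(kappa >= 0, all(utilities >= 0))
  if (kappa == 0) return(rep(1 / length(utilities), length(utilities)))
  if (all(utilities == 0)) {
    warning("all candidate utilities are zero; falling back to uniform",
            call. = FALSE)
    return(rep(1 / length(utilities), length(utilities)))
  }
  w <- (utilities / max(utilities))^kappa   # rescale for numerical stability
  w / sum(w)
}
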