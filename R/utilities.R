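#' Elicited joint-outcome utility table
#'
#' Utilities of the four (toxicity, efficacy) outcome pairs.  The anchors
#' are fixed by convention: the best outcome (no toxicity, response) has
#' utility 100 and the worst (toxicity, no response) utility 0.  The two
#' intermediate utilities are elicited from the clinical team subject to
#' `0 < u00 < 100` and `0 < u11 < 100`.  The defaults `u00 = 40`,
#' `u11 = 60` are those of the simulation study.
#'
#' @param u00 Utility of (no toxicity, no response).
#' @param u11 Utility of (toxicity, response).
#' @param u10 Utility of (toxicity, no response); anchored at 0.
#' @param u01 Utility of (no toxicity, response); anchored at 100.
#' @return A `utility_table` object.
#' @export
utility_table <- function(u00 = 40, u11 = 60, u10 = 0, u01 = 100) {
  if (u10 != 0 || u01 != 100)
    stop("utility anchors are fixed: U(1,0) = 0 and U(0,1) = 100", call. = FALSE)
  if (!(u00 > 0 && u00 < 100) || !(u11 > 0 && u11 < 100))
    stop("intermediate utilities must lie strictly between 0 and 100",
         call. = FALSE)
  structure(list(u10 = u10, u00 = u00, u11 = u11, u01 = u01),
            class = "utility_table")
}

#' True mean utility of a dose under independent outcomes
#'
#' Mean utility computed from marginal true toxicity and efficacy
#' probabilities treating the two outcomes as independent:
#' \deqn{U = u_{01}(1-\pi_T)\pi_E + u_{00}(1-\pi_T)(1-\pi_E) +
#'   u_{11}\pi_T\pi_E + u_{10}\pi_T(1-\pi_E).}
#' This is the utility scale on which simulation scenarios are defined:
#' scenario truths are specified directly as marginal rates (deliberately
#' not generated from the fitted outcome model), with toxicity and efficacy
#' independent.
#'
#' @param piT,piE True marginal probabilities in `[0, 1]` (vectorized).
#' @param u A [utility_table()].
#' @return True mean utility (vectorized).
#' @examples
#' true_mean_utility(0.06, 0.41)  # 62.2
#' @export
true_mean_utility <- function(piT, piE, u = utility_table()) {
  if (any(piT < 0 | piT > 1) || any(piE < 0 | piE > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  u$u01 * (1 - piT) * piE + u$u00 * (1 - piT) * (1 - piE) +
    u$u11 * piT * piE + u$u10 * piT * (1 - piE)
}
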