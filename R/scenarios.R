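#' Load the simulation scenario library
#'
#' Eighteen stress-test scenarios defining the simulation truth: per-stage,
#' per-dose true toxicity and efficacy probabilities, deliberately specified
#' on the probability scale (not generated from the fitted outcome model) to
#' reflect realistic dose-response shapes and model misspecification.
#' Scenarios 1-10 have two manufacturing stages (one tweak); scenarios
#' 11-18 have three stages (two tweaks).  Scenario truth treats the two
#' outcomes as independent Bernoulli draws, which reproduces every tabulated
#' true mean utility exactly.
#'
#' On load, every cell's stored utility is recomputed from its `(piT, piE)`
#' via [true_mean_utility()]; any 1-dp discrepancy aborts the load naming
#' the offending cell.
#'
#' @param file Optional path to a scenario CSV (columns `scenario`, `stage`,
#'   `dose`, `piT`, `piE`, `utility`); defaults to the packaged library.
#' @param u A [utility_table()] used for the self-check and derived optima.
#' @param pi_bar_T,pi_low_E Acceptability limits used to derive each
#'   stage's true optimal dose.
#' @return Named list of `scenario` objects.  Each has `id`, `stages`
#'   (count), `piT`/`piE`/`utility` (stage-by-dose matrices), `optimal`
#'   (per-stage true optimal dose, 0 = none acceptable), and `homogeneous`
#'   (identical truth in all stages).
#' @export
load_scenarios <- function(file = NULL, u = utility_table(),
                           pi_bar_T = 0.30, pi_low_E = 0.20) {
  if (is.null(file))
    file <- system.file("extdata", "scenarios.csv", package = "bar12",
                        mustWork = TRUE)
  d <- read.csv(file)
  need <- c("scenario", "stage", "dose", "piT", "piE", "utility")
  if (!all(need %in% names(d)))
    stop("scenario file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  recomputed <- round(true_mean_utility(d$piT, d$piE, u), 1)
  bad <- which(abs(recomputed - d$utility) > 0.051)
  if (length(bad))
    stop("scenario fixture self-check failed at scenario ",
         d$scenario[bad[1]], " stage ", d$stage[bad[1]], " dose ",
         d$dose[bad[1]], ": stored ", d$utility[bad[1]], ", recomputed ",
         recomputed[bad[1]], call. = FALSE)
  out <- lapply(split(d, d$scenario), function(s) {
    K <- max(s$stage); J <- max(s$dose)
    piT <- piE <- uu <- matrix(NA_real_, K, J)
    for (i in seq_len(nrow(s))) {
      piT[s$stage[i], s$dose[i]] <- s$piT[i]
      piE[s$stage[i], s$dose[i]] <- s$piE[i]
      uu[s$stage[i], s$dose[i]] <- s$utility[i]
    }
    opt <- vapply(seq_len(K), function(k) {
      acc <- which(piT[k, ] <= pi_bar_T & piE[k, ] >= pi_low_E)
      if (!length(acc)) 0L else acc[which.max(uu[k, acc])]
    }, 0L)
    structure(list(id = s$scenario[1], stages = K, J = J,
                   piT = piT, piE = piE, utility = uu, optimal = opt,
                   homogeneous = all(apply(piT, 2, function(v)
                     length(unique(v)) == 1)) &&
                     all(apply(piE, 2, function(v)
                       length(unique(v)) == 1))),
              class = "scenario")
  })
  names(out) <- paste0("scenario_", vapply(out, `[[`, 0, "id"))
  out[order(vapply(out, `[[`, 0, "id"))]
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$id, "-", x$stages, "stage(s),",
      if (x$homogeneous) "homogeneous" else "heterogeneous", "\n")
  for (k in seq_len(x$stages))
    cat(sprintf("  stage %d: optimal dose %s | piT %s | piE %s\n", k,
                if (x$optimal[k] == 0) "none" else x$optimal[k],
                paste(x$piT[k, ], collapse = " "),
                paste(x$piE[k, ], collapse = " ")))
  invisible(x)
}

#' Generate synthetic patient outcomes under a scenario truth
#'
#' Draws `n` independent outcome pairs for patients treated at one dose in
#' one stage: `YT ~ Bernoulli(piT)` and `YE ~ Bernoulli(piE)`,
#' independent of each other (the scenario-truth convention).
#'
#' @param scenario A `scenario` object from [load_scenarios()].
#' @param stage,dose Stage and dose level of the treated patients.
#' @param n Number of patients.
#' @return Data frame with columns `yT`, `yE`.
#' @export
generate_outcomes <- function(scenario, stage, dose, n) {
  stopifnot(stage >= 1, stage <= scenario$stages,
            dose >= 1, dose <= scenario$J, n >= 0)
  data.frame(yT = rbinom(n, 1, scenario$piT[stage, dose]),
             yE = rbinom(n, 1, scenario$piE[stage, dose]))
}
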