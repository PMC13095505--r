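#' Operating characteristics over replicated trials
#'
#' Runs [run_trial()] for replicate seeds `base_seed, base_seed + 1, ...,
#' base_seed + n_reps - 1` and aggregates the selection distribution and
#' mean patient allocation in the standard reporting layout: per-dose
#' selection percentage (plus a none-selected percentage) and per-stage
#' per-dose mean patient counts, each with a binomial Monte-Carlo standard
#' error.  Replicates are seed-isolated, so results are identical for any
#' worker count.
#'
#' @param design `"BAR12"`, `"Identical"`, or `"Separate"`.
#' @param scenario A `scenario` from [load_scenarios()].
#' @param config A [design_config()].
#' @param slab A [slab_prior()].
#' @param settings An [mcmc_settings()] (default: the light `"oc"` preset).
#' @param n_reps Number of replicated trials.
#' @param base_seed First replicate seed.
#' @param workers Parallel workers (forked; 1 = serial).  Each replicate
#'   carries its own seed, so the result does not depend on `workers`.
#' @param ... Further arguments passed to [run_trial()].
#' @return An `oc_summary`: `selection_pct` (named vector over doses and
#'   `"none"`), `selection_se`, `mean_counts` (stage-by-dose matrix),
#'   `mean_treated`, `pct_stopped_early`, `n_reps`, `n_failed`,
#'   `n_warnings`, `seeds`, and the per-replicate `selected` vector.
#' @export
simulate_ocs <- function(design, scenario, config = design_config(),
                         slab = slab_prior(), settings = mcmc_preset("oc"),
                         n_reps = 100L, base_seed = 1L, workers = 1L, ...) {
  stopifnot(n_reps >= 1)
  seeds <- base_seed + seq_len(n_reps) - 1L
  one <- function(s) {
    tryCatch(run_trial(design, scenario, config, slab, settings,
                       seed = s, ...),
             error = function(e) structure(list(seed = s,
                                                message = conditionMessage(e)),
                                           class = "trial_failure"))
  }
  results <- if (workers > 1L &&
                 requireNamespace("parallel", quietly = TRUE) &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(seeds, one, mc.cores = workers)
  } else {
    lapply(seeds, one)
  }
  failed <- vapply(results, inherits, TRUE, "trial_failure")
  ok <- results[!failed]
  n_ok <- length(ok)
  if (!n_ok) stop("every replicate failed", call. = FALSE)
  J <- ncol(ok[[1]]$counts)
  K <- nrow(ok[[1]]$counts)
  selected <- vapply(ok, `[[`, 0L, "selected")
  sel_counts <- tabulate(selected + 1L, nbins = J + 1L)  # index 1 = none
  sel_pct <- 100 * sel_counts / n_ok
  names(sel_pct) <- c("none", paste0("dose", seq_len(J)))
  sel_pct <- sel_pct[c(paste0("dose", seq_len(J)), "none")]
  sel_se <- sqrt(sel_pct / 100 * (1 - sel_pct / 100) / n_ok) * 100
  mean_counts <- Reduce(`+`, lapply(ok, `[[`, "counts")) / n_ok
  dimnames(mean_counts) <- list(paste0("stage", seq_len(K)),
                                paste0("dose", seq_len(J)))
  structure(list(design = design, scenario_id = scenario$id,
                 selection_pct = sel_pct, selection_se = sel_se,
                 mean_counts = mean_counts,
                 mean_treated = mean(vapply(ok, `[[`, 0L, "n_treated")),
                 pct_stopped_early = 100 * mean(vapply(ok, `[[`, TRUE,
                                                       "stopped_early")),
                 n_reps = n_reps, n_failed = sum(failed),
                 n_warnings = sum(vapply(ok, `[[`, 0L, "n_warnings")),
                 seeds = seeds, selected = selected,
                 failures = results[failed]),
            class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat(sprintf("Operating characteristics: %s, scenario %s, %d replicates (%d failed)\n",
              x$design, x$scenario_id, x$n_reps, x$n_failed))
  tab <- rbind(`selection %` = round(x$selection_pct[seq_len(ncol(x$mean_counts))], 1),
               round(x$mean_counts, 1))
  print(tab)
  cat(sprintf("none selected: %.1f%% | mean treated: %.1f | early stops: %.1f%% | convergence flags: %d\n",
              x$selection_pct[["none"]], x$mean_treated,
              x$pct_stopped_early, x$n_warnings))
  invisible(x)
}

#' Tidy one-row-per-dose OC table
#'
#' @param x An `oc_summary`.
#' @param ... Unused.
#' @return Data frame with dose-level selection percentages, MC standard
#'   errors, and per-stage mean counts (plus a `none` row).
#' @export
as.data.frame.oc_summary <- function(x, ...) {
  J <- ncol(x$mean_counts)
  d <- data.frame(dose = c(seq_len(J), 0L),
                  selection_pct = as.numeric(x$selection_pct),
                  selection_se = as.numeric(x$selection_se))
  for (k in seq_len(nrow(x$mean_counts)))
    d[[paste0("mean_n", k)]] <- c(x$mean_counts[k, ], NA)
  d
}
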