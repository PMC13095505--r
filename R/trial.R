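#' Assign one adaptive-randomization block
#'
#' A block of up to `c * L` patients is partitioned into sub-cohorts of
#' size `c`; each sub-cohort's dose is drawn independently from the
#' candidate set with the adaptive-randomization probabilities (so doses
#' may repeat across sub-cohorts).  A partial final block (stage budget
#' not a multiple of `c * L`) simply gets fewer sub-cohorts.
#'
#' @param candidates Candidate dose levels (best-first).
#' @param ar_probs Allocation probabilities, same length.
#' @param c_size Sub-cohort size `c`.
#' @param n_patients Number of patients in the block.
#' @return Integer vector of `n_patients` dose assignments.
#' @export
assign_block <- function(candidates, ar_probs, c_size, n_patients) {
  stopifnot(length(candidates) >= 1, length(ar_probs) == length(candidates),
            n_patients >= 1)
  out <- integer(0)
  while (length(out) < n_patients) {
    d <- if (length(candidates) == 1L) candidates
    else sample(candidates, 1L, prob = ar_probs)
    out <- c(out, rep(d, min(c_size, n_patients - length(out))))
  }
  out
}

#' Simulate a single dose-finding trial
#'
#' Runs one trial under the scenario truth with the chosen design:
#'
#' * **BAR12**: stage 1 escalates greedily by posterior mean utility with
#'   the no-skip rule, refitting after every cohort.  At each tweak the
#'   informative spike's covariance is frozen from the current posterior
#'   (its mean rides the previous stage's sampled parameters; see
#'   [fit_model()]) and the next stage's parameters get the
#'   spike-and-slab mixture prior; post-tweak patients are adaptively
#'   randomized in blocks of `c * L` over the refreshed top-`L`
#'   candidate set.
#' * **Identical**: ignores tweaks entirely -- one parameter set, pooled
#'   data, greedy conduct throughout.
#' * **Separate**: each stage is an independent mini-trial -- previous data
#'   are discarded, the prior resets to the slab, and escalation restarts
#'   at the starting dose; early stage termination advances to the next
#'   tweak rather than abandoning the trial, since later manufacturing
#'   processes may behave differently.
#'
#' For BAR12 and Identical an empty admissible set terminates the trial
#' with no dose selected.  Doses found unacceptable stay excluded for the
#' remainder of their stage and are re-evaluated after a tweak (BAR12);
#' for Identical, which ignores tweaks, exclusion is permanent.  At the
#' maximum sample size the dose with the highest posterior mean utility
#' among the final admissible set is selected.
#'
#' Outcomes are pre-generated per (stage, dose, patient-slot) from the
#' replicate seed before any design logic runs, so all three designs see
#' common random numbers; sampler seeds are derived per fit from the same
#' replicate seed.
#'
#' @param design `"BAR12"`, `"Identical"`, or `"Separate"`.
#' @param scenario A `scenario` from [load_scenarios()].
#' @param config A [design_config()]; `length(stage_splits)` must not
#'   exceed the scenario's stage count.
#' @param slab A [slab_prior()].
#' @param settings An [mcmc_settings()]; the `"oc"` preset is the default
#'   for simulation work.
#' @param seed Replicate seed driving outcomes, sampling, and allocation.
#' @param grid Dose grid (defaults to the six-level study grid).
#' @param weight_a,weight_b Borrowing-weight Beta hyperparameters (BAR12).
#' @param omega_fix Named vector `c(T = ., E = .)` fixing the borrowing
#'   weights (`NA` = sampled); used for degeneracy checks.
#' @param force_slab_spike If `TRUE` the spike component is replaced by
#'   the slab itself (degeneracy checks).
#' @param decision_frailty How decision quantities (exceedance
#'   probabilities and posterior mean utilities) treat the patient
#'   frailty: `"integrate"` (default) averages each draw's dose-outcome
#'   probabilities over the frailty distribution (the unconditional
#'   marginals); `"condition"` evaluates them for the population-typical
#'   patient `eps = 0`.
#' @return A `trial_result`: `selected` (dose level, 0 = none),
#'   `counts` (stage-by-dose treated), `stopped_early`, `n_fits`,
#'   `n_warnings` (convergence flags), `decisions` (audit log data frame),
#'   `data` (the accumulated [trial_data()]), plus inputs (`design`,
#'   `scenario_id`, `seed`).
#' @export
run_trial <- function(design = c("BAR12", "Identical", "Separate"),
                      scenario, config = design_config(),
                      slab = slab_prior(),
                      settings = mcmc_preset("oc"), seed = 1L,
                      grid = default_grid(),
                      weight_a = 1, weight_b = 1,
                      omega_fix = c(T = NA_real_, E = NA_real_),
                      force_slab_spike = FALSE,
                      decision_frailty = c("integrate", "condition")) {
  decision_frailty <- match.arg(decision_frailty)
  design <- match.arg(design)
  n_stages <- length(config$stage_splits)
  if (scenario$stages < n_stages)
    stop("scenario has ", scenario$stages, " stage(s) but the design plans ",
         n_stages, call. = FALSE)
  if (scenario$J != grid$J)
    stop("scenario and dose grid disagree on the number of doses",
         call. = FALSE)
  J <- grid$J

  ## common-random-numbers outcome streams: one uniform pair per
  ## (stage, dose, slot), drawn before any design logic
  set.seed(seed)
  maxN <- config$N
  uT <- array(runif(n_stages * J * maxN), c(n_stages, J, maxN))
  uE <- array(runif(n_stages * J * maxN), c(n_stages, J, maxN))
  slot <- matrix(0L, n_stages, J)
  mcmc_base <- (as.numeric(seed) %% 1e6) * 1000 + 7

  data <- trial_data(J = J)
  treated <- matrix(0L, n_stages, J)
  cur <- 1L
  blacklist <- integer()
  highest_tried <- 0L
  spikes <- list()
  n_fits <- 0L
  n_warn <- 0L
  decisions <- list()
  selected <- 0L
  stopped_early <- FALSE
  fresh <- TRUE                     # next action: treat first cohort of a
                                    # (re)started escalation at start_dose

  treat <- function(stage, dose, m) {
    s <- slot[stage, dose]
    idx <- s + seq_len(m)
    slot[stage, dose] <<- s + m
    yT <- as.integer(uT[stage, dose, idx] < scenario$piT[stage, dose])
    yE <- as.integer(uE[stage, dose, idx] < scenario$piE[stage, dose])
    data <<- append_records(data, rep(dose, m), rep(stage, m), yT, yE)
    treated[stage, dose] <<- treated[stage, dose] + m
    highest_tried <<- max(highest_tried, dose)
  }

  do_fit <- function() {
    n_fits <<- n_fits + 1L
    st <- settings
    st$seed <- as.integer((mcmc_base + n_fits * 31) %% 2147483647)
    r <- data$records
    if (design == "BAR12") {
      fit <- withCallingHandlers(
        fit_model(data, slab, grid, spikes = spikes, settings = st,
                  omega_fix = omega_fix, n_stages = cur),
        warning = function(w) {
          n_warn <<- n_warn + 1L
          invokeRestart("muffleWarning")
        })
      list(fit = fit, model_stage = cur)
    } else {
      keep <- if (design == "Separate") r$stage == cur else rep(TRUE, nrow(r))
      d1 <- trial_data(r$dose[keep], rep(1L, sum(keep)), r$yT[keep],
                       r$yE[keep], J = J)
      fit <- withCallingHandlers(
        fit_model(d1, slab, grid, spikes = NULL, settings = st,
                  n_stages = 1L),
        warning = function(w) {
          n_warn <<- n_warn + 1L
          invokeRestart("muffleWarning")
        })
      list(fit = fit, model_stage = 1L)
    }
  }

  log_decision <- function(action, A, util, dose = NA_integer_,
                           excT = numeric(), excE = numeric()) {
    decisions[[length(decisions) + 1L]] <<- data.frame(
      n = nrow(data$records), stage = cur, action = action,
      admissible = paste(A, collapse = ","),
      utilities = paste(round(util, 2), collapse = ","),
      excT = paste(round(excT, 3), collapse = ","),
      excE = paste(round(excE, 3), collapse = ","),
      dose = paste(dose, collapse = ","))
  }

  advance_stage <- function() {
    cur <<- cur + 1L
    blacklist <<- integer()
    if (design == "Separate") {
      highest_tried <<- 0L
      fresh <<- TRUE
    }
  }

  repeat {
    if (fresh) {                       # step 1: first cohort, no model yet
      fresh <- FALSE
      m <- min(config$cohort, config$stage_splits[cur] - sum(treated[cur, ]))
      treat(cur, config$start_dose, m)
      log_decision("start", integer(), numeric(), config$start_dose)
      next
    }
    res <- do_fit()
    marg <- posterior_marginals(res$fit, res$model_stage, config$utility,
                                frailty = decision_frailty)
    util <- colMeans(marg$utility)
    excT <- colMeans(marg$piT > config$pi_bar_T)
    excE <- colMeans(marg$piE > config$pi_low_E)
    # doses with data in the stage under evaluation are fully screened;
    # doses without such data are screened for toxicity only, and
    # permanent within-stage exclusion likewise applies only to doses
    # with data at exclusion time
    tried_now <- if (design == "Identical") which(colSums(treated) > 0)
    else which(treated[cur, ] > 0)
    pass <- admissible_set(res$fit, res$model_stage, config,
                           blacklist = integer(),
                           futility_exempt = setdiff(seq_len(J), tried_now),
                           marginals = marg)
    A <- setdiff(pass, blacklist)     # within-stage exclusions are permanent
    blacklist <- union(blacklist, intersect(setdiff(seq_len(J), pass),
                                            tried_now))
    at_boundary <- sum(treated[cur, ]) >= config$stage_splits[cur]

    if (at_boundary) {
      if (cur == n_stages) {           # final analysis
        if (length(A)) {
          selected <- A[which.max(util[A])]
          log_decision("select", A, util, selected, excT, excE)
        } else {
          log_decision("select_none", A, util, excT = excT, excE = excE)
        }
        break
      }
      if (design == "BAR12")           # freeze the spike at the tweak
        spikes[[cur]] <- if (force_slab_spike)
          slab_as_spike(slab, weight_a, weight_b)
        else withCallingHandlers(
          build_spike_slab(res$fit, slab, weight_a, weight_b, stage = cur),
          warning = function(w) {
            n_warn <<- n_warn + 1L
            invokeRestart("muffleWarning")
          })
      log_decision("tweak", A, util, excT = excT, excE = excE)
      advance_stage()
      next
    }

    if (!length(A)) {                  # no acceptable dose in this stage
      if (design == "Separate" && cur < n_stages) {
        log_decision("stage_stop", A, util, excT = excT, excE = excE)
        advance_stage()                # later processes may differ; restart
        next
      }
      stopped_early <- TRUE
      log_decision("terminate", A, util, excT = excT, excE = excE)
      break
    }

    remaining <- config$stage_splits[cur] - sum(treated[cur, ])
    if (design == "BAR12" && cur >= 2L) {
      C <- candidate_set(A, util, config$L)
      p <- ar_probabilities(util[C], config$kappa)
      m <- min(config$cohort * config$L, remaining)
      doses <- assign_block(C, p, config$cohort, m)
      for (d in unique(doses)) treat(cur, d, sum(doses == d))
      log_decision("ar_block", A, util, unique(doses), excT, excE)
    } else {
      d <- select_next_dose(A, util, highest_tried)
      if (is.na(d)) {                  # admissible doses exist but none is
        stopped_early <- TRUE         # reachable without skipping
        log_decision("terminate_no_assignable", A, util, excT = excT, excE = excE)
        break
      }
      treat(cur, d, min(config$cohort, remaining))
      log_decision("cohort", A, util, d, excT, excE)
    }
  }

  structure(list(design = design, scenario_id = scenario$id, seed = seed,
                 selected = selected, counts = treated,
                 stopped_early = stopped_early, n_treated = sum(treated),
                 n_fits = n_fits, n_warnings = n_warn,
                 decisions = do.call(rbind, decisions), data = data),
            class = "trial_result")
}

#' Spike component equal to the slab (degeneracy checks)
#' @noRd
slab_as_spike <- function(slab, weight_a = 1, weight_b = 1) {
  spike_slab_prior(slab$tox_mean, diag(slab$tox_var),
                   c(slab$eff_mean, slab$tau_loc),
                   diag(c(slab$eff_var, slab$tau_scale^2)),
                   slab, weight_a, weight_b)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(x$design, "trial, scenario", x$scenario_id, "| selected dose:",
      if (x$selected == 0) "none" else x$selected,
      "| treated:", x$n_treated,
      if (x$stopped_early) "(stopped early)" else "", "\n")
  cnt <- x$counts
  dimnames(cnt) <- list(paste0("stage", seq_len(nrow(cnt))),
                        paste0("d", seq_len(ncol(cnt))))
  print(cnt)
  invisible(x)
}
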