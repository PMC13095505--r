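#' Trial design configuration
#'
#' All design constants of the dose-finding algorithm.  Defaults are the
#' simulation-study settings: upper toxicity limit 0.30, lower efficacy
#' limit 0.20, acceptability cutoffs `c_T = 0.70` and `c_E = 0.15`, cohorts
#' of 3, candidate-set size `L = 2`, adaptive-randomization power
#' `kappa = 1`, maximum of 42 patients split 18/24 across the two
#' manufacturing stages, starting at dose level 1, with utility anchors
#' `(0, 40, 60, 100)`.
#'
#' @param pi_bar_T Upper limit on the toxicity probability.
#' @param pi_low_E Lower limit on the efficacy probability.
#' @param c_T,c_E Posterior probability cutoffs of the acceptability rules:
#'   a dose is dropped when `Pr(piT > pi_bar_T) >= c_T` (the protocol's 0.70
#'   evidence level for excess toxicity) or when `Pr(piE > pi_low_E) <= c_E`.
#'   The protocol states its futility evidence level as 0.85, i.e. a dose is
#'   dropped when at least 85% sure its efficacy rate is below the limit;
#'   on the acceptability scale used here that is `c_E = 1 - 0.85 = 0.15`.
#' @param cohort Cohort size `c`.
#' @param L Number of candidate doses for adaptive randomization.
#' @param kappa Adaptive-randomization tuning power (>= 0).
#' @param stage_splits Planned per-stage sample sizes `n_1..n_K`; their sum
#'   is the maximum sample size `N`.  Each split must be a multiple of the
#'   cohort size (a tweak cannot interrupt a cohort); offending splits are
#'   rounded down with a warning.
#' @param start_dose Starting dose level.
#' @param utility A [utility_table()].
#' @return A `design_config` object (with derived element `N`).
#' @export
design_config <- function(pi_bar_T = 0.30, pi_low_E = 0.20,
                          c_T = 0.70, c_E = 0.15,
                          cohort = 3L, L = 2L, kappa = 1,
                          stage_splits = c(18L, 24L),
                          start_dose = 1L, utility = utility_table()) {
  errs <- character()
  chk01 <- function(v, nm) if (!is.numeric(v) || v <= 0 || v >= 1)
    errs <<- c(errs, paste0(nm, " must lie strictly in (0, 1), got ", v))
  chk01(pi_bar_T, "pi_bar_T"); chk01(pi_low_E, "pi_low_E")
  chk01(c_T, "c_T"); chk01(c_E, "c_E")
  if (kappa < 0) errs <- c(errs, "kappa must be nonnegative")
  if (L < 1) errs <- c(errs, "L must be at least 1")
  if (cohort < 1) errs <- c(errs, "cohort size must be at least 1")
  if (any(stage_splits < 1)) errs <- c(errs, "stage splits must be positive")
  if (length(errs))
    stop("invalid design configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  stage_splits <- as.integer(stage_splits)
  off <- stage_splits %% as.integer(cohort) != 0L
  if (any(off)) {
    warning("stage splits ", paste(stage_splits[off], collapse = ", "),
            " are not multiples of the cohort size; rounded down",
            call. = FALSE)
    stage_splits <- stage_splits - stage_splits %% as.integer(cohort)
  }
  structure(list(pi_bar_T = pi_bar_T, pi_low_E = pi_low_E,
                 c_T = c_T, c_E = c_E, cohort = as.integer(cohort),
                 L = as.integer(L), kappa = kappa,
                 stage_splits = stage_splits, N = sum(stage_splits),
                 start_dose = as.integer(start_dose), utility = utility),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Design configuration\n")
  cat(sprintf("  limits: pi_bar_T = %g, pi_low_E = %g; cutoffs: c_T = %g, c_E = %g\n",
              x$pi_bar_T, x$pi_low_E, x$c_T, x$c_E))
  cat(sprintf("  cohort %d, L = %d, kappa = %g, N = %d (splits %s), start dose %d\n",
              x$cohort, x$L, x$kappa, x$N,
              paste(x$stage_splits, collapse = "/"), x$start_dose))
  cat(sprintf("  utilities: U(1,0)=%g U(0,0)=%g U(1,1)=%g U(0,1)=%g\n",
              x$utility$u10, x$utility$u00, x$utility$u11, x$utility$u01))
  invisible(x)
}

#' Validate a configuration document
#'
#' Reads a structured configuration (YAML or JSON file, or an already
#' parsed list) and returns the fully populated, range-checked design
#' configuration, slab prior, and MCMC settings.  Unspecified fields take
#' the package defaults; invalid fields produce itemized errors.  An empty
#' document yields the full default configuration.
#'
#' Recognized top-level sections: `design` (fields of [design_config()],
#' with `u00`/`u11` for the utility table and `N` cross-checked against
#' `stage_splits`), `prior` (fields of [slab_prior()] plus `weight_a`,
#' `weight_b`, and optional `frailty` = `"normal"`/`"student_t"` with
#' `frailty_df`), and `mcmc` (fields of [mcmc_settings()] or
#' `preset`).
#'
#' @param document File path or named list.
#' @return List with elements `design`, `prior`, `weight_a`, `weight_b`,
#'   `frailty`, and `mcmc`.
#' @export
validate_config <- function(document = list()) {
  doc <- document
  if (is.character(document) && length(document) == 1L) {
    if (!file.exists(document))
      stop("configuration file not found: ", document, call. = FALSE)
    doc <- if (grepl("\\.json$", document, ignore.case = TRUE))
      jsonlite::read_json(document, simplifyVector = TRUE)
    else yaml::read_yaml(document)
    if (is.null(doc)) doc <- list()
  }
  if (!is.list(doc)) stop("configuration must be a named list", call. = FALSE)

  de <- doc$design %||% list()
  ut <- utility_table(u00 = de$u00 %||% 40, u11 = de$u11 %||% 60)
  cfg <- design_config(
    pi_bar_T = de$pi_bar_T %||% 0.30, pi_low_E = de$pi_low_E %||% 0.20,
    c_T = de$c_T %||% 0.70, c_E = de$c_E %||% 0.15,
    cohort = de$cohort %||% 3L, L = de$L %||% 2L,
    kappa = de$kappa %||% 1,
    stage_splits = de$stage_splits %||% c(18L, 24L),
    start_dose = de$start_dose %||% 1L, utility = ut)
  if (!is.null(de$N) && de$N != cfg$N)
    stop("invalid design configuration:\n  - stage_splits (",
         paste(cfg$stage_splits, collapse = "/"), ") do not sum to N = ",
         de$N, call. = FALSE)

  pc <- doc$prior %||% list()
  slab <- slab_prior(
    tox_mean = pc$tox_mean %||% c(-3, 1.1),
    tox_var = pc$tox_var %||% c(25, 4),
    eff_mean = pc$eff_mean %||% c(-1, 1.1, -5, -0.1),
    eff_var = pc$eff_var %||% c(6, 2, 3, 2),
    tau_loc = pc$tau_loc %||% 0.8, tau_scale = pc$tau_scale %||% 1,
    tau_bounds = pc$tau_bounds %||% c(0, 1.5),
    frailty_scale = pc[["frailty_scale"]] %||% 1,
    frailty_prior = pc[["frailty_prior"]] %||% "sd")
  frailty_family <- pc[["frailty"]] %||% "normal"
  if (!frailty_family %in% c("normal", "student_t"))
    stop("prior$frailty must be 'normal' or 'student_t'", call. = FALSE)

  mc <- doc$mcmc %||% list()
  mcmc <- if (!is.null(mc$preset)) mcmc_preset(mc$preset)
  else mcmc_settings(chains = mc$chains %||% 4L,
                     warmup = mc$warmup %||% 1000L,
                     keep = mc$keep %||% 2500L,
                     gh_order = mc$gh_order %||% 40L,
                     seed = mc$seed)
  list(design = cfg, prior = slab,
       weight_a = pc$weight_a %||% 1, weight_b = pc$weight_b %||% 1,
       frailty = list(family = frailty_family, df = pc[["frailty_df"]] %||% 5),
       mcmc = mcmc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records everything needed to reconstruct a run: content hashes of the
#' configuration and prior inputs, scenario ids, designs, replicate count,
#' seeds, package version, and a timestamp.  Hashes are MD5 over the
#' serialized objects, stable across platforms for identical inputs.
#'
#' @param path Output JSON path.
#' @param config A [design_config()] (or full [validate_config()] result).
#' @param prior A [slab_prior()].
#' @param scenarios Scenario ids used.
#' @param designs Design names used.
#' @param n_reps Replicates.
#' @param seeds Seeds used.
#' @return The manifest list, invisibly; written as JSON to `path`.
#' @export
write_manifest <- function(path, config, prior, scenarios = integer(),
                           designs = character(), n_reps = 0L,
                           seeds = integer()) {
  hash_obj <- function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    # version-pinned serialization keeps the hash platform-stable
    saveRDS(x, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
  }
  manifest <- list(config_hash = hash_obj(unclass(config)),
                   prior_hash = hash_obj(unclass(prior)),
                   scenarios = scenarios, designs = designs,
                   n_reps = n_reps, seeds = seeds,
                   package_version = as.character(utils::packageVersion("bar12")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
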