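# Convergence diagnostics for the Metropolis draws: split R-hat, MCMC
# effective sample size by the multi-chain variogram method, and Monte
# Carlo standard errors.

#' Split chains in half for R-hat
#' @noRd
split_chains <- function(v, chain) {
  out <- list()
  for (ch in unique(chain)) {
    x <- v[chain == ch]
    h <- floor(length(x) / 2)
    out[[length(out) + 1L]] <- x[seq_len(h)]
    out[[length(out) + 1L]] <- x[h + seq_len(h)]
  }
  out
}

#' Split R-hat for one parameter
#' @noRd
rhat_one <- function(v, chain) {
  parts <- split_chains(v, chain)
  m <- length(parts); n <- length(parts[[1L]])
  if (n < 2) return(NA_real_)
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size for one parameter (multi-chain autocorrelation)
#' @noRd
ess_one <- function(v, chain) {
  chains <- lapply(unique(chain), function(ch) v[chain == ch])
  m <- length(chains); n <- length(chains[[1L]])
  W <- mean(vapply(chains, var, 0))
  if (W == 0) return(NA_real_)
  mean_all <- mean(v)
  B_means <- if (m > 1) var(vapply(chains, mean, 0)) else 0
  var_plus <- W * (n - 1) / n + B_means
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1L, 500L)
  acfs <- vapply(chains, function(x)
    as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf), numeric(max_lag + 1L))
  # combined autocorrelation (BDA3): rho_t = 1 - (W - mean within-chain
  # autocovariance at lag t) / var_plus
  rho <- 1 - (W - rowMeans(acfs * rep(vapply(chains, var, 0),
                                      each = max_lag + 1L))) / var_plus
  # Geyer initial positive sequence on paired sums
  s <- 0; t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' MCMC convergence diagnostics
#'
#' Split R-hat, effective sample size, and Monte Carlo standard error for
#' every sampled parameter.  Parameters with split R-hat above 1.05 are
#' flagged.  With a single chain, R-hat is omitted with a warning.
#'
#' @param draws Matrix of posterior draws (columns = parameters).
#' @param chain Integer vector of chain indices, one per row.
#' @return A data frame with columns `param`, `rhat`, `ess`, `mcse`,
#'   `flag`.
#' @export
mcmc_diagnostics <- function(draws, chain) {
  single <- length(unique(chain)) < 2
  if (single)
    warning("single chain: split R-hat requires at least 2 chains",
            call. = FALSE)
  out <- data.frame(param = colnames(draws), rhat = NA_real_,
                    ess = NA_real_, mcse = NA_real_, flag = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(draws))) {
    v <- draws[, i]
    if (sd(v) == 0) next          # fixed parameter (e.g. pinned omega)
    out$rhat[i] <- rhat_one(v, chain)
    out$ess[i] <- ess_one(v, chain)
    out$mcse[i] <- sd(v) / sqrt(out$ess[i])
  }
  if (single) out$rhat <- NA_real_
  out$flag <- !is.na(out$rhat) & out$rhat > 1.05
  out
}
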