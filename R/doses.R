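#' Standardize a raw dose grid to the unit interval
#'
#' Maps raw cell doses \eqn{d_1 < \dots < d_J} onto standardized doses
#' \deqn{x_j = \frac{\log_{10} d_j - \log_{10} d_1}{\log_{10} d_J - \log_{10} d_1},}
#' so that the lowest dose maps to 0 and the highest to 1.  Dose-response
#' models in this package are parameterized on the standardized scale, which
#' keeps regression coefficients comparable across trials whose raw doses
#' may span orders of magnitude (e.g. 1e6 to 1e9 cells).
#'
#' @param raw_doses Numeric vector of at least two strictly increasing,
#'   strictly positive raw doses (cells per infusion).
#' @return An object of class `dose_grid`: a list with elements `raw_doses`,
#'   `std_doses` (full precision, not rounded) and `J` (number of doses).
#' @examples
#' standardize_doses(c(1, 2.5, 6.3, 15.8, 39.8, 100) * 1e6)
#' @export
standardize_doses <- function(raw_doses) {
  if (!is.numeric(raw_doses) || length(raw_doses) < 2)
    stop("at least 2 raw doses are required", call. = FALSE)
  if (any(!is.finite(raw_doses)) || any(raw_doses <= 0))
    stop("raw doses must be finite and strictly positive", call. = FALSE)
  if (any(diff(raw_doses) <= 0))
    stop("raw doses must be strictly increasing", call. = FALSE)
  ld <- log10(raw_doses)
  x <- (ld - ld[1L]) / (ld[length(ld)] - ld[1L])
  dose_grid(raw_doses, x)
}

#' Construct a dose grid
#'
#' Low-level constructor pairing raw doses with standardized doses.  Most
#' users should call [standardize_doses()]; this constructor exists for the
#' case where a trial protocol states the standardized grid directly (e.g.
#' exactly `c(0, 0.2, 0.4, 0.6, 0.8, 1)`).
#'
#' @param raw_doses Strictly increasing positive raw doses.
#' @param std_doses Strictly increasing standardized doses in `[0, 1]`, with
#'   endpoints 0 and 1, same length as `raw_doses`.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(raw_doses, std_doses) {
  if (length(raw_doses) != length(std_doses))
    stop("raw and standardized doses must have the same length", call. = FALSE)
  if (any(diff(std_doses) <= 0))
    stop("standardized doses must be strictly increasing", call. = FALSE)
  J <- length(std_doses)
  if (J >= 2 && (abs(std_doses[1L]) > 1e-12 || abs(std_doses[J] - 1) > 1e-12))
    stop("standardized doses must start at 0 and end at 1", call. = FALSE)
  structure(list(raw_doses = as.numeric(raw_doses),
                 std_doses = as.numeric(std_doses),
                 J = J),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid (", x$J, " doses)\n", sep = "")
  print(data.frame(level = seq_len(x$J), raw = x$raw_doses,
                   std = round(x$std_doses, 4)), row.names = FALSE)
  invisible(x)
}

#' Default six-level dose grid
#'
#' The grid used throughout the simulation study: raw doses
#' `{1, 2.5, 6.3, 15.8, 39.8, 100} x 1e6` cells, whose standardized values
#' are exactly `{0, 0.2, 0.4, 0.6, 0.8, 1}` to within printing precision.
#' The exact one-decimal grid is used, as in the trial protocol.
#'
#' @return A `dose_grid` with 6 levels.
#' @export
default_grid <- function() {
  dose_grid(c(1, 2.5, 6.3, 15.8, 39.8, 100) * 1e6,
            c(0, 0.2, 0.4, 0.6, 0.8, 1))
}
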