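#' Accumulated trial data
#'
#' Ordered patient records for a (possibly multi-stage) trial: for each
#' patient the assigned dose level, the manufacturing stage under which
#' their product was made, and the binary toxicity and efficacy outcomes.
#'
#' @param dose Integer vector of dose levels (1-based indices into the
#'   dose grid).
#' @param stage Integer vector of stage labels, nondecreasing in patient
#'   order.
#' @param yT,yE Binary outcome indicators.
#' @param J Number of dose levels in the grid.
#' @return A `trial_data` object: data frame `records` plus `stage_sizes`.
#' @export
trial_data <- function(dose = integer(), stage = integer(),
                       yT = integer(), yE = integer(), J = 6L) {
  n <- length(dose)
  stopifnot(length(stage) == n, length(yT) == n, length(yE) == n)
  if (n > 0) {
    if (any(dose < 1 | dose > J)) stop("dose index outside grid", call. = FALSE)
    if (any(diff(stage) < 0))
      stop("stage labels must be nondecreasing in patient order", call. = FALSE)
    if (!all(yT %in% c(0, 1)) || !all(yE %in% c(0, 1)))
      stop("outcomes must be binary", call. = FALSE)
  }
  records <- data.frame(patient = seq_len(n), dose = as.integer(dose),
                        stage = as.integer(stage), yT = as.integer(yT),
                        yE = as.integer(yE))
  structure(list(records = records,
                 stage_sizes = if (n) as.integer(table(factor(stage,
                   levels = seq_len(max(stage))))) else integer(),
                 J = as.integer(J)),
            class = "trial_data")
}

#' Append one cohort of records to trial data
#' @noRd
append_records <- function(data, dose, stage, yT, yE) {
  trial_data(c(data$records$dose, dose), c(data$records$stage, stage),
             c(data$records$yT, yT), c(data$records$yE, yE), J = data$J)
}

#' Outcome-cell counts, stages 1..K by dose by (yT, yE) cell
#'
#' Cell order within a dose is `yT + 2*yE`: (0,0), (1,0), (0,1), (1,1).
#' @noRd
count_array <- function(data, K) {
  cnt <- integer(K * data$J * 4L)
  r <- data$records
  if (nrow(r)) {
    idx <- (r$stage - 1L) * data$J * 4L + (r$dose - 1L) * 4L +
      r$yT + 2L * r$yE + 1L
    tab <- table(idx)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  cnt
}
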