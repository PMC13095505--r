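# Helper: marginals object with fixed per-draw probabilities per dose.
fixed_marginals <- function(piT, piE, n = 1000L) {
  J <- length(piT)
  list(piT = matrix(piT, n, J, byrow = TRUE),
       piE = matrix(piE, n, J, byrow = TRUE),
       utility = matrix(true_mean_utility(piT, piE), n, J, byrow = TRUE))
}

test_that("vacuous cutoffs admit every dose; point masses obey the rules", {
  # interior exceedances (jittered posterior) so the strict inequalities
  # against the boundary cutoffs are vacuous
  set.seed(1)
  mj <- fixed_marginals(c(0.1, 0.2, 0.5), c(0.1, 0.4, 0.6), n = 200L)
  mj$piT <- mj$piT + matrix(rnorm(600, 0, 0.3), 200)
  mj$piE <- mj$piE + matrix(rnorm(600, 0, 0.3), 200)
  vac <- list(pi_bar_T = 0.3, pi_low_E = 0.2, c_T = 1, c_E = 0,
              utility = utility_table())
  expect_identical(admissible_set(NULL, 1, vac, marginals = mj), 1:3)
  m <- fixed_marginals(c(0.1, 0.2, 0.5), c(0.1, 0.4, 0.6))
  cfg <- design_config()
  # dose 3: Pr(piT > 0.3) = 1 >= 0.70 -> excluded; dose 1: futile
  expect_identical(admissible_set(NULL, 1, cfg, marginals = m), 2L)
  # blacklist and futility exemption compose
  expect_identical(admissible_set(NULL, 1, cfg, blacklist = 2L,
                                  marginals = m), integer(0))
  expect_identical(admissible_set(NULL, 1, cfg, futility_exempt = 1L,
                                  marginals = m), 1:2)
})

test_that("stochastic exceedance respects the cutoff on constructed draws", {
  set.seed(2)
  n <- 2000
  # dose 2 exceeds the toxicity limit in exactly 75% of draws
  piT <- cbind(rep(0.1, n), ifelse(seq_len(n) <= 0.75 * n, 0.5, 0.1))
  m <- list(piT = piT, piE = matrix(0.6, n, 2),
            utility = matrix(50, n, 2))
  base <- list(pi_bar_T = 0.3, pi_low_E = 0.2, c_E = 0.15,
               utility = utility_table())
  cfg70 <- c(base, list(c_T = 0.70))
  cfg80 <- c(base, list(c_T = 0.80))
  expect_identical(admissible_set(NULL, 1, cfg70, marginals = m), 1L)
  expect_identical(admissible_set(NULL, 1, cfg80, marginals = m), 1:2)
})

test_that("admissibility is monotone in the cutoffs", {
  set.seed(14)
  for (i in 1:30) {
    m <- fixed_marginals(runif(6, 0, 0.6), runif(6, 0, 0.8),
                         n = 50L)
    # jitter draws so exceedances are interior
    m$piT <- m$piT + matrix(rnorm(300, 0, 0.1), 50)
    m$piE <- m$piE + matrix(rnorm(300, 0, 0.1), 50)
    c1 <- list(pi_bar_T = 0.3, pi_low_E = 0.2, c_T = runif(1, 0.2, 0.9),
               c_E = runif(1, 0.05, 0.6), utility = utility_table())
    c2 <- c1; c2$c_T <- min(c1$c_T + 0.2, 0.999); c2$c_E <- c1$c_E * 0.5
    A1 <- admissible_set(NULL, 1, c1, marginals = m)
    A2 <- admissible_set(NULL, 1, c2, marginals = m)
    expect_true(all(A1 %in% A2))
  }
})

test_that("greedy selection maximizes utility under the no-skip rule", {
  u <- c(40, 45, 50, 55, 60, 58)
  expect_identical(select_next_dose(1:6, u, highest_tried = 2L), 3L)
  expect_identical(select_next_dose(1:6, u, highest_tried = 5L), 5L)
  # low-dose tie break
  expect_identical(select_next_dose(1:2, c(50, 50), highest_tried = 2L), 1L)
  # empty admissible set or nothing assignable terminates
  expect_identical(select_next_dose(integer(), u, 3L), NA_integer_)
  expect_identical(select_next_dose(5:6, u, highest_tried = 2L), NA_integer_)
})

test_that("the no-skip rule is never violated across randomized states", {
  set.seed(99)
  bad <- 0L
  for (i in 1:10000) {
    A <- sort(sample.int(6, sample.int(6, 1)))
    u <- runif(6, 0, 100)
    h <- sample(0:6, 1)
    d <- select_next_dose(A, u, h)
    ok <- if (!is.na(d)) (d <= h + 1L) && (d %in% A)
    else length(A[A <= h + 1L]) == 0L
    if (!ok) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("candidate sets rank admissible doses by utility", {
  u <- c(70, 60, 50, 65, 40, 30)
  expect_identical(candidate_set(3:5, u, 2L), c(4L, 3L))
  expect_identical(candidate_set(2L, u, 3L), 2L)
  expect_identical(candidate_set(integer(), u, 2L), integer())
  # ties resolve toward the lower dose
  expect_identical(candidate_set(1:3, c(50, 50, 50), 2L), c(1L, 2L))
})

test_that("adaptive randomization probabilities follow the power rule", {
  expect_equal(ar_probabilities(c(60, 40), kappa = 1), c(0.6, 0.4))
  expect_equal(ar_probabilities(c(10, 70, 20), kappa = 0), rep(1 / 3, 3))
  expect_equal(ar_probabilities(55, kappa = 1), 1)
  expect_equal(sum(ar_probabilities(c(33.3, 44.4, 22.2), kappa = 2.5)), 1,
               tolerance = 1e-12)
  # zero-utility candidates get exactly zero unless all are zero
  expect_equal(ar_probabilities(c(0, 50), kappa = 1), c(0, 1))
  expect_warning(p0 <- ar_probabilities(c(0, 0), kappa = 1), "uniform")
  expect_equal(p0, c(0.5, 0.5))
})

test_that("randomization sharpens with kappa and respects utility order", {
  u <- c(62, 55, 48)
  p1 <- ar_probabilities(u, 1)
  expect_true(all(diff(p1) < 0))
  # monotone in a candidate's utility
  p_up <- ar_probabilities(c(70, 55, 48), 1)
  expect_gt(p_up[1], p1[1])
  # large kappa concentrates on the maximum
  expect_gt(ar_probabilities(u, 200)[1], 0.99)
})
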