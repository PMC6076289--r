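rand_lrc <- function(n = 3, seed = 1) {
  set.seed(seed)
  local_response_matrix(matrix(rnorm(n * n), n, n))
}

two_cond_set <- function(seed = 1, rho = FALSE) {
  mk <- function(s) {
    cc <- list(r = rand_lrc(seed = s))
    if (rho) cc$rho <- exp(rnorm(3, 0, 0.3))
    cc
  }
  set.seed(seed + 100)
  response_set(list(c1 = mk(seed), c2 = mk(seed + 1)))
}

test_that("response sets validate their structure", {
  bad <- matrix(0, 3, 3) # diagonal not -1
  expect_error(response_set(list(a = list(r = bad))), "diagonal")
  expect_error(response_set(list(list(r = unclass(rand_lrc())))), "named")
  expect_error(response_set(list(a = list(r = unclass(rand_lrc()),
                                          rho = c(1, -2)))), "positive")
})

test_that("overall distance: identity, norm cancellation, homogeneity", {
  obs <- two_cond_set(seed = 2, rho = TRUE)
  expect_equal(overall_distance(obs, obs), 0)
  # a zero off-diagonal prediction contributes exactly 1 per r block
  zero <- response_set(list(
    c1 = list(r = local_response_matrix(matrix(0, 3, 3)),
              rho = obs$conditions$c1$rho),
    c2 = list(r = local_response_matrix(matrix(0, 3, 3)),
              rho = obs$conditions$c2$rho)))
  expect_equal(overall_distance(obs, zero), 2)
  # doubling observed and simulated r together leaves the r term unchanged
  norho <- two_cond_set(seed = 5)
  sim <- two_cond_set(seed = 9)
  dbl <- function(rs) { # double every off-diagonal entry
    for (nm in names(rs$conditions)) {
      r2 <- 2 * unclass(rs$conditions[[nm]]$r)
      diag(r2) <- -1
      rs$conditions[[nm]]$r <- local_response_matrix(r2)
    }
    rs
  }
  expect_equal(overall_distance(dbl(norho), dbl(sim)),
               overall_distance(norho, sim), tolerance = 1e-12)
  # missing conditions are named in the error
  expect_error(
    overall_distance(obs, response_set(list(c1 = obs$conditions$c1))),
    "c2")
})

test_that("augmented distance adds time-course and vanishing-rate blocks", {
  obs_tc <- data.frame(time = rep(c(0, 5, 10), 2),
                       species = rep(c("A", "B"), each = 3),
                       value = c(0, 2, 1, 0, 4, 3))
  obs <- response_set(list(c1 = list(r = rand_lrc(seed = 3),
                                     timecourse = obs_tc,
                                     pss_times = 5)))
  sim_same <- response_set(list(c1 = list(r = obs$conditions$c1$r,
                                          timecourse = obs_tc,
                                          rates = c(0, 0, 0))))
  expect_equal(augmented_distance(obs, sim_same), 0)
  # rate block is the Euclidean norm of the model rates at the pss times
  sim_rates <- sim_same
  sim_rates$conditions$c1$rates <- c(3, 4, 0)
  expect_equal(augmented_distance(obs, sim_rates), 5)
  # time-course block is normalised by the observed-side norm
  sim_tc <- sim_same
  sim_tc$conditions$c1$timecourse$value <- obs_tc$value * 2
  expect_equal(augmented_distance(obs, sim_tc), 1, tolerance = 1e-12)
  # mismatched grids are refused
  sim_bad <- sim_same
  sim_bad$conditions$c1$timecourse <- obs_tc[-1, ]
  expect_error(augmented_distance(obs, sim_bad), "grids")
  sim_norates <- sim_same
  sim_norates$conditions$c1$rates <- NULL
  expect_error(augmented_distance(obs, sim_norates), "rates")
})

test_that("rate block vanishes at a true steady state", {
  m <- linear_2node_model()
  ss <- find_steady_state(m, x0 = c(0, 0))
  rates <- model_rate(m, ss$state)
  obs <- response_set(list(c1 = list(r = rand_lrc(2, seed = 4),
                                     pss_times = 0)))
  sim <- response_set(list(c1 = list(r = obs$conditions$c1$r,
                                     rates = rates)))
  expect_lt(augmented_distance(obs, sim), 1e-8)
})

test_that("weighted-norm triangle-type inequality holds on random sets", {
  set.seed(31)
  for (i in 1:10) {
    a <- two_cond_set(seed = i, rho = TRUE)
    b <- two_cond_set(seed = i + 50, rho = TRUE)
    c_ <- two_cond_set(seed = i + 90, rho = TRUE)
    lhs <- overall_distance(a, c_)
    # middle term re-weighted by a's norms, per block
    mid <- 0
    for (nm in names(a$conditions)) {
      n_r <- sqrt(sum(offdiag(a$conditions[[nm]]$r)^2))
      mid <- mid + sqrt(sum((offdiag(b$conditions[[nm]]$r) -
                               offdiag(c_$conditions[[nm]]$r))^2)) / n_r
      n_rho <- sqrt(sum(a$conditions[[nm]]$rho^2))
      mid <- mid + sqrt(sum((b$conditions[[nm]]$rho -
                               c_$conditions[[nm]]$rho)^2)) / n_rho
    }
    expect_lte(lhs, overall_distance(a, b) + mid + 1e-12)
  }
})

test_that("distance is invariant to amplification and replicate count at sigma 0", {
  d1 <- simulate_experiment(egf_builder(), doses = c(0.1, 1), sigma = 0,
                            k_f = 10, n_replicates = 2, seed = 4)
  d2 <- simulate_experiment(egf_builder(), doses = c(0.1, 1), sigma = 0,
                            k_f = 1000, n_replicates = 6, seed = 44)
  rs1 <- estimate_response_set(d1)
  rs2 <- estimate_response_set(d2)
  expect_lt(overall_distance(rs1, rs2), 1e-7)
})

test_that("constraint-point bookkeeping counts data, not definitions", {
  r3 <- rand_lrc(3, seed = 6)
  rs <- response_set(list(
    EGF = list(r = r3, pss_times = 5),
    NGF = list(r = rand_lrc(3, seed = 7), pss_times = 15)))
  # two 3x3 LRC matrices contribute 6 off-diagonals each; one vanishing-rate
  # time per condition contributes 3 rates each
  expect_identical(feature_count(rs), 18L)
  rs2 <- response_set(list(a = list(r = r3, rho = c(1, 2, 3))))
  expect_identical(feature_count(rs2), 9L)
})
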