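# A cheap deterministic toy evaluator: distance of log-parameters to a
# fixed target point.
toy_evaluator <- function(target) {
  function(theta) {
    list(distance = sqrt(sum((log(theta) - log(target))^2)), features = NULL)
  }
}

test_that("prior draws respect support, spread and seeding", {
  pri <- prior_spec(c(k1 = 2, k2 = 0.5), scale = 1.5)
  set.seed(1)
  x <- sample_prior(pri, 500)
  expect_true(all(x > 0))
  expect_identical(colnames(x), c("k1", "k2"))
  # vanishing spread concentrates on the location
  tight <- prior_spec(c(k1 = 2.3), scale = 1e-9)
  set.seed(2)
  expect_equal(unname(sample_prior(tight, 5)[, 1]), rep(2.3, 5),
               tolerance = 1e-6)
  # the natural-scale location is the log-normal median
  set.seed(3)
  big <- sample_prior(prior_spec(c(k = 2.3), scale = 2), 1e5)
  expect_equal(median(big), 2.3, tolerance = 0.02 * 2.3)
  # normal-prior parameters live on the natural scale
  gn <- prior_spec(c(mu = -3), scale = 0.5, dist = "normal")
  set.seed(4)
  g <- sample_prior(gn, 1e4)
  expect_equal(mean(g), -3, tolerance = 0.05)
  expect_error(prior_spec(c(a = -1)), "positive")
})

test_that("threshold schedule is the quantile of accepted distances", {
  expect_equal(epsilon_schedule(c(1, 2, 3, 4), 0.5), 2.5)
  expect_lte(epsilon_schedule(c(1, 2, 3, 4), 0.9), 4)
  expect_error(epsilon_schedule(c(2, 2, 2), 0.5), "degenerate")
  expect_error(epsilon_schedule(c(1, 2), 1.5), "alpha")
})

test_that("first stage accepts prior draws below eps1 with equal weights", {
  pri <- mapk_egf_prior()
  ev <- toy_evaluator(mapk_egf_parameters())
  ens <- initial_stage(pri, ev, eps1 = Inf, n_abc = 50, n_batch = 25,
                       seed = 11)
  expect_identical(ens$n_abc, 50L)
  expect_equal(ens$weights, rep(1 / 50, 50))
  expect_true(all(is.finite(ens$distances)))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  # a finite eps1 is enforced strictly
  ens2 <- initial_stage(pri, ev, eps1 = median(ens$distances), n_abc = 20,
                        n_batch = 50, seed = 11)
  expect_true(all(ens2$distances < median(ens$distances)))
  # an unsatisfiable threshold aborts with a diagnostic
  expect_error(
    initial_stage(pri, ev, eps1 = 1e-8, n_abc = 10, n_batch = 100,
                  seed = 1, min_acceptance = 1e-2),
    "acceptance rate")
})

test_that("batch evaluation is reproducible regardless of worker count", {
  pri <- prior_spec(c(a = 1, b = 1), scale = 1)
  noisy_ev <- function(theta) {
    # deliberately stochastic evaluator: exercises the per-particle seeding
    list(distance = abs(log(theta[1]) + rnorm(1, 0, 0.1)), features = NULL)
  }
  e1 <- initial_stage(pri, noisy_ev, n_abc = 30, n_batch = 15, seed = 21,
                      n_workers = 1)
  e2 <- initial_stage(pri, noisy_ev, n_abc = 30, n_batch = 15, seed = 21,
                      n_workers = 2)
  expect_equal(e1$distances, e2$distances)
  expect_equal(e1$theta, e2$theta)
})

test_that("refinement stages enforce the threshold contract", {
  pri <- prior_spec(c(a = 1, b = 1), scale = 1)
  ev <- toy_evaluator(c(a = 1, b = 1))
  ens <- initial_stage(pri, ev, n_abc = 60, n_batch = 60, seed = 5)
  eps2 <- epsilon_schedule(ens$distances, 0.5)
  s2 <- smc_stage(ens, eps2, ev, pri, seed = 6, n_batch = 60)
  expect_true(all(s2$distances < eps2))
  expect_equal(sum(s2$weights), 1, tolerance = 1e-12)
  expect_identical(s2$stage, 2L)
  expect_error(smc_stage(ens, ens$epsilon + 1, ev, pri, seed = 1),
               "decrease")
})

test_that("importance weights match a brute-force evaluation of the formula", {
  pri <- prior_spec(c(a = 2, b = 3), scale = 1)
  ev <- toy_evaluator(c(a = 2, b = 3))
  prev <- initial_stage(pri, ev, n_abc = 40, n_batch = 40, seed = 31)
  scales <- c(0.4, 0.6)
  eps2 <- epsilon_schedule(prev$distances, 0.5)
  s2 <- smc_stage(prev, eps2, ev, pri, kernel_scales = scales, seed = 32,
                  n_batch = 40, defensive = 0, kc_bandwidth = Inf)
  # naive recomputation: w_k = prior(z_k) / sum_j w_j N(z_k; z_j, D)
  z_prev <- log(prev$theta)
  z_new <- log(s2$theta)
  w_naive <- numeric(nrow(z_new))
  for (k in seq_len(nrow(z_new))) {
    pr <- prod(dnorm(z_new[k, ], log(c(2, 3)), c(1, 1)))
    denom <- 0
    for (j in seq_len(nrow(z_prev))) {
      denom <- denom + prev$weights[j] *
        prod(dnorm(z_new[k, ], z_prev[j, ], scales))
    }
    w_naive[k] <- pr / denom
  }
  w_naive <- w_naive / sum(w_naive)
  expect_equal(s2$weights, w_naive, tolerance = 1e-8)
})

test_that("full runs are seed-reproducible and stochastically contract", {
  pri <- prior_spec(c(a = 1, b = 1, c = 1), scale = 1)
  ev <- toy_evaluator(c(a = 2, b = 0.5, c = 1))
  r1 <- run_abc_smc(ev, pri, n_abc = 60, n_batch = 60, max_stages = 5,
                    seed = 41, pilot = 0)
  r2 <- run_abc_smc(ev, pri, n_abc = 60, n_batch = 60, max_stages = 5,
                    seed = 41, pilot = 0)
  expect_equal(r1$final$theta, r2$final$theta)
  expect_equal(r1$epsilons, r2$epsilons)
  meds <- vapply(r1$history, function(h) median(h$distances), numeric(1))
  expect_true(all(diff(meds) <= 0))
  expect_true(all(diff(r1$epsilons[-1]) < 0))
})

test_that("posterior concentrates on identifiable features of the 2-node chain", {
  # data: noise-free steady state of the chain at known parameters; the
  # evaluator matches relative steady concentrations, which pins u/a (= x1)
  # and b/c (= x2/x1)
  truth <- c(u = 2, a = 1, b = 3, c = 2)
  x_true <- c(2, 3)
  ev <- function(theta) {
    m <- linear_2node_model(theta[["u"]], theta[["a"]], theta[["b"]],
                            theta[["c"]])
    ss <- find_steady_state(m, x0 = c(0, 0))
    if (!isTRUE(ss$converged)) return(list(distance = Inf))
    list(distance = sqrt(sum(((ss$state - x_true) / x_true)^2)),
         features = NULL)
  }
  pri <- prior_spec(c(u = 2, a = 2, b = 2, c = 2), scale = 1)
  res <- run_abc_smc(ev, pri, n_abc = 150, n_batch = 150, max_stages = 6,
                     seed = 51, pilot = 0)
  ratio <- mean(res$final$theta[, "b"] / res$final$theta[, "c"])
  expect_lt(abs(ratio - 1.5) / 1.5, 0.2)
})

test_that("stage persistence round-trips and runs resume deterministically", {
  pri <- prior_spec(c(a = 1, b = 1), scale = 1)
  ev <- toy_evaluator(c(a = 2, b = 1))
  d_full <- file.path(tempdir(), "abc_full")
  d_part <- file.path(tempdir(), "abc_part")
  unlink(c(d_full, d_part), recursive = TRUE)
  r_full <- run_abc_smc(ev, pri, n_abc = 40, n_batch = 40, max_stages = 4,
                        seed = 61, pilot = 0, out_dir = d_full)
  expect_true(file.exists(file.path(d_full, "run_manifest.json")))
  expect_length(list.files(d_full, pattern = "^stage_"), 4)
  # replay the first two stages, then resume to the same endpoint
  dir.create(d_part)
  for (f in c("stage_001.csv", "stage_002.csv")) {
    file.copy(file.path(d_full, f), file.path(d_part, f))
  }
  r_res <- run_abc_smc(ev, pri, n_abc = 40, n_batch = 40, max_stages = 4,
                       seed = 61, pilot = 0, out_dir = d_part, resume = TRUE)
  expect_equal(r_res$final$epsilon, r_full$final$epsilon, tolerance = 1e-10)
  expect_equal(r_res$final$theta, r_full$final$theta, tolerance = 1e-8)
})
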