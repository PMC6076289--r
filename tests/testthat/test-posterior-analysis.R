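make_identical_ensemble <- function(theta, n = 5, evaluator = NULL) {
  th <- matrix(rep(theta, each = n), n, length(theta),
               dimnames = list(NULL, names(theta)))
  feats <- NULL
  if (!is.null(evaluator)) feats <- lapply(seq_len(n),
                                           function(i) evaluator(theta)$features)
  structure(list(stage = 1L, theta = th, distances = rep(0, n),
                 weights = rep(1 / n, n), epsilon = Inf, features = feats,
                 acceptance = 1, n_abc = n),
            class = "particle_ensemble")
}

test_that("identical particles predict with zero standard error and -1 diagonals", {
  obs <- standard_response_set(sigma = 0, seed = 101)
  ev <- mapk_egf_evaluator(obs)
  ens <- make_identical_ensemble(mapk_egf_parameters(), n = 4, evaluator = ev)
  pred <- predict_features(ens)
  for (nm in names(pred$conditions)) {
    pc <- pred$conditions[[nm]]
    expect_equal(unname(diag(pc$r_mean)), rep(-1, 3))
    expect_true(all(pc$r_se < 1e-12))
    if (!is.null(pc$rho_se)) expect_true(all(pc$rho_se < 1e-12))
  }
  expect_identical(pred$n_failed, 0L)
  # the true-parameter ensemble reproduces the noise-free data features to
  # within the finite-knockdown bias
  expect_lt(ssq_fit_error(obs, pred), 0.1)
})

test_that("sum-of-squares fit error on plain response sets", {
  r <- local_response_matrix(rbind(c(-1, 1), c(2, -1)))
  obs <- response_set(list(a = list(r = r, rho = c(1, 2))))
  expect_equal(ssq_fit_error(obs, obs), 0)
  pred <- response_set(list(a = list(r = local_response_matrix(
    rbind(c(-1, 0), c(0, -1))), rho = c(1, 2))))
  expect_equal(ssq_fit_error(obs, pred), 5) # (1-0)^2 + (2-0)^2
  expect_error(ssq_fit_error(obs, response_set(list(b = list(r = r)))),
               "missing condition a")
})

test_that("steady-state dose response of the cascade rises sigmoidally", {
  doses <- c(0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8, 25.6, 51.2, 102.4)
  ens <- make_identical_ensemble(mapk_egf_parameters(), n = 2)
  dr <- dose_response(ens, function(theta, dose) {
    build_mapk_egf_model(theta, egf = dose)
  }, doses)
  expect_equal(nrow(dr), length(doses))
  expect_true(all(diff(dr$mean) >= -1e-8)) # monotone nondecreasing
  expect_true(all(dr$se < 1e-10))
  expect_true(all(dr$lo67 <= dr$mean + 1e-12 & dr$mean <= dr$hi67 + 1e-12))
  # a 4-parameter logistic explains the curve better than a straight line
  sig <- sigmoid_fit(dr$dose, dr$mean)
  lin <- sum(resid(lm(mean ~ dose, data = dr))^2)
  expect_lt(sig$ssq, lin)
})

test_that("dose zero leaves starved cells inactive", {
  ss <- find_steady_state(build_mapk_egf_model(egf = 0))
  expect_equal(unname(ss$state), c(0, 0, 0))
})

test_that("wash-out simulations are continuous and eventually decay", {
  p <- eq8_demo_parameters()
  builder <- function(theta, dose) {
    build_mapk_egf_ngf_model(p, eq8_demo_totals(), "EGF", dose = dose)
  }
  ens <- make_identical_ensemble(p, n = 2)
  times <- seq(0, 60, by = 1)
  wo <- washout_timecourse(ens, builder, dose = 2, neutralize_at = 10,
                           times = times)
  expect_equal(nrow(wo), length(times))
  # continuity at the switch: neighbouring samples around t = 10 are close
  i <- which(times == 10)
  expect_lt(abs(wo$mean[i + 1] - wo$mean[i]),
            5 * max(abs(diff(wo$mean[1:(i - 1)]))) + 1e-9)
  # after the RAS pulse has decayed, active ERK only falls
  late <- wo$mean[times >= 30]
  expect_true(all(diff(late) <= 1e-8))
  expect_gt(max(wo$mean), 0) # the pulse did activate the cascade
  # neutralising at t = 0 from the starved state keeps everything at zero
  flat <- washout_timecourse(ens, builder, dose = 2, neutralize_at = 0,
                             times = seq(0, 20, by = 5))
  expect_true(all(abs(flat$mean) < 1e-10))
})

test_that("modality analysis separates unimodal from bimodal populations", {
  set.seed(77)
  uni <- rnorm(1000)
  res_uni <- modality_analysis(uni)
  expect_identical(res_uni$n_modes, 1L)
  mix <- c(rnorm(500, 0, 1), rnorm(500, 10, 1))
  res_mix <- modality_analysis(mix)
  expect_identical(res_mix$n_modes, 2L)
  expect_identical(res_mix$n_components, 2L)
  expect_equal(sort(res_mix$modes), c(0, 10), tolerance = 0.5)
  # the KDE is a proper density
  dx <- diff(res_mix$density$x[1:2])
  expect_equal(sum(res_mix$density$y) * dx, 1, tolerance = 1e-3)
  # the 2-component fit can never be worse than the 1-component fit by more
  # than numerical noise
  expect_lte(res_mix$ssq[["two"]], res_mix$ssq[["one"]] + 1e-10)
  expect_error(modality_analysis(rep(3, 100)), "zero variance")
  expect_error(modality_analysis(rnorm(10)), "at least 50")
})

test_that("modality calls agree with an independent mixture-model oracle", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(require(mclust, quietly = TRUE))
  set.seed(88)
  cases <- list(unimodal = rnorm(600, 5, 2),
                bimodal = c(rnorm(300, 0, 0.7), rnorm(300, 6, 0.7)))
  for (nm in names(cases)) {
    ours <- modality_analysis(cases[[nm]])$n_modes
    bic <- mclust::Mclust(cases[[nm]], G = 1:2, verbose = FALSE)$G
    expect_identical(ours, as.integer(bic))
  }
})
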