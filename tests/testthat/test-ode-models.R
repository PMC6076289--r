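test_that("Michaelis-Menten building blocks evaluate and validate", {
  expect_equal(michaelis_activation(k = 1, K = 10, S = 10, M = 1), 0.5)
  expect_equal(michaelis_activation(k = 1, K = 10, S = 0, M = 5), 0)
  expect_equal(michaelis_activation(k = 0.1, K = 10, S = 90, M = 2), 0.18)
  expect_equal(michaelis_decay(V = 2, K = 10, S = 10), 1)
  expect_equal(michaelis_decay(V = 10, K = 10, S = 0), 0)
  expect_equal(michaelis_decay(V = 10, K = 10, S = 90), 9)
  expect_error(michaelis_activation(1, 0, 1, 1), "positive")
  expect_error(michaelis_decay(1, -1, 1), "positive")
  # monotone increasing in substrate and modifier
  s <- seq(0, 50, by = 5)
  expect_true(all(diff(michaelis_activation(1, 10, s, 2)) > 0))
  expect_true(all(diff(michaelis_activation(1, 10, 5, s)) >= 0))
})

test_that("EGF cascade model: bookkeeping, starved fixed point, validation", {
  m <- build_mapk_egf_model(egf = 0)
  expect_s3_class(m, "rate_model")
  expect_identical(n_unknowns(m), 16L)
  expect_length(m$parameters, 16)
  # no ligand, no activity: starved state is a fixed point
  expect_equal(model_rate(m, c(0, 0, 0)), c(aRAF = 0, aMEK = 0, aERK = 0))
  p <- mapk_egf_parameters()
  expect_error(build_mapk_egf_model(p[-1], egf = 1), "missing")
  expect_error(build_mapk_egf_model(p, totals = c(RAF_TOT = -1, MEK_TOT = 1,
                                                  ERK_TOT = 1)), "positive")
  expect_error(build_mapk_egf_model(p, egf = -2), "nonnegative")
})

test_that("EGF cascade steady state matches an independent stiff integrator", {
  m <- build_mapk_egf_model(egf = 0.1)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  # independent route: pure-R rate function through a different integrator
  oracle <- deSolve::ode(
    y = c(0, 0, 0), times = c(0, 1e5),
    func = function(t, y, parms) list(m$rate(y, t)),
    method = "radau", rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(ss$state), unname(oracle[2, 2:4]), tolerance = 1e-6)
})

test_that("trajectories started inside [0, totals] stay inside the box", {
  set.seed(42)
  for (i in 1:5) {
    theta <- sample_prior(mapk_egf_prior(), 1)[1, ]
    m <- build_mapk_egf_model(theta, egf = runif(1, 0.1, 5))
    x0 <- runif(3, 0, 1) * m$totals
    tc <- simulate_timecourse(m, seq(0, 100, by = 20), x0 = x0)
    vals <- as.matrix(tc[, -1])
    expect_true(all(vals >= -1e-6))
    expect_true(all(sweep(vals, 2, m$totals, `-`) <= 1e-6))
  }
})

test_that("numerical Jacobian of the cascade agrees with a complex-step oracle", {
  p <- mapk_egf_parameters()
  tot <- mapk_default_totals()
  egf <- 0.5
  # test-side copy of the rate equations in plain arithmetic so that
  # complex-step differentiation applies
  rate_cplx <- function(x) {
    ma <- function(k, K, S, M) k * S * M / (K + S)
    m0 <- function(V, K, S) V * S / (K + S)
    c(ma(p["k_f1"], p["K_mf1"], tot[1] - x[1], egf) -
        ma(p["k_r1"], p["K_mr1"], x[1], x[3]) -
        m0(p["V_m1"], p["K_m1"], x[1]),
      ma(p["k_f2"], p["K_mf2"], tot[2] - x[2], x[1]) -
        ma(p["k_r2"], p["K_mr2"], x[2], x[3]) -
        m0(p["V_m2"], p["K_m2"], x[2]),
      ma(p["k_f3"], p["K_mf3"], tot[3] - x[3], x[2]) -
        m0(p["V_m3"], p["K_m3"], x[3]))
  }
  m <- build_mapk_egf_model(p, tot, egf = egf)
  set.seed(7)
  for (i in 1:3) {
    x <- runif(3, 0.5, 50)
    J <- numerical_jacobian(m, x)
    h <- 1e-20
    J_cs <- sapply(1:3, function(j) {
      xc <- as.complex(x)
      xc[j] <- xc[j] + h * 1i
      Im(rate_cplx(xc)) / h
    })
    expect_equal(unname(J), unname(J_cs), tolerance = 1e-6)
  }
})

test_that("RAS input pulse: boundary, peak location and value", {
  expect_equal(ras_input(1, 1, 0), 0)
  # unimodal with maximum at t = 5/kd
  for (kd in c(0.5, 1, 2)) {
    tpk <- 5 / kd
    expect_gt(ras_input(1, kd, tpk), ras_input(1, kd, tpk * 0.9))
    expect_gt(ras_input(1, kd, tpk), ras_input(1, kd, tpk * 1.1))
  }
  expect_equal(ras_input(1, 1, 5), 0.5 * 5^5 * exp(-5), tolerance = 1e-10)
  expect_equal(ras_input(1, 1, 5), 10.52804, tolerance = 1e-5)
  expect_error(ras_input(1, 1, -1), "nonnegative")
  expect_error(ras_input(-1, 1, 1), "nonnegative")
  expect_error(ras_input(1, 0, 1), "positive")
})

test_that("EGF/NGF cascade: ligand flags, unknown count, dose-0 quiescence", {
  p <- eq8_demo_parameters()
  m_egf <- build_mapk_egf_ngf_model(p, eq8_demo_totals(), "EGF", dose = 1)
  expect_identical(n_unknowns(m_egf), 27L)
  expect_length(mapk_egf_ngf_parameter_names(), 24)
  # with b_n = 0 the NGF-specific feedback/feedforward terms are inert
  p2 <- p
  p2[c("k_f14", "k_f32")] <- p2[c("k_f14", "k_f32")] * 100
  m_alt <- build_mapk_egf_ngf_model(p2, eq8_demo_totals(), "EGF", dose = 1)
  for (t in c(1, 5, 20)) {
    x <- c(3, 10, 40)
    expect_equal(model_rate(m_egf, x, t), model_rate(m_alt, x, t))
  }
  # and under NGF they are active
  m_ngf <- build_mapk_egf_ngf_model(p, eq8_demo_totals(), "NGF", dose = 1)
  m_ngf2 <- build_mapk_egf_ngf_model(p2, eq8_demo_totals(), "NGF", dose = 1)
  expect_false(isTRUE(all.equal(model_rate(m_ngf, c(3, 10, 40), 5),
                                model_rate(m_ngf2, c(3, 10, 40), 5))))
  # dose 0 from the starved state never moves
  m0 <- build_mapk_egf_ngf_model(p, eq8_demo_totals(), "EGF", dose = 0)
  for (t in c(0, 2, 10)) {
    expect_equal(unname(model_rate(m0, c(0, 0, 0), t)), c(0, 0, 0))
  }
  expect_error(build_mapk_egf_ngf_model(p, eq8_demo_totals(), "TGF", 1))
})

test_that("native and pure-R rate evaluations agree along trajectories", {
  m <- build_mapk_egf_model(egf = 1)
  m_r <- m
  m_r$native <- NULL
  t1 <- simulate_timecourse(m, seq(0, 50, by = 10))
  t2 <- simulate_timecourse(m_r, seq(0, 50, by = 10))
  expect_equal(t1, t2, tolerance = 1e-8)
  p <- eq8_demo_parameters()
  mn <- build_mapk_egf_ngf_model(p, eq8_demo_totals(), "NGF", dose = 2)
  mn_r <- mn
  mn_r$native <- NULL
  t3 <- simulate_timecourse(mn, seq(0, 60, by = 15))
  t4 <- simulate_timecourse(mn_r, seq(0, 60, by = 15))
  expect_equal(t3, t4, tolerance = 1e-8)
})
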