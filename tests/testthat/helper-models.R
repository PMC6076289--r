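# Shared fixtures, all built in code.

# Open two-node linear chain: constant input u feeds node 1, node 1 feeds
# node 2, both decay linearly. Closed-form steady state (u/a, b*u/(a*c));
# constant Jacobian [[-a, 0], [b, -c]].
linear_2node_model <- function(u = 2, a = 1, b = 3, c = 2) {
  rate_model(
    species = c("n1", "n2"),
    rate = function(state, t = 0) {
      c(u - a * state[1], b * state[1] - c * state[2])
    },
    parameters = c(u = u, a = a, b = b, c = c),
    totals = c(n1 = 1e6, n2 = 1e6),
    label = "linear two-node chain"
  )
}

egf_builder <- function(parameters = mapk_egf_parameters(),
                        totals = mapk_default_totals()) {
  function(dose) build_mapk_egf_model(parameters, totals, egf = dose)
}

# A fixed, well-behaved parameterisation of the EGF/NGF cascade used by
# posterior-predictive tests (the study infers these from data; any stable
# positive set exercises the machinery).
eq8_demo_parameters <- function() {
  p <- stats::setNames(rep(2, 24), mapk_egf_ngf_parameter_names())
  p[grep("^K_m", names(p))] <- 10
  p[c("kd_egf", "kd_ngf")] <- c(1, 0.3)
  p
}

eq8_demo_totals <- function() c(RAF_TOT = 25, MEK_TOT = 100, ERK_TOT = 400)

# Cache expensive shared objects across tests within one run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

standard_egf_dataset <- function(sigma = 0, seed = 101) {
  cached(sprintf("egf_data_%g_%d", sigma, seed),
         simulate_experiment(egf_builder(), sigma = sigma, seed = seed))
}

standard_response_set <- function(sigma = 0, seed = 101) {
  cached(sprintf("egf_rs_%g_%d", sigma, seed),
         estimate_response_set(standard_egf_dataset(sigma, seed)))
}

# Full scaled fitting protocol used by the fit-quality checks: 200 particles,
# median threshold schedule, at most 10 stages. Returns the sum-of-squares
# fit error of the ensemble-mean features against the data-derived features.
fit_protocol_ssq <- function(sigma, prior_location, seed) {
  key <- sprintf("fit_%g_%g_%d", sigma, prior_location, seed)
  cached(key, {
    obs <- standard_response_set(sigma, seed)
    ev <- mapk_egf_evaluator(obs)
    res <- run_abc_smc(ev, mapk_egf_prior(location = prior_location),
                       n_abc = 200, n_batch = 200, alpha = 0.5,
                       max_stages = 10, seed = seed)
    ssq_fit_error(obs, predict_features(res$final))
  })
}
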