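# Adaptive-weight ABC-SMC: likelihood-free posterior sampling through a
# sequence of shrinking acceptance thresholds. Stage 1 filters prior draws;
# later stages resample ancestors with probability proportional to
# weight x closeness-kernel, perturb them with a component-wise Gaussian
# kernel (in log space for positive parameters), accept below the stage
# threshold, and reweight by the importance formula
# w_k ~ prior(theta_k) / sum_j w_j q(theta_k | theta_j).

#' Specify independent parameter priors
#'
#' Log-normal priors (the default, for strictly positive rate constants and
#' concentrations) are parameterised by a natural-scale median `location`
#' (so `meanlog = log(location)`) and log-scale standard deviation `scale`;
#' set `location_log = TRUE` to interpret `location` as `meanlog` directly.
#' Normal priors take `location`/`scale` as mean and sd.
#'
#' @param location Numeric vector of prior locations (recycled against
#'   `names`).
#' @param scale Numeric vector of prior scales (> 0), default 2.
#' @param dist `"lognormal"` or `"normal"`, per parameter.
#' @param names Parameter names; taken from `location` if named.
#' @param location_log For log-normal entries, whether `location` is already
#'   on the log scale.
#' @return data.frame of class `prior_spec` with columns `name`, `dist`,
#'   `mu`, `sigma` (`mu` on the proposal/internal scale: log scale for
#'   log-normal parameters).
#' @export
prior_spec <- function(location, scale = 2, dist = "lognormal",
                       names = NULL, location_log = FALSE) {
  if (is.null(names)) names <- base::names(location)
  if (is.null(names)) stop("parameter names are required")
  n <- length(names)
  location <- rep_len(as.numeric(location), n)
  scale <- rep_len(as.numeric(scale), n)
  dist <- rep_len(as.character(dist), n)
  if (!all(dist %in% c("lognormal", "normal"))) {
    stop("dist must be 'lognormal' or 'normal'")
  }
  if (any(scale <= 0)) stop("prior scale must be strictly positive")
  if (any(dist == "lognormal" & !location_log & location <= 0)) {
    stop("log-normal prior locations must be strictly positive")
  }
  mu <- ifelse(dist == "lognormal" & !location_log, log(location), location)
  structure(data.frame(name = names, dist = dist, mu = mu, sigma = scale,
                       stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Default prior for the EGF-driven MAPK model
#'
#' Log-normal priors with a common location for all 16 kinetic parameters
#' (the in-silico study uses location 2.3 and log-sd 2).
#'
#' @param location Natural-scale prior median (default 2.3).
#' @param scale Log-scale sd (default 2).
#' @return A [prior_spec()].
#' @export
mapk_egf_prior <- function(location = 2.3, scale = 2) {
  prior_spec(stats::setNames(rep(location, 16), .mapk_egf_par_names),
             scale = scale)
}

#' Default prior for the EGF/NGF MAPK model
#'
#' Log-normal priors for the 24 kinetic parameters (location 2, except 0.2
#' for the RAS pulse decay rates `kd_egf`/`kd_ngf`) and the three totals
#' (locations 25, 100, 400); log-sd 2 throughout. 27 unknowns in all.
#'
#' @return A [prior_spec()].
#' @export
mapk_egf_ngf_prior <- function() {
  nm <- c(.mapk_egf_ngf_par_names, "RAF_TOT", "MEK_TOT", "ERK_TOT")
  loc <- stats::setNames(rep(2, length(nm)), nm)
  loc[c("kd_egf", "kd_ngf")] <- 0.2
  loc[c("RAF_TOT", "MEK_TOT", "ERK_TOT")] <- c(25, 100, 400)
  prior_spec(loc, scale = 2)
}

#' Draw parameter vectors from a prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @return `n x p` matrix, columns named by parameter.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  p <- nrow(prior)
  draws <- matrix(stats::rnorm(n * p), n, p)
  draws <- sweep(sweep(draws, 2, prior$sigma, `*`), 2, prior$mu, `+`)
  ln <- prior$dist == "lognormal"
  draws[, ln] <- exp(draws[, ln, drop = FALSE])
  colnames(draws) <- prior$name
  draws
}

# natural <-> internal (proposal-space) coordinates
.to_internal <- function(prior, theta) {
  theta <- rbind(theta)[, prior$name, drop = FALSE]
  ln <- prior$dist == "lognormal"
  theta[, ln] <- log(theta[, ln, drop = FALSE])
  theta
}

.from_internal <- function(prior, z) {
  ln <- prior$dist == "lognormal"
  z[, ln] <- exp(z[, ln, drop = FALSE])
  colnames(z) <- prior$name
  z
}

# log prior density in internal coordinates (the per-parameter log-Jacobians
# cancel against the proposal density computed in the same coordinates)
.log_prior_internal <- function(prior, z) {
  z <- rbind(z)
  rowSums(vapply(seq_len(nrow(prior)), function(j) {
    stats::dnorm(z[, j], prior$mu[j], prior$sigma[j], log = TRUE)
  }, numeric(nrow(z))))
}

.particle_ensemble <- function(stage, theta, distances, weights, epsilon,
                               features = NULL, acceptance = NA_real_) {
  structure(list(stage = stage, theta = theta, distances = distances,
                 weights = weights, epsilon = epsilon, features = features,
                 acceptance = acceptance, n_abc = nrow(theta)),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf(
    "<particle_ensemble> stage %d: %d particles, epsilon %.4g, median d %.4g\n",
    x$stage, x$n_abc, x$epsilon, stats::median(x$distances)))
  invisible(x)
}

# Evaluate a batch of particles under the deterministic-given-seed parallel
# contract: each particle gets its own sub-seed drawn from the main stream,
# so results are identical whatever the worker count.
.evaluate_batch <- function(theta, evaluator, n_workers = 1) {
  n <- nrow(theta)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  main_seed <- get0(".Random.seed", envir = globalenv())
  eval_one <- function(i) {
    set.seed(seeds[i])
    evaluator(theta[i, ])
  }
  res <- if (n_workers > 1) {
    parallel::mclapply(seq_len(n), eval_one, mc.cores = n_workers)
  } else {
    lapply(seq_len(n), eval_one)
  }
  if (!is.null(main_seed)) assign(".Random.seed", main_seed,
                                  envir = globalenv())
  dist <- vapply(res, function(r) {
    d <- if (is.list(r)) r$distance else r
    if (!is.finite(d)) Inf else as.numeric(d)
  }, numeric(1))
  feats <- lapply(res, function(r) if (is.list(r)) r$features else NULL)
  list(distances = dist, features = feats)
}

#' First ABC-SMC stage: filtered prior sampling
#'
#' Draws parameters from the prior in batches, evaluates each draw, and keeps
#' those whose distance falls below `eps1` until `n_abc` particles are
#' accepted; every accepted particle receives weight `1 / n_abc`. With
#' `eps1 = Inf` the first `n_abc` (finitely evaluable) prior draws are kept.
#'
#' @param prior A [prior_spec()].
#' @param evaluator Function mapping a named parameter vector to either a
#'   distance or a list `(distance, features)`; failures should yield `Inf`.
#' @param eps1 Stage-1 threshold (default `Inf`).
#' @param n_abc Number of particles to accept.
#' @param n_batch Batch size for (optionally parallel) evaluation.
#' @param seed Optional seed set on entry.
#' @param n_workers Worker processes for batch evaluation.
#' @param min_acceptance Abort when the running acceptance rate drops below
#'   this floor (default 1e-4).
#' @return A `particle_ensemble` (stage 1).
#' @export
initial_stage <- function(prior, evaluator, eps1 = Inf, n_abc = 1000,
                          n_batch = 100, seed = NULL, n_workers = 1,
                          min_acceptance = 1e-4) {
  if (!is.null(seed)) set.seed(seed)
  if (eps1 <= 0) stop("eps1 must be positive")
  kept_theta <- NULL; kept_d <- numeric(0); kept_f <- list()
  attempts <- 0
  while (length(kept_d) < n_abc) {
    theta <- sample_prior(prior, n_batch)
    ev <- .evaluate_batch(theta, evaluator, n_workers)
    ok <- which(ev$distances < eps1)
    kept_theta <- rbind(kept_theta, theta[ok, , drop = FALSE])
    kept_d <- c(kept_d, ev$distances[ok])
    kept_f <- c(kept_f, ev$features[ok])
    attempts <- attempts + n_batch
    if (attempts >= max(20 * n_abc, 2000) &&
        length(kept_d) / attempts < min_acceptance) {
      stop(sprintf(
        "stage 1 acceptance rate below %.2g (%d accepted of %d attempts); ",
        min_acceptance, length(kept_d), attempts),
        "eps1 is too tight or the evaluator always fails")
    }
  }
  keep <- seq_len(n_abc)
  .particle_ensemble(
    stage = 1L, theta = kept_theta[keep, , drop = FALSE],
    distances = kept_d[keep],
    weights = rep(1 / n_abc, n_abc), epsilon = eps1,
    features = kept_f[keep], acceptance = n_abc / attempts
  )
}

#' One refinement stage of the adaptive-weight ABC-SMC sampler
#'
#' Ancestors are resampled from the previous stage with probability
#' proportional to `weight x K_c(distance)`, where the closeness kernel
#' `K_c` is Gaussian on the accepted distances (the adaptive-weight
#' ingredient: particles that sat close to the data are proposed from more
#' often); its bandwidth, unless given, is chosen so the selection keeps a
#' workable effective ancestor pool, and the weight factor is tempered to
#' the same end. Proposals perturb the selected ancestor with a Gaussian
#' kernel in internal (log) coordinates whose covariance is twice the
#' empirical covariance of the parent pool (plus a small jitter floor), or a
#' diagonal kernel when `kernel_scales` is given. Accepted particles
#' (distance below `eps_t`) are reweighted by the importance formula
#' `w_k ~ prior(theta_k) / sum_j p_j q(theta_k | theta_j)` (with `p` the
#' actual selection probabilities) and normalised.
#'
#' A small fraction (`defensive`) of proposals is drawn directly from the
#' prior rather than from the perturbation mixture. This "defensive mixture"
#' bounds the importance weights at `1 / defensive` and thereby keeps the
#' effective sample size from collapsing, which a broad prior over many
#' parameters would otherwise cause; the proposal density used in the weight
#' denominator is the exact density of the mixture actually sampled from.
#'
#' @param prev Previous `particle_ensemble`.
#' @param eps_t New threshold; must be strictly smaller than `prev$epsilon`.
#' @param evaluator As in [initial_stage()].
#' @param prior The [prior_spec()] the run started from.
#' @param kernel_scales Optional per-parameter proposal bandwidths.
#' @param seed,n_batch,n_workers,min_acceptance As in [initial_stage()].
#' @param defensive Fraction of proposals drawn from the prior (default 0.1).
#' @param scale Multiplier on the proposal covariance (default 1); the run
#'   driver shrinks it when acceptance drops, so that late-stage proposals
#'   stay on the ridge the ensemble has found.
#' @param kc_bandwidth Closeness-kernel bandwidth; `NULL` (default) selects
#'   it adaptively by the effective-pool target.
#' @param jitter_floor Minimum per-parameter proposal standard deviation on
#'   the internal scale (default 0.02), preventing the population from
#'   collapsing onto clones of one particle.
#' @return A `particle_ensemble` for stage `prev$stage + 1`.
#' @export
smc_stage <- function(prev, eps_t, evaluator, prior, kernel_scales = NULL,
                      seed = NULL, n_batch = 100, n_workers = 1,
                      min_acceptance = 1e-3, defensive = 0.1, scale = 1,
                      kc_bandwidth = NULL, jitter_floor = 0.02) {
  stopifnot(inherits(prev, "particle_ensemble"))
  if (!is.null(seed)) set.seed(seed)
  if (!(eps_t < prev$epsilon)) {
    stop("thresholds must decrease: eps_t = ", format(eps_t),
         " is not below the previous threshold ", format(prev$epsilon))
  }
  n_abc <- prev$n_abc
  p <- nrow(prior)
  z_prev <- .to_internal(prior, prev$theta)

  # Closeness kernel on the ancestors' distances: ancestors that sat close to
  # the data are resampled preferentially (the adaptive-weight ingredient).
  # When no bandwidth is given it is set by bisection so that the selection
  # keeps an effective ancestor pool of about an eighth of the ensemble:
  # sharp enough to drive the population down the distance landscape, broad
  # enough not to collapse it onto a single particle.
  target_ess <- max(20, n_abc / 8)
  log_w_prev <- log(pmax(prev$weights, 1e-300))
  # temper the importance weights for resampling only (w^beta, beta chosen so
  # the weight part of the selection keeps an effective pool of ~2x target);
  # untempered weights would concentrate the pool on a handful of particles
  # whenever the accepted region spans a wide range of prior density
  ess_of <- function(lp) {
    q <- exp(lp - max(lp))
    q <- q / sum(q)
    1 / sum(q^2)
  }
  beta <- 1
  if (ess_of(log_w_prev) < 2 * target_ess) {
    lo_b <- 0; hi_b <- 1
    for (it in 1:40) {
      beta <- (lo_b + hi_b) / 2
      if (ess_of(beta * log_w_prev) < 2 * target_ess) hi_b <- beta
      else lo_b <- beta
    }
    beta <- lo_b
  }
  sel_probs <- function(bw) {
    log_kc <- if (is.finite(bw) && bw > 0) {
      -0.5 * (prev$distances / bw)^2
    } else {
      rep(0, n_abc)
    }
    lp <- beta * log_w_prev + log_kc
    q <- exp(lp - max(lp))
    if (sum(q) <= 0) NULL else q / sum(q)
  }
  if (is.null(kc_bandwidth)) {
    lo <- 1e-4 * max(stats::sd(prev$distances), 1e-12)
    hi <- 100 * max(prev$distances[is.finite(prev$distances)], 1)
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      pr <- sel_probs(mid)
      ess <- if (is.null(pr)) 0 else 1 / sum(pr^2)
      if (ess < target_ess) lo <- mid else hi <- mid
      if (hi / lo < 1.01) break
    }
    kc_bandwidth <- hi
  }
  resample_p <- sel_probs(kc_bandwidth)
  if (is.null(resample_p)) stop("degenerate resampling probabilities")

  # proposal kernel: Gaussian with twice the empirical covariance of the
  # selected parent pool in internal coordinates, so proposals follow the
  # correlation structure of the region the population is descending into;
  # a diagonal kernel is available through kernel_scales
  if (is.null(kernel_scales)) {
    zm <- colSums(resample_p * z_prev)
    zc <- sweep(z_prev, 2, zm)
    Sigma <- 2 * crossprod(zc * sqrt(resample_p), zc * sqrt(resample_p))
    # jitter floor (2% on the internal scale) keeps the population from
    # collapsing onto clones of a single particle at late stages
    Sigma <- scale * Sigma + diag(jitter_floor^2, p)
  } else {
    kernel_scales <- pmax(rep_len(kernel_scales, p), 1e-8)
    Sigma <- scale * diag(kernel_scales^2, p)
  }
  ch <- chol(Sigma)
  log_det_term <- -sum(log(diag(ch))) - 0.5 * p * log(2 * pi)

  stopifnot(defensive >= 0, defensive < 1)
  kept_z <- NULL; kept_d <- numeric(0); kept_f <- list()
  attempts <- 0
  while (length(kept_d) < n_abc) {
    anc <- sample.int(n_abc, n_batch, replace = TRUE, prob = resample_p)
    noise <- matrix(stats::rnorm(n_batch * p), n_batch, p) %*% ch
    z_new <- z_prev[anc, , drop = FALSE] + noise
    if (defensive > 0) {
      from_prior <- stats::runif(n_batch) < defensive
      if (any(from_prior)) {
        z_new[from_prior, ] <- .to_internal(
          prior, sample_prior(prior, sum(from_prior)))
      }
    }
    theta_new <- .from_internal(prior, z_new)
    ev <- .evaluate_batch(theta_new, evaluator, n_workers)
    ok <- which(ev$distances < eps_t)
    kept_z <- rbind(kept_z, z_new[ok, , drop = FALSE])
    kept_d <- c(kept_d, ev$distances[ok])
    kept_f <- c(kept_f, ev$features[ok])
    attempts <- attempts + n_batch
    if (attempts >= max(20 * n_abc, 2000) &&
        length(kept_d) / attempts < min_acceptance) {
      stop(sprintf(
        "acceptance stalled at stage %d: %d accepted of %d attempts (< %.2g)",
        prev$stage + 1L, length(kept_d), attempts, min_acceptance))
    }
  }
  keep <- seq_len(n_abc)
  kept_z <- kept_z[keep, , drop = FALSE]
  kept_d <- kept_d[keep]
  kept_f <- kept_f[keep]

  log_prior <- .log_prior_internal(prior, kept_z)
  log_resample_p <- log(resample_p)
  log_w <- vapply(seq_len(n_abc), function(k) {
    dev <- sweep(z_prev, 2, kept_z[k, ])
    maha <- colSums(backsolve(ch, t(dev), transpose = TRUE)^2)
    logq <- log_det_term - 0.5 * maha
    m <- max(log_resample_p + logq)
    log_mix <- m + log(sum(exp(log_resample_p + logq - m)))
    if (defensive > 0) {
      a <- max(log(1 - defensive) + log_mix, log(defensive) + log_prior[k])
      log_mix <- a + log(exp(log(1 - defensive) + log_mix - a) +
                           exp(log(defensive) + log_prior[k] - a))
    }
    log_prior[k] - log_mix
  }, numeric(1))
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)

  .particle_ensemble(
    stage = prev$stage + 1L, theta = .from_internal(prior, kept_z),
    distances = kept_d, weights = w, epsilon = eps_t,
    features = kept_f, acceptance = n_abc / attempts
  )
}

#' Adaptive threshold schedule
#'
#' The next acceptance threshold is the `alpha`-quantile of the distances
#' accepted at the previous stage, which guarantees a monotonically
#' decreasing schedule without having to fix thresholds in advance.
#'
#' @param prev_distances Accepted distances of the previous stage.
#' @param alpha Quantile in (0, 1); default 0.5 (the median).
#' @return The next threshold.
#' @export
epsilon_schedule <- function(prev_distances, alpha = 0.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  d <- prev_distances[is.finite(prev_distances)]
  if (!length(d)) stop("no finite distances to build a schedule from")
  if (diff(range(d)) == 0) {
    stop("degenerate distances (all equal); the schedule cannot decrease ",
         "further")
  }
  stats::quantile(d, alpha, names = FALSE)
}

#' Run the full adaptive-weight ABC-SMC sampler
#'
#' Stage 1 filters prior draws at `eps1` (default: accept the first `n_abc`
#' evaluable draws); each later stage sets its threshold to the
#' `alpha`-quantile of the previously accepted distances and refines the
#' ensemble with [smc_stage()]. The run ends after `max_stages` stages, or
#' earlier when acceptance stalls (below `min_acceptance`) or the distance
#' distribution degenerates. The final ensemble approximates the posterior.
#'
#' @param evaluator Function mapping a named parameter vector to a distance
#'   or `(distance, features)` list; parameter draws for which the model has
#'   no usable steady state should evaluate to `Inf` (rejection).
#' @param prior A [prior_spec()].
#' @param n_abc Particles per stage (the study uses 1000).
#' @param n_batch Evaluation batch size.
#' @param alpha Threshold quantile, see [epsilon_schedule()].
#' @param max_stages Stage budget (default 10).
#' @param eps1 Stage-1 threshold (default `Inf`).
#' @param seed Seed for the whole run (required); per-stage sub-seeds are
#'   derived from it, which also makes resumed runs reproducible.
#' @param n_workers Workers for batch evaluation (results are identical for
#'   any worker count).
#' @param min_acceptance Stall floor for stages >= 2.
#' @param kc_rule How the closeness-kernel bandwidth is set per stage:
#'   `"spread"` (the standard deviation of the previously accepted
#'   distances; sharp, data-driven selection) or `"epsilon"` (tied to the
#'   previous threshold).
#' @param pilot,pilot_quantile When `eps1` is infinite, `pilot` prior draws
#'   are evaluated first and `eps1` is set to the `pilot_quantile` of their
#'   distances, so the schedule starts inside the informative region; set
#'   `pilot = 0` to accept the first `n_abc` evaluable prior draws instead.
#' @param out_dir Optional directory: each stage is persisted as CSV plus a
#'   JSON run manifest, and an interrupted run can be resumed.
#' @param resume If `TRUE`, continue from the last stage persisted in
#'   `out_dir`.
#' @param verbose Print one line per stage.
#' @return List of class `abc_smc_result`: `final` (last
#'   `particle_ensemble`), `history` (all stages), `epsilons`,
#'   `acceptance_rates`, `seed`, and `termination` (why the run stopped).
#' @export
run_abc_smc <- function(evaluator, prior, n_abc = 1000, n_batch = 100,
                        alpha = 0.5, max_stages = 10, eps1 = Inf,
                        seed, n_workers = 1, min_acceptance = 1e-3,
                        kc_rule = c("spread", "epsilon"), pilot = 1000,
                        pilot_quantile = 0.1,
                        out_dir = NULL, resume = FALSE, verbose = FALSE) {
  kc_rule <- match.arg(kc_rule)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, max_stages)

  history <- list()
  if (resume) {
    if (is.null(out_dir)) stop("resume requires out_dir")
    history <- .load_stage_history(out_dir, prior)
  }

  termination <- sprintf("stage budget (%d) reached", max_stages)
  kernel_scale <- 1
  for (h in history[-1]) { # replay the scale adaptation of resumed stages
    kernel_scale <- min(1, max(0.02, kernel_scale * h$acceptance / 0.3))
  }
  if (length(history) == 0) {
    if (is.infinite(eps1) && !is.null(pilot) && pilot > 0) {
      # initialise the threshold schedule from a pilot sample of the prior:
      # eps1 is set so that roughly the best pilot_quantile of prior draws
      # pass, which starts the schedule inside the informative region
      # instead of accepting arbitrarily poor particles at stage 1
      pilot_draws <- sample_prior(prior, pilot)
      pilot_d <- .evaluate_batch(pilot_draws, evaluator,
                                 n_workers)$distances
      pilot_d <- pilot_d[is.finite(pilot_d)]
      if (length(pilot_d) >= 20) {
        eps1 <- stats::quantile(pilot_d, pilot_quantile, names = FALSE)
      }
    }
    ens <- initial_stage(prior, evaluator, eps1 = eps1, n_abc = n_abc,
                         n_batch = n_batch, seed = stage_seeds[1],
                         n_workers = n_workers)
    history[[1]] <- ens
    if (!is.null(out_dir)) .persist_stage(out_dir, ens)
    if (verbose) print(ens)
  }
  t0 <- length(history)
  if (t0 < max_stages) {
    for (t in seq(t0 + 1L, max_stages)) {
      prev <- history[[t - 1L]]
      eps_t <- tryCatch(epsilon_schedule(prev$distances, alpha),
                        error = function(e) NA_real_)
      if (!is.finite(eps_t) || !(eps_t < prev$epsilon)) {
        termination <- "distance distribution degenerate; schedule exhausted"
        break
      }
      # "spread": closeness-kernel bandwidth set to the spread of the
      # accepted distances (sharp, data-driven selection pressure);
      # "epsilon": bandwidth tied to the last threshold
      kc_bw <- if (kc_rule == "spread") {
        max(stats::sd(prev$distances), 1e-12)
      } else {
        prev$epsilon
      }
      ens <- tryCatch(
        smc_stage(prev, eps_t, evaluator, prior, seed = stage_seeds[t],
                  n_batch = n_batch, n_workers = n_workers,
                  min_acceptance = min_acceptance, scale = kernel_scale,
                  kc_bandwidth = kc_bw),
        error = function(e) e
      )
      if (inherits(ens, "error")) {
        termination <- conditionMessage(ens)
        break
      }
      history[[t]] <- ens
      # keep per-stage acceptance near a workable level by shrinking or
      # regrowing the proposal covariance for the next stage
      kernel_scale <- min(1, max(0.02, kernel_scale * ens$acceptance / 0.3))
      if (!is.null(out_dir)) .persist_stage(out_dir, ens)
      if (verbose) print(ens)
    }
  }
  res <- structure(
    list(final = history[[length(history)]], history = history,
         epsilons = vapply(history, `[[`, numeric(1), "epsilon"),
         acceptance_rates = vapply(history, `[[`, numeric(1), "acceptance"),
         seed = seed, termination = termination),
    class = "abc_smc_result"
  )
  if (!is.null(out_dir)) .persist_manifest(out_dir, res, prior, n_abc,
                                           n_batch, alpha, max_stages)
  res
}

#' @export
print.abc_smc_result <- function(x, ...) {
  cat(sprintf("<abc_smc_result> %d stage(s), %d particles each\n",
              length(x$history), x$final$n_abc))
  cat("  epsilons:", paste(signif(x$epsilons, 4), collapse = " > "), "\n")
  cat("  termination:", x$termination, "\n")
  invisible(x)
}

.stage_file <- function(out_dir, stage) {
  file.path(out_dir, sprintf("stage_%03d.csv", stage))
}

.persist_stage <- function(out_dir, ens) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(stage = ens$stage, particle = seq_len(ens$n_abc),
                   weight = ens$weights, distance = ens$distances,
                   epsilon = ens$epsilon, acceptance = ens$acceptance,
                   ens$theta, check.names = FALSE)
  # full double precision so that resumed runs replay bit-identically
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  utils::write.csv(df, .stage_file(out_dir, ens$stage), row.names = FALSE,
                   quote = FALSE)
}

.load_stage_history <- function(out_dir, prior) {
  files <- sort(list.files(out_dir, pattern = "^stage_\\d+\\.csv$",
                           full.names = TRUE))
  lapply(files, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    .particle_ensemble(
      stage = df$stage[1],
      theta = as.matrix(df[, prior$name, drop = FALSE]),
      distances = df$distance, weights = df$weight,
      epsilon = df$epsilon[1], acceptance = df$acceptance[1]
    )
  })
}

.persist_manifest <- function(out_dir, res, prior, n_abc, n_batch, alpha,
                              max_stages) {
  manifest <- list(
    seed = res$seed, n_abc = n_abc, n_batch = n_batch, alpha = alpha,
    max_stages = max_stages, stages_run = length(res$history),
    epsilons = res$epsilons, acceptance_rates = res$acceptance_rates,
    termination = res$termination,
    prior = prior[, c("name", "dist", "mu", "sigma")],
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Weighted posterior summaries of an ensemble's parameters
#'
#' @param ensemble A `particle_ensemble`.
#' @return data.frame with weighted mean, sd and quantiles per parameter.
#' @export
ensemble_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  w <- ensemble$weights
  qs <- function(v) {
    o <- order(v)
    cw <- cumsum(w[o])
    v[o][c(which(cw >= 0.165)[1], which(cw >= 0.5)[1], which(cw >= 0.835)[1])]
  }
  out <- t(apply(ensemble$theta, 2, function(v) {
    m <- sum(w * v)
    c(mean = m, sd = sqrt(sum(w * (v - m)^2)), q = qs(v))
  }))
  data.frame(parameter = colnames(ensemble$theta),
             mean = out[, 1], sd = out[, 2],
             q16.5 = out[, 3], median = out[, 4], q83.5 = out[, 5],
             row.names = NULL)
}
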