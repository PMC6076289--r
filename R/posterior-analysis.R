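# Posterior-predictive machinery: ensemble feature reconstruction with
# standard errors, sum-of-squares fit error, dose-response curves, ligand
# wash-out time courses, and cell-population modality analysis (each sampled
# parameter set is read as one cell of a population).

.wmean_se <- function(values, weights) {
  m <- sum(weights * values)
  v <- sum(weights * (values - m)^2)
  ess <- 1 / sum(weights^2)
  c(mean = m, se = sqrt(v / ess))
}

#' Posterior-predictive response features of an ensemble
#'
#' Re-evaluates the model features (local response matrices and ligand
#' response ratios) for each particle and summarises them across the
#' ensemble by mean and standard error (sd divided by the square root of the
#' effective sample size). The default treats the final ensemble as a plain
#' collection of fitted models — every particle is one model (or one cell)
#' and the prediction is their unweighted average, which is how the study
#' protocol aggregates its thousand-model ensembles; importance weighting is
#' available as an alternative. Particles whose evaluation fails are
#' excluded and counted.
#'
#' @param ensemble A `particle_ensemble`.
#' @param evaluator The evaluator the ensemble was fitted with (e.g.
#'   [mapk_egf_evaluator()]); it must return features. Cached features
#'   stored in the ensemble are reused when present.
#' @param weighting `"equal"` (ensemble-of-models average, the default) or
#'   `"importance"` (use the stage's importance weights).
#' @return Object of class `posterior_prediction`: per condition, matrices
#'   `r_mean`/`r_se` and vectors `rho_mean`/`rho_se`; plus `n_failed`.
#' @export
predict_features <- function(ensemble, evaluator = NULL,
                             weighting = c("equal", "importance")) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  weighting <- match.arg(weighting)
  if (weighting == "equal") {
    ensemble$weights <- rep(1 / ensemble$n_abc, ensemble$n_abc)
  }
  feats <- ensemble$features
  if (is.null(feats) || all(vapply(feats, is.null, logical(1)))) {
    if (is.null(evaluator)) {
      stop("ensemble carries no cached features; supply the evaluator")
    }
    feats <- lapply(seq_len(ensemble$n_abc), function(i) {
      evaluator(ensemble$theta[i, ])$features
    })
  }
  ok <- !vapply(feats, is.null, logical(1))
  n_failed <- sum(!ok)
  if (!any(ok)) stop("no particle produced evaluable features")
  feats <- feats[ok]
  w <- ensemble$weights[ok]
  w <- w / sum(w)

  cond_names <- names(feats[[1]]$conditions)
  out <- list()
  for (nm in cond_names) {
    rs <- lapply(feats, function(f) as.matrix(f$conditions[[nm]]$r))
    dims <- dim(rs[[1]])
    arr <- array(unlist(rs), dim = c(dims, length(rs)))
    r_mean <- apply(arr, c(1, 2), function(v) sum(w * v))
    r_se <- apply(arr, c(1, 2), function(v) .wmean_se(v, w)[["se"]])
    dimnames(r_mean) <- dimnames(r_se) <- dimnames(rs[[1]])
    diag(r_mean) <- -1
    diag(r_se) <- 0
    cond_out <- list(r_mean = r_mean, r_se = r_se)
    if (!is.null(feats[[1]]$conditions[[nm]]$rho)) {
      rhos <- vapply(feats, function(f) as.numeric(f$conditions[[nm]]$rho),
                     numeric(length(feats[[1]]$conditions[[nm]]$rho)))
      rhos <- rbind(rhos)
      stats_rho <- apply(rhos, 1, .wmean_se, weights = w)
      cond_out$rho_mean <- stats::setNames(
        stats_rho["mean", ], names(feats[[1]]$conditions[[nm]]$rho))
      cond_out$rho_se <- stats::setNames(
        stats_rho["se", ], names(feats[[1]]$conditions[[nm]]$rho))
    }
    out[[nm]] <- cond_out
  }
  structure(list(conditions = out, n_failed = n_failed),
            class = "posterior_prediction")
}

#' Sum-of-squares fit error between observed and predicted features
#'
#' Total squared deviation between the data-derived response features and
#' the posterior-mean predictions, over all off-diagonal local response
#' coefficients and all ligand response ratios of every condition. This is
#' the scalar used to judge fit quality across noise levels and prior
#' choices.
#'
#' @param observed The data-derived [response_set()].
#' @param predicted A [predict_features()] result (or a `response_set` of
#'   point predictions).
#' @return Nonnegative scalar.
#' @export
ssq_fit_error <- function(observed, predicted) {
  stopifnot(inherits(observed, "response_set"))
  get_pred <- function(nm) {
    if (inherits(predicted, "posterior_prediction")) {
      pc <- predicted$conditions[[nm]]
      if (is.null(pc)) stop("prediction is missing condition ", nm)
      list(r = pc$r_mean, rho = pc$rho_mean)
    } else {
      pc <- predicted$conditions[[nm]]
      if (is.null(pc)) stop("prediction is missing condition ", nm)
      pc
    }
  }
  total <- 0
  for (nm in names(observed$conditions)) {
    oc <- observed$conditions[[nm]]
    pc <- get_pred(nm)
    if (!is.null(oc$r)) {
      if (is.null(pc$r) || !all(dim(pc$r) == dim(oc$r))) {
        stop("condition ", nm, ": predicted r missing or of different shape")
      }
      total <- total + sum((offdiag(oc$r) - offdiag(pc$r))^2)
    }
    if (!is.null(oc$rho)) {
      if (is.null(pc$rho) || length(pc$rho) != length(oc$rho)) {
        stop("condition ", nm, ": predicted rho missing or wrong length")
      }
      total <- total + sum((as.numeric(oc$rho) - as.numeric(pc$rho))^2)
    }
  }
  total
}

#' Simulate a model time course
#'
#' @param model A [rate_model].
#' @param times Output time grid (minutes), starting at the initial time.
#' @param x0 Initial state (default: starved, all zeros).
#' @return data.frame `time` plus one column per species.
#' @export
simulate_timecourse <- function(model, times, x0 = NULL) {
  stopifnot(inherits(model, "rate_model"), length(times) >= 2)
  if (is.null(x0)) x0 <- rep(0, length(model$species))
  out <- .integrate(model, x0, times)
  df <- as.data.frame(out)
  names(df) <- c("time", model$species)
  df
}

#' Ensemble dose-response curve
#'
#' For each particle and each ligand dose, reads out one species of the
#' model (its steady state, or its level at a fixed time) and aggregates
#' across the ensemble: weighted mean, standard error, and the 16.5/83.5
#' weighted percentiles (a 67% ensemble interval).
#'
#' @param ensemble A `particle_ensemble` (or a one-row parameter matrix).
#' @param model_builder Function `(theta, dose)` returning a [rate_model].
#' @param doses Positive ligand doses.
#' @param species Readout species (default `"aERK"`).
#' @param readout `"steady_state"` or `"time"`.
#' @param readout_time Readout time in minutes when `readout = "time"`
#'   (e.g. 5 for the peak response after ligand stimulation).
#' @param weighting `"equal"` (ensemble-of-models average, default) or
#'   `"importance"`.
#' @return data.frame `dose`, `mean`, `se`, `lo67`, `hi67`, `n_failed`.
#' @export
dose_response <- function(ensemble, model_builder, doses, species = "aERK",
                          readout = c("steady_state", "time"),
                          readout_time = NULL,
                          weighting = c("equal", "importance")) {
  readout <- match.arg(readout)
  weighting <- match.arg(weighting)
  if (weighting == "equal") {
    ensemble$weights <- rep(1 / ensemble$n_abc, ensemble$n_abc)
  }
  stopifnot(all(doses > 0))
  if (readout == "time" && is.null(readout_time)) {
    stop("readout_time is required for readout = 'time'")
  }
  theta <- ensemble$theta
  w <- ensemble$weights
  one <- function(th, dose) {
    model <- model_builder(th, dose)
    if (readout == "steady_state") {
      ss <- find_steady_state(model)
      if (!isTRUE(ss$converged)) return(NA_real_)
      ss$state[[species]]
    } else {
      tc <- simulate_timecourse(model, c(0, readout_time))
      tc[[species]][nrow(tc)]
    }
  }
  rows <- lapply(doses, function(dose) {
    vals <- vapply(seq_len(nrow(theta)), function(i) {
      tryCatch(one(theta[i, ], dose), error = function(e) NA_real_)
    }, numeric(1))
    ok <- is.finite(vals)
    wi <- w[ok] / sum(w[ok])
    ms <- .wmean_se(vals[ok], wi)
    o <- order(vals[ok]); cw <- cumsum(wi[o])
    data.frame(dose = dose, mean = ms[["mean"]], se = ms[["se"]],
               lo67 = vals[ok][o][which(cw >= 0.165)[1]],
               hi67 = vals[ok][o][which(cw >= 0.835)[1]],
               n_failed = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Ligand wash-out (neutralizing antibody) time course
#'
#' Simulates stimulation up to `neutralize_at` minutes, then continues with
#' the ligand concentration forced to zero (the effect of a growth-factor
#' neutralizing antibody), the state carrying over continuously at the
#' switch. Aggregated over the ensemble.
#'
#' @param ensemble A `particle_ensemble`.
#' @param model_builder Function `(theta, dose)`; dose 0 must give the
#'   neutralized model.
#' @param dose Ligand dose before neutralization.
#' @param neutralize_at Switch time in minutes (>= 0).
#' @param times Output grid covering `[0, horizon]`.
#' @param species Readout species (default `"aERK"`).
#' @param weighting `"equal"` (ensemble-of-models average, default) or
#'   `"importance"`.
#' @return data.frame `time`, `mean`, `se`.
#' @export
washout_timecourse <- function(ensemble, model_builder, dose,
                               neutralize_at = 10,
                               times = seq(0, 60, by = 1),
                               species = "aERK",
                               weighting = c("equal", "importance")) {
  stopifnot(neutralize_at >= 0, all(diff(times) > 0))
  weighting <- match.arg(weighting)
  if (weighting == "equal") {
    ensemble$weights <- rep(1 / ensemble$n_abc, ensemble$n_abc)
  }
  theta <- ensemble$theta
  w <- ensemble$weights
  curves <- lapply(seq_len(nrow(theta)), function(i) {
    th <- theta[i, ]
    pre_t <- unique(c(times[times <= neutralize_at], neutralize_at))
    m1 <- model_builder(th, dose)
    if (length(pre_t) >= 2) {
      pre <- simulate_timecourse(m1, pre_t)
    } else {
      pre <- data.frame(time = neutralize_at,
                        t(rep(0, length(m1$species))))
      names(pre) <- c("time", m1$species)
    }
    x_switch <- as.numeric(pre[nrow(pre), -1])
    post_t <- unique(c(neutralize_at, times[times > neutralize_at]))
    m0 <- model_builder(th, 0)
    post <- simulate_timecourse(m0, post_t, x0 = x_switch)
    full <- rbind(pre[pre$time %in% times, ], post[post$time %in% times &
                                                     post$time > neutralize_at, ])
    stats::approx(full$time, full[[species]], xout = times)$y
  })
  mat <- do.call(cbind, curves)
  agg <- t(apply(mat, 1, .wmean_se, weights = w))
  data.frame(time = times, mean = agg[, "mean"], se = agg[, "se"])
}

#' Least-squares Gaussian mixture fit to a density curve
#'
#' Fits a k-component Gaussian mixture density to `(x, y)` points by
#' unweighted least squares (Nelder-Mead on transformed parameters).
#'
#' @param x,y Density curve (e.g. from [stats::density()]).
#' @param k 1 or 2 components.
#' @param init_values Raw draws used to initialise means and sds.
#' @return List `par` (data.frame weight/mean/sd per component), `ssq`,
#'   `fitted` (values on `x`).
#' @keywords internal
.fit_gaussian_mixture <- function(x, y, k, init_values) {
  mix_density <- function(par, x) {
    if (k == 1) {
      stats::dnorm(x, par[1], exp(par[2]))
    } else {
      pi1 <- stats::plogis(par[5])
      pi1 * stats::dnorm(x, par[1], exp(par[2])) +
        (1 - pi1) * stats::dnorm(x, par[3], exp(par[4]))
    }
  }
  obj <- function(par) {
    f <- mix_density(par, x)
    if (any(!is.finite(f))) return(1e10)
    sum((y - f)^2)
  }
  if (k == 1) {
    par0 <- c(mean(init_values), log(stats::sd(init_values)))
  } else {
    med <- stats::median(init_values)
    lo <- init_values[init_values <= med]
    hi <- init_values[init_values > med]
    par0 <- c(mean(lo), log(max(stats::sd(lo), 1e-3)),
              mean(hi), log(max(stats::sd(hi), 1e-3)), 0)
  }
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  par <- fit$par
  comp <- if (k == 1) {
    data.frame(weight = 1, mean = par[1], sd = exp(par[2]))
  } else {
    data.frame(weight = c(stats::plogis(par[5]), 1 - stats::plogis(par[5])),
               mean = c(par[1], par[3]), sd = c(exp(par[2]), exp(par[4])))
  }
  list(par = comp, ssq = fit$value, fitted = mix_density(par, x))
}

#' Modality analysis of ensemble readouts
#'
#' Treats each particle's readout as one cell of a population: estimates the
#' population density by a kernel density estimator (Silverman's bandwidth),
#' fits one- and two-component Gaussian mixtures to the density curve by
#' least squares, selects the component count with the smaller fitting
#' error, and reports the modes (local maxima) of the selected fit.
#'
#' @param readouts Numeric vector of per-particle readouts (>= 50 values
#'   with nonzero spread).
#' @param n_grid KDE grid size.
#' @return List: `n_modes`, `n_components`, `modes` (locations), `components`
#'   (data.frame of the selected mixture), `ssq` (per component count),
#'   `density` (the KDE as a data.frame).
#' @export
modality_analysis <- function(readouts, n_grid = 512) {
  readouts <- readouts[is.finite(readouts)]
  if (length(readouts) < 50) {
    stop("modality analysis needs at least 50 finite ensemble readouts")
  }
  if (stats::sd(readouts) == 0) {
    stop("degenerate readouts: zero variance, density estimate undefined")
  }
  den <- stats::density(readouts, bw = "nrd", n = n_grid)
  fit1 <- .fit_gaussian_mixture(den$x, den$y, 1, readouts)
  fit2 <- .fit_gaussian_mixture(den$x, den$y, 2, readouts)
  best <- if (fit2$ssq < fit1$ssq) fit2 else fit1
  n_components <- if (fit2$ssq < fit1$ssq) 2L else 1L
  # modes = strict local maxima of the selected fitted density (two heavily
  # overlapping components form a single mode)
  f <- best$fitted
  up <- diff(f) > 0
  peaks <- which(c(FALSE, up) & c(!up, FALSE))
  peaks <- peaks[f[peaks] > 1e-3 * max(f)]
  if (length(peaks) == 0) peaks <- which.max(f)
  list(n_modes = length(peaks), n_components = n_components,
       modes = den$x[peaks], components = best$par,
       ssq = c(one = fit1$ssq, two = fit2$ssq),
       density = data.frame(x = den$x, y = den$y))
}

#' Four-parameter logistic fit of a dose-response curve
#'
#' Least-squares fit of `lo + (hi - lo) / (1 + (ec50 / dose)^h)` on the log
#' dose axis; used to summarise sigmoidal ligand dose responses.
#'
#' @param dose Positive doses.
#' @param response Mean responses.
#' @return List `par` (lo, hi, ec50, h), `ssq`, `fitted`.
#' @export
sigmoid_fit <- function(dose, response) {
  stopifnot(all(dose > 0), length(dose) == length(response))
  ld <- log(dose)
  f <- function(par, ld) {
    par[1] + (par[2] - par[1]) / (1 + exp(-par[4] * (ld - par[3])))
  }
  obj <- function(par) {
    r <- f(par, ld)
    if (any(!is.finite(r))) return(1e10)
    sum((response - r)^2)
  }
  par0 <- c(min(response), max(response), stats::median(ld), 1)
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  list(par = c(lo = fit$par[1], hi = fit$par[2],
               ec50 = exp(fit$par[3]), h = fit$par[4]),
       ssq = fit$value, fitted = f(fit$par, ld))
}
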