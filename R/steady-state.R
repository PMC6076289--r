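# Steady-state location, numerical Jacobians, and model-side local response
# coefficients. The model-side LRCs are what make perturbation simulation
# unnecessary: one steady state + one Jacobian per condition replaces one ODE
# run per perturbation.

.desolve_func <- function(model) {
  function(t, y, parms) list(model$rate(y, t))
}

.integrate <- function(model, x0, times, rtol = 1e-8, atol = 1e-8) {
  if (!is.null(model$native)) {
    deSolve::lsoda(y = unname(x0), times = times, func = model$native$func,
                   parms = model$native$parms, dllname = "mrafit",
                   initfunc = model$native$initfunc,
                   rtol = rtol, atol = atol)
  } else {
    deSolve::lsoda(y = unname(x0), times = times, func = .desolve_func(model),
                   parms = NULL, rtol = rtol, atol = atol)
  }
}

#' Numerical Jacobian of a rate model
#'
#' Central finite differences of the rate function with per-component step
#' `h_j = max(1e-6 * |x_j|, 1e-8)`.
#'
#' @param model A [rate_model].
#' @param x State vector at which to differentiate.
#' @param t Time (non-autonomous models only).
#' @return The N x N matrix `J[i, j] = d f_i / d x_j`, dimnames set to the
#'   species names.
#' @export
numerical_jacobian <- function(model, x, t = 0) {
  stopifnot(inherits(model, "rate_model"))
  x <- as.numeric(x)
  n <- length(model$species)
  stopifnot(length(x) == n, all(is.finite(x)))
  J <- matrix(NA_real_, n, n, dimnames = list(model$species, model$species))
  for (j in seq_len(n)) {
    h <- max(1e-6 * abs(x[j]), 1e-8)
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    fp <- model$rate(xp, t)
    fm <- model$rate(xm, t)
    if (any(!is.finite(fp)) || any(!is.finite(fm))) {
      bad <- model$species[which(!is.finite(fp) | !is.finite(fm))[1]]
      stop(sprintf(
        "non-finite rate for species '%s' while probing derivative w.r.t. '%s'",
        bad, model$species[j]))
    }
    J[, j] <- (fp - fm) / (2 * h)
  }
  J
}

#' Find the steady state of a rate model
#'
#' Integrates the ODE from `x0` for a burn-in horizon, then polishes the
#' endpoint with damped Newton iterations on the rate equations. The
#' integrate-then-polish strategy converges to the stable steady state that
#' the stimulated system actually relaxes into, avoiding spurious unstable
#' fixed points (such as the fully inactive state) that a pure root-finder
#' could return. Local stability is checked through the eigenvalues of the
#' Jacobian at the solution; an unstable solution triggers a warning and is
#' flagged.
#'
#' @param model An autonomous [rate_model].
#' @param x0 Initial state, componentwise within `[0, totals]`; defaults to
#'   the starved state (all zeros).
#' @param tol Residual tolerance: convergence requires `max |f_i| < tol`.
#' @param burn_in Integration horizon (minutes) before polishing; extended
#'   once (x 30) if the first pass does not converge.
#' @param max_newton Newton iteration budget per polish.
#' @return Object of class `steady_state`: fields `state` (named vector),
#'   `residual_norm`, `converged`, `stable`, `eigenvalues`.
#' @export
find_steady_state <- function(model, x0 = NULL, tol = 1e-9,
                              burn_in = 500, max_newton = 50) {
  stopifnot(inherits(model, "rate_model"))
  if (!model$autonomous) {
    stop("model is non-autonomous (time-dependent inputs); ",
         "no fixed point is defined - use simulate_timecourse()")
  }
  n <- length(model$species)
  if (is.null(x0)) x0 <- rep(0, n)
  stopifnot(length(x0) == n)
  if (any(x0 < -1e-12) || any(x0 > model$totals + 1e-12)) {
    stop("x0 must lie within [0, totals] componentwise")
  }

  solve_once <- function(horizon) {
    # capture the solver's console chatter (step-limit diagnostics from
    # DLSODA for pathological parameter draws) along with its warnings
    utils::capture.output(
      out <- try(suppressWarnings(.integrate(model, x0, c(0, horizon))),
                 silent = TRUE),
      type = "output")
    if (inherits(out, "try-error") || nrow(out) < 2 ||
        any(!is.finite(out[nrow(out), -1]))) {
      return(NULL)
    }
    x <- as.numeric(out[nrow(out), -1])
    for (it in seq_len(max_newton)) {
      fx <- model$rate(x, horizon)
      if (any(!is.finite(fx))) return(NULL)
      if (max(abs(fx)) < tol) break
      J <- numerical_jacobian(model, x)
      step <- try(solve(J, fx), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      lambda <- 1
      repeat { # damp the step to stay in the admissible box
        xn <- x - lambda * step
        if (all(xn > -0.1 * model$totals) && all(xn < 1.1 * model$totals)) break
        lambda <- lambda / 2
        if (lambda < 1e-6) { xn <- x; break }
      }
      x <- xn
    }
    x
  }

  x <- solve_once(burn_in)
  res <- if (is.null(x)) Inf else max(abs(model$rate(x, burn_in)))
  if (!is.finite(res) || res >= tol) {
    x2 <- solve_once(30 * burn_in)
    res2 <- if (is.null(x2)) Inf else max(abs(model$rate(x2, 30 * burn_in)))
    if (is.finite(res2) && (!is.finite(res) || res2 < res)) {
      x <- x2; res <- res2
    }
  }
  if (is.null(x)) {
    return(structure(list(state = stats::setNames(rep(NA_real_, n),
                                                  model$species),
                          residual_norm = Inf, converged = FALSE,
                          stable = NA, eigenvalues = NULL),
                     class = "steady_state"))
  }
  converged <- is.finite(res) && res < tol
  ev <- NULL
  stable <- NA
  if (converged) {
    ev <- eigen(numerical_jacobian(model, x), only.values = TRUE)$values
    stable <- all(Re(ev) < 0)
    if (!stable) {
      warning("steady state is not locally stable ",
              "(Jacobian has an eigenvalue with nonnegative real part)")
    }
  }
  structure(
    list(state = stats::setNames(pmax(x, 0), model$species),
         residual_norm = res, converged = converged,
         stable = stable, eigenvalues = ev),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(residual %.3g)\n", x$residual_norm))
  print(x$state)
  invisible(x)
}

#' Local response matrix of a model at steady state
#'
#' Scales the steady-state Jacobian into local response coefficients
#' `r[i, j] = -J[i, j] * x[j] / (J[i, i] * x[i])`: the fractional change in
#' node i per fractional change in node j with every other route through the
#' network severed. Diagonal entries are `-1` by definition and are set
#' exactly. This is the model-side half of the fitting method: it requires
#' one steady state and one Jacobian, and no perturbation simulations.
#'
#' @param model An autonomous [rate_model].
#' @param ss A converged [find_steady_state()] result for `model` (computed
#'   if omitted).
#' @param condition Optional condition label attached to the result.
#' @return A `local_response_matrix`: N x N numeric matrix, diagonal exactly
#'   -1, with attribute `condition`.
#' @export
model_lrc <- function(model, ss = NULL, condition = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (is.null(ss)) ss <- find_steady_state(model)
  stopifnot(inherits(ss, "steady_state"))
  if (!isTRUE(ss$converged)) {
    stop("steady state did not converge; cannot compute local response matrix")
  }
  x <- as.numeric(ss$state)
  if (any(x <= 0)) {
    stop("degenerate steady state: zero concentration for species ",
         paste(model$species[x <= 0], collapse = ", "),
         " - this condition cannot yield local response coefficients")
  }
  J <- numerical_jacobian(model, x)
  dJ <- diag(J)
  if (any(dJ == 0) || any(!is.finite(dJ))) {
    stop("degenerate Jacobian: zero diagonal element, ",
         "local response coefficients undefined")
  }
  r <- -J * outer(1 / (dJ * x), x)
  diag(r) <- -1
  local_response_matrix(r, condition = condition)
}

#' Construct/validate a local response matrix
#'
#' @param r Square numeric matrix of local response coefficients; diagonal is
#'   forced to exactly -1 (the defining convention).
#' @param condition Optional condition label (ligand, dose).
#' @return Matrix of class `local_response_matrix`.
#' @export
local_response_matrix <- function(r, condition = NULL) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), all(is.finite(r)))
  diag(r) <- -1
  structure(r, class = c("local_response_matrix", "matrix"),
            condition = condition)
}

#' Off-diagonal entries of a square matrix, column-major
#' @param m Square matrix.
#' @return Numeric vector of the `n^2 - n` off-diagonal entries.
#' @export
offdiag <- function(m) {
  m <- as.matrix(m)
  m[row(m) != col(m)]
}
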