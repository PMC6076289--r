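#' Michaelis-Menten activation rate
#'
#' Rate of activation of a substrate pool `S` catalysed by a modifier `M`:
#' `k * S * M / (K + S)`. This is the elementary building block of the MAPK
#' cascade models, where `S` is the inactive form of a kinase and `M` the
#' upstream activator (a ligand input or an active kinase).
#'
#' @param k Rate constant (> 0, per concentration per minute).
#' @param K Michaelis constant (> 0, concentration units).
#' @param S Substrate concentration (>= 0).
#' @param M Modifier concentration (>= 0).
#' @return The reaction rate, a nonnegative number; monotone increasing in
#'   both `S` and `M`.
#' @examples
#' michaelis_activation(k = 1, K = 10, S = 10, M = 1) # 0.5
#' @export
michaelis_activation <- function(k, K, S, M) {
  if (any(K <= 0)) stop("Michaelis constant K must be strictly positive")
  k * S * M / (K + S)
}

#' Michaelis-Menten decay rate
#'
#' Saturable first-order inactivation `V * S / (K + S)`, bounded above by the
#' maximal rate `V`. Models phosphatase-mediated deactivation of an active
#' kinase pool.
#'
#' @param V Maximal rate (> 0).
#' @param K Michaelis constant (> 0).
#' @param S Substrate concentration (>= 0).
#' @return The decay rate, in `[0, V)` for finite `S`.
#' @examples
#' michaelis_decay(V = 2, K = 10, S = 10) # 1
#' @export
michaelis_decay <- function(V, K, S) {
  if (any(K <= 0)) stop("Michaelis constant K must be strictly positive")
  V * S / (K + S)
}

#' Construct an ODE rate model of a signalling network
#'
#' A `rate_model` bundles everything needed to evaluate d(state)/dt for an
#' N-node network: the ordered species names (active forms), a rate function,
#' the named parameter vector, the total concentration of each species
#' (active + inactive pool), and any ligand inputs. Models built from the
#' bundled MAPK equations additionally carry a `native` descriptor so that
#' time integration can run through deSolve's compiled-code interface.
#'
#' @param species Character vector of active-form node names (state order).
#' @param rate Function `(state, t)` returning the length-N derivative vector.
#'   For autonomous models `t` is ignored.
#' @param parameters Named numeric vector of strictly positive parameters.
#' @param totals Named numeric vector of strictly positive total
#'   concentrations, one per species; the inactive pool of species i is
#'   `totals[i] - state[i]`.
#' @param inputs Named list/vector of nonnegative ligand levels (may be empty).
#' @param native Optional list `(func, initfunc, parms)` naming compiled
#'   deSolve routines in this package's DLL. Internal use.
#' @param autonomous Logical; `FALSE` for models whose rate depends on time
#'   (transient ligand inputs), in which case no fixed point is sought.
#' @param n_unknowns Number of quantities treated as unknown when the model is
#'   fitted (free kinetic parameters, plus totals where those are inferred).
#' @param label Short human-readable model name.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(species, rate, parameters, totals, inputs = list(),
                       native = NULL, autonomous = TRUE,
                       n_unknowns = length(parameters), label = "rate_model") {
  stopifnot(is.character(species), length(species) >= 1, is.function(rate))
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("all parameters must be named")
  }
  if (any(!is.finite(parameters)) || any(parameters <= 0)) {
    stop("all parameters must be finite and strictly positive")
  }
  if (length(totals) != length(species)) {
    stop("one total concentration is required per species")
  }
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("all total concentrations must be finite and strictly positive")
  }
  if (is.null(names(totals))) names(totals) <- species
  if (length(inputs) && any(unlist(inputs) < 0)) {
    stop("ligand inputs must be nonnegative")
  }
  structure(
    list(species = species, rate = rate, parameters = parameters,
         totals = totals, inputs = inputs, native = native,
         autonomous = autonomous, n_unknowns = n_unknowns, label = label),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s\n", x$label))
  cat(sprintf("  species: %s\n", paste(x$species, collapse = ", ")))
  cat(sprintf("  %d parameters, %d treated as unknown when fitting\n",
              length(x$parameters), x$n_unknowns))
  cat(sprintf("  totals: %s\n",
              paste(sprintf("%s=%g", names(x$totals), x$totals),
                    collapse = ", ")))
  if (length(x$inputs)) {
    cat(sprintf("  inputs: %s\n",
                paste(sprintf("%s=%g", names(x$inputs), unlist(x$inputs)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Evaluate the rate vector of a model
#'
#' @param model A `rate_model`.
#' @param state Numeric state vector (active concentrations), length and order
#'   matching `model$species`.
#' @param t Time at which to evaluate (matters only for non-autonomous models).
#' @return Named numeric vector of derivatives.
#' @export
model_rate <- function(model, state, t = 0) {
  stopifnot(inherits(model, "rate_model"),
            length(state) == length(model$species))
  out <- model$rate(as.numeric(state), t)
  names(out) <- model$species
  out
}

#' Number of unknown quantities a model exposes to fitting
#'
#' @param model A `rate_model`.
#' @return Integer count: free kinetic parameters plus, where applicable,
#'   total concentrations that are themselves inferred.
#' @export
n_unknowns <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  as.integer(model$n_unknowns)
}
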