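# Bridges the sampler to the models: a particle evaluator that, for one
# parameter draw, computes model-side response features (LRCs per condition,
# ligand response ratios against the reference) from steady states and
# Jacobians only — no perturbation is ever simulated — and returns the
# composite distance to the observed features.

#' Build a steady-state LRC evaluator for ABC-SMC
#'
#' Returns a closure suitable for [run_abc_smc()]: given a parameter vector
#' it builds one model per observed condition, solves each model's single
#' unperturbed steady state, converts the steady-state Jacobians into local
#' response matrices, forms ligand response ratios against the reference
#' condition, and evaluates [overall_distance()] to the observed
#' [response_set()]. Any failure (no convergence, instability, a degenerate
#' zero-concentration state) yields `Inf`, i.e. the particle is rejected.
#'
#' @param observed The data-derived [response_set()]; its condition elements
#'   must carry `dose` (as produced by [estimate_response_set()]).
#' @param model_builder Function `(theta, dose)` returning an autonomous
#'   [rate_model]; `theta` is the named parameter vector being fitted.
#' @param require_stable Reject steady states whose Jacobian has an
#'   eigenvalue with nonnegative real part (default `TRUE`).
#' @param ss_tol Residual tolerance passed to [find_steady_state()].
#' @return Function `theta -> list(distance, features)`.
#' @export
lrc_evaluator <- function(observed, model_builder, require_stable = TRUE,
                          ss_tol = 1e-9) {
  stopifnot(inherits(observed, "response_set"), is.function(model_builder))
  cond_names <- names(observed$conditions)
  doses <- vapply(observed$conditions, function(cc) {
    if (is.null(cc$dose)) NA_real_ else as.numeric(cc$dose)
  }, numeric(1))
  if (any(is.na(doses))) {
    stop("every observed condition must carry its ligand dose")
  }
  reference <- observed$reference

  function(theta) {
    sim <- vector("list", length(cond_names))
    names(sim) <- cond_names
    xs <- vector("list", length(cond_names))
    names(xs) <- cond_names
    ok <- tryCatch({
      for (nm in cond_names) {
        model <- model_builder(theta, doses[[nm]])
        ss <- find_steady_state(model, tol = ss_tol)
        if (!isTRUE(ss$converged)) return(list(distance = Inf))
        if (require_stable && !isTRUE(ss$stable)) return(list(distance = Inf))
        sim[[nm]] <- list(r = suppressWarnings(model_lrc(model, ss)),
                          dose = doses[[nm]])
        xs[[nm]] <- ss$state
      }
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!isTRUE(ok)) return(list(distance = Inf))
    if (!is.null(reference)) {
      for (nm in cond_names) {
        if (!is.null(observed$conditions[[nm]]$rho)) {
          sim[[nm]]$rho <- tryCatch(
            ligand_response_ratios(xs[[nm]], xs[[reference]]),
            error = function(e) NULL)
          if (is.null(sim[[nm]]$rho)) return(list(distance = Inf))
        }
      }
    }
    sim_rs <- response_set(sim, reference = reference)
    d <- tryCatch(overall_distance(observed, sim_rs),
                  error = function(e) Inf)
    list(distance = d, features = sim_rs)
  }
}

#' Evaluator builder for the bundled EGF-driven MAPK model
#'
#' Convenience wrapper around [lrc_evaluator()] for the standard in-silico
#' protocol: totals are treated as known, and the 16 kinetic parameters are
#' fitted.
#'
#' @param observed The data-derived [response_set()].
#' @param totals Known total concentrations (default
#'   [mapk_default_totals()]).
#' @return Function `theta -> list(distance, features)`.
#' @export
mapk_egf_evaluator <- function(observed, totals = mapk_default_totals()) {
  lrc_evaluator(observed, function(theta, dose) {
    build_mapk_egf_model(theta, totals, egf = dose)
  })
}
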