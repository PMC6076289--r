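# In-silico perturbation experiments: starved cells, ligand stimulation to
# steady state, siRNA knockdowns of total kinase pools, antibody/reporter
# amplification, additive Gaussian measurement noise, replicates.

#' Apply an siRNA-style knockdown to a model
#'
#' siRNA transfection reduces the total amount of its target protein, so a
#' knockdown is modelled by scaling the target's total concentration by
#' `1 - fraction`; every parameter and every other total is unchanged.
#'
#' @param model A [rate_model].
#' @param target Species name to knock down.
#' @param fraction Knockdown fraction, strictly between 0 and 1.
#' @return A new [rate_model] with the reduced total.
#' @export
apply_knockdown <- function(model, target, fraction) {
  stopifnot(inherits(model, "rate_model"))
  idx <- match(target, model$species)
  if (is.na(idx)) {
    stop("unknown species '", target, "'; model species are: ",
         paste(model$species, collapse = ", "))
  }
  if (length(fraction) != 1 || !is.finite(fraction) ||
      fraction <= 0 || fraction >= 1) {
    stop("knockdown fraction must lie strictly between 0 and 1")
  }
  totals <- model$totals
  totals[idx] <- totals[idx] * (1 - fraction)
  # Rebuild through the model's own constructor path where possible so the
  # compiled parameter vector stays consistent with the totals.
  if (!is.null(model$native) && model$native$func == "derivs_mapk_egf") {
    return(build_mapk_egf_model(model$parameters, totals,
                                egf = model$inputs$EGF))
  }
  if (!is.null(model$native) && model$native$func == "derivs_mapk_egf_ngf") {
    ligand <- if (model$inputs$EGF > 0 || model$inputs$NGF == 0) "EGF" else "NGF"
    dose <- max(model$inputs$EGF, model$inputs$NGF)
    return(build_mapk_egf_ngf_model(model$parameters, totals,
                                    ligand = ligand, dose = dose))
  }
  m <- model
  m$totals <- totals
  m
}

#' Simulate a steady-state perturbation experiment
#'
#' Emulates the full in-silico protocol: for each ligand dose, starved cells
#' (zero active kinases) are stimulated and relaxed to steady state, both
#' unperturbed and under one knockdown per species; steady concentrations are
#' amplified by a large constant `k_f` (antibody/reporter readout) and each
#' of `n_replicates` replicate measurements receives i.i.d. additive Gaussian
#' noise of standard deviation `sigma` on the amplified scale. Noisy values
#' are floored at `1e-6 * k_f` so that ratio-based downstream quantities stay
#' defined.
#'
#' @param model_builder Function `(dose)` returning an autonomous
#'   [rate_model] for that ligand dose (totals and parameters baked in).
#' @param doses Positive ligand doses; the in-silico study uses EGF at
#'   0.1, 1, 2 and 5 ng/ml.
#' @param knockdown_fraction Fraction of each target's total removed by its
#'   siRNA (default 0.5).
#' @param k_f Amplification constant (default 100).
#' @param sigma Noise standard deviation on the amplified scale; the study
#'   grid is 0, 2, 5, 10, 15, 20.
#' @param n_replicates Replicates per measurement (default 6).
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @param ligand Ligand label stored in the dataset (default `"EGF"`).
#' @return Long-form data.frame (see [aggregate_replicates()] for the
#'   schema) with a `meta` attribute recording `k_f`, `sigma`,
#'   `knockdown_fraction`, `n_replicates` and `seed`.
#' @export
simulate_experiment <- function(model_builder,
                                doses = c(0.1, 1, 2, 5),
                                knockdown_fraction = 0.5,
                                k_f = 100,
                                sigma = 0,
                                n_replicates = 6,
                                seed = 1,
                                ligand = "EGF") {
  stopifnot(is.function(model_builder), all(doses > 0),
            n_replicates >= 1, sigma >= 0, k_f > 0)
  if (is.null(seed)) stop("a seed is required")
  set.seed(seed)
  floor_value <- 1e-6 * k_f
  rows <- list()
  for (dose in doses) {
    cid <- sprintf("%s_%g", ligand, dose)
    base <- model_builder(dose)
    targets <- c("none", base$species)
    for (tg in targets) {
      m <- if (tg == "none") base else {
        apply_knockdown(base, tg, knockdown_fraction)
      }
      ss <- find_steady_state(m)
      if (!isTRUE(ss$converged)) {
        stop(sprintf("steady state failed at dose %g, perturbation '%s'",
                     dose, tg))
      }
      amp <- k_f * ss$state
      for (sp in m$species) {
        noisy <- amp[[sp]] + stats::rnorm(n_replicates, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cid, ligand = ligand, dose = dose,
          perturbation_target = tg, replicate = seq_len(n_replicates),
          species = sp, value = pmax(noisy, floor_value),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "meta") <- list(k_f = k_f, sigma = sigma,
                            knockdown_fraction = knockdown_fraction,
                            n_replicates = n_replicates, seed = seed,
                            doses = doses, ligand = ligand)
  out
}
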