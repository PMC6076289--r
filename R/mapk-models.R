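# Bundled MAPK/ERK cascade models. Three active-kinase states (aRAF, aMEK,
# aERK); inactive pools are totals minus active forms. Units are arbitrary
# concentration units and minutes.

.mapk_species <- c("aRAF", "aMEK", "aERK")

.mapk_egf_par_names <- c(
  "k_f1", "K_mf1", "V_m1", "K_m1",
  "k_f2", "K_mf2", "V_m2", "K_m2",
  "k_f3", "K_mf3", "V_m3", "K_m3",
  "k_r1", "K_mr1", "k_r2", "K_mr2"
)

.mapk_egf_ngf_par_names <- c(
  "k_f11", "K_mf11", "k_r12", "K_mr12",
  "k_f13", "K_mf13", "k_f14", "K_mf14",
  "V_m1", "K_m1",
  "k_f21", "K_mf21", "k_f22", "K_mf22",
  "V_m2", "K_m2",
  "k_f31", "K_mf31", "k_f32", "K_mf32",
  "V_m3", "K_m3",
  "kd_egf", "kd_ngf"
)

.check_named_pars <- function(parameters, needed, what) {
  missing <- setdiff(needed, names(parameters))
  if (length(missing)) {
    stop(sprintf("missing %s parameter(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  p <- parameters[needed]
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop(sprintf("all %s parameters must be finite and strictly positive",
                 what))
  }
  p
}

#' Reference parameters of the EGF-driven MAPK cascade model
#'
#' The 16 rate constants, Michaelis constants and maximal rates of the
#' three-tier RAF/MEK/ERK model with two ERK-mediated negative feedback
#' loops, at the values used throughout the in-silico study.
#'
#' @return Named numeric vector of length 16.
#' @export
mapk_egf_parameters <- function() {
  c(k_f1 = 1, K_mf1 = 10, V_m1 = 2, K_m1 = 10,
    k_f2 = 1, K_mf2 = 10, V_m2 = 1, K_m2 = 10,
    k_f3 = 0.1, K_mf3 = 10, V_m3 = 10, K_m3 = 10,
    k_r1 = 1, K_mr1 = 10, k_r2 = 1, K_mr2 = 10)
}

#' Default total kinase concentrations
#'
#' Total (active + inactive) RAF, MEK and ERK used by the in-silico
#' perturbation study. Order-of-magnitude consistent with the models'
#' half-saturation constants (all Michaelis constants are 10).
#'
#' @return Named numeric vector `(RAF_TOT, MEK_TOT, ERK_TOT)`.
#' @export
mapk_default_totals <- function() {
  c(RAF_TOT = 100, MEK_TOT = 100, ERK_TOT = 100)
}

#' Build the EGF-driven MAPK cascade model
#'
#' Three-species ODE model of the RAF -> MEK -> ERK cascade in which EGF acts
#' directly as the activating modifier of RAF, and active ERK feeds back
#' negatively on both RAF and MEK by catalysing their inactivation. All
#' activation/inactivation steps are Michaelis-Menten terms
#' ([michaelis_activation()], [michaelis_decay()]):
#'
#' \preformatted{
#' d(aRAF)/dt = Ma(k_f1, K_mf1, iRAF, EGF)  - Ma(k_r1, K_mr1, aRAF, aERK)
#'              - M0(V_m1, K_m1, aRAF)
#' d(aMEK)/dt = Ma(k_f2, K_mf2, iMEK, aRAF) - Ma(k_r2, K_mr2, aMEK, aERK)
#'              - M0(V_m2, K_m2, aMEK)
#' d(aERK)/dt = Ma(k_f3, K_mf3, iERK, aMEK) - M0(V_m3, K_m3, aERK)
#' }
#'
#' with `iX = X_TOT - aX`. The model has 16 free parameters.
#'
#' @param parameters Named vector containing the 16 parameters of
#'   [mapk_egf_parameters()] (extra names are ignored).
#' @param totals Named vector `(RAF_TOT, MEK_TOT, ERK_TOT)`, all positive.
#' @param egf EGF dose (nonnegative; ng/ml in the simulated protocol).
#' @return A [rate_model] with species `aRAF, aMEK, aERK`.
#' @export
build_mapk_egf_model <- function(parameters = mapk_egf_parameters(),
                                 totals = mapk_default_totals(),
                                 egf = 0.1) {
  p <- .check_named_pars(parameters, .mapk_egf_par_names, "MAPK/EGF")
  tot <- .check_named_pars(totals, c("RAF_TOT", "MEK_TOT", "ERK_TOT"),
                           "total-concentration")
  if (length(egf) != 1 || !is.finite(egf) || egf < 0) {
    stop("egf dose must be a single nonnegative number")
  }
  force(p); force(tot)
  rate <- function(state, t = 0) {
    aRAF <- state[1]; aMEK <- state[2]; aERK <- state[3]
    c(
      michaelis_activation(p[["k_f1"]], p[["K_mf1"]], tot[[1]] - aRAF, egf) -
        michaelis_activation(p[["k_r1"]], p[["K_mr1"]], aRAF, aERK) -
        michaelis_decay(p[["V_m1"]], p[["K_m1"]], aRAF),
      michaelis_activation(p[["k_f2"]], p[["K_mf2"]], tot[[2]] - aMEK, aRAF) -
        michaelis_activation(p[["k_r2"]], p[["K_mr2"]], aMEK, aERK) -
        michaelis_decay(p[["V_m2"]], p[["K_m2"]], aMEK),
      michaelis_activation(p[["k_f3"]], p[["K_mf3"]], tot[[3]] - aERK, aMEK) -
        michaelis_decay(p[["V_m3"]], p[["K_m3"]], aERK)
    )
  }
  rate_model(
    species = .mapk_species, rate = rate, parameters = p, totals = tot,
    inputs = list(EGF = egf),
    native = list(func = "derivs_mapk_egf", initfunc = "initmod_mapk_egf",
                  parms = unname(c(p, tot, egf))),
    autonomous = TRUE, n_unknowns = 16L, label = "MAPK cascade (EGF input)"
  )
}

#' Transient RAS activation pulse downstream of a ligand
#'
#' Receptor/adaptor/RAS signalling is collapsed into a gamma-function input
#' `(L / (1 + L)) * t^5 * exp(-kd * t)`: zero at `t = 0`, unimodal in time
#' with its peak at `t = 5 / kd` minutes, saturating in the ligand dose `L`.
#'
#' @param ligand_level Ligand dose `L` (>= 0).
#' @param kd Decay rate of the pulse (> 0, per minute).
#' @param t Time (>= 0, minutes); may be a vector.
#' @return Input level(s), nonnegative.
#' @export
ras_input <- function(ligand_level, kd, t) {
  if (any(ligand_level < 0)) stop("ligand level must be nonnegative")
  if (any(kd <= 0)) stop("decay rate kd must be strictly positive")
  if (any(t < 0)) stop("time must be nonnegative")
  (ligand_level / (1 + ligand_level)) * t^5 * exp(-kd * t)
}

#' Build the EGF/NGF MAPK cascade model with transient RAS input
#'
#' Three-species RAF/MEK/ERK model for cells stimulated with either EGF or
#' NGF. RAF is driven by a transient RAS pulse ([ras_input()]) rather than a
#' constant ligand level, so the system is non-autonomous. Binary flags
#' `b_e`/`b_n` (set by `ligand`) switch ligand-specific wiring: under EGF an
#' ERK-mediated negative feedback on RAF (`k_r12` term); under NGF a positive
#' ERK->RAF feedback (`k_f14` term) and a RAF->ERK feed-forward (`k_f32`
#' term). The 24 kinetic parameters plus the three totals give 27 unknowns.
#'
#' @param parameters Named vector with the 24 parameters listed in
#'   `mapk_egf_ngf_parameter_names()`.
#' @param totals Named vector `(RAF_TOT, MEK_TOT, ERK_TOT)`.
#' @param ligand `"EGF"` or `"NGF"`; selects `(b_e, b_n) = (1, 0)` or
#'   `(0, 1)`. Supplying both flags is a configuration error by construction.
#' @param dose Ligand dose (>= 0).
#' @return A non-autonomous [rate_model].
#' @export
build_mapk_egf_ngf_model <- function(parameters,
                                     totals = c(RAF_TOT = 25, MEK_TOT = 100,
                                                ERK_TOT = 400),
                                     ligand = c("EGF", "NGF"),
                                     dose = 1) {
  p <- .check_named_pars(parameters, .mapk_egf_ngf_par_names, "MAPK/EGF-NGF")
  tot <- .check_named_pars(totals, c("RAF_TOT", "MEK_TOT", "ERK_TOT"),
                           "total-concentration")
  ligand <- match.arg(ligand)
  if (length(dose) != 1 || !is.finite(dose) || dose < 0) {
    stop("ligand dose must be a single nonnegative number")
  }
  b_e <- as.numeric(ligand == "EGF")
  b_n <- as.numeric(ligand == "NGF")
  egf <- if (b_e) dose else 0
  ngf <- if (b_n) dose else 0
  force(p); force(tot)
  rate <- function(state, t = 0) {
    aRAF <- state[1]; aMEK <- state[2]; aERK <- state[3]
    iRAF <- tot[[1]] - aRAF; iMEK <- tot[[2]] - aMEK; iERK <- tot[[3]] - aERK
    ras_egf <- if (b_e) ras_input(egf, p[["kd_egf"]], t) else 0
    ras_ngf <- if (b_n) ras_input(ngf, p[["kd_ngf"]], t) else 0
    c(
      b_e * (michaelis_activation(p[["k_f11"]], p[["K_mf11"]], iRAF, ras_egf) -
               michaelis_activation(p[["k_r12"]], p[["K_mr12"]], aRAF, aERK)) +
        b_n * (michaelis_activation(p[["k_f13"]], p[["K_mf13"]], iRAF, ras_ngf) +
                 michaelis_activation(p[["k_f14"]], p[["K_mf14"]], iRAF, aERK)) -
        michaelis_decay(p[["V_m1"]], p[["K_m1"]], aRAF),
      michaelis_activation(p[["k_f21"]], p[["K_mf21"]], iMEK, aRAF) -
        michaelis_activation(p[["k_f22"]], p[["K_mf22"]], aMEK, aERK) -
        michaelis_decay(p[["V_m2"]], p[["K_m2"]], aMEK),
      michaelis_activation(p[["k_f31"]], p[["K_mf31"]], iERK, aMEK) +
        b_n * michaelis_activation(p[["k_f32"]], p[["K_mf32"]], iERK, aRAF) -
        michaelis_decay(p[["V_m3"]], p[["K_m3"]], aERK)
    )
  }
  rate_model(
    species = .mapk_species, rate = rate, parameters = p, totals = tot,
    inputs = list(EGF = egf, NGF = ngf),
    native = list(func = "derivs_mapk_egf_ngf",
                  initfunc = "initmod_mapk_egf_ngf",
                  parms = unname(c(p, tot, b_e, b_n, egf, ngf))),
    autonomous = FALSE, n_unknowns = 27L,
    label = sprintf("MAPK cascade (transient RAS input, %s)", ligand)
  )
}

#' Parameter names of the EGF/NGF MAPK model
#'
#' @return Character vector of the 24 free kinetic parameter names, in the
#'   order expected by [build_mapk_egf_ngf_model()].
#' @export
mapk_egf_ngf_parameter_names <- function() .mapk_egf_ngf_par_names
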