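# The composite distance between data-derived and model-derived response
# features: per-condition local response matrices and ligand response ratios,
# each block normalised by the observed-side Euclidean norm, plus optional
# time-course and pseudo-steady-state augmentation blocks.

#' Bundle response features per condition
#'
#' A `response_set` holds, for each experimental condition (ligand, dose),
#' the features compared during fitting: the local response matrix `r`,
#' optional ligand response ratios `rho` against a reference condition,
#' optional time-course measurements, and optional pseudo-steady-state
#' constraints (time points where all rates must vanish).
#'
#' @param conditions Named list; each element is a list with fields `r`
#'   (square matrix, diagonal -1), and optionally `rho` (positive named
#'   vector), `timecourse` (data.frame `time`, `species`, `value`),
#'   `pss_times` (numeric vector of minutes), `rates` (numeric vector of
#'   model rate values at the pseudo-steady-state times, simulated side
#'   only), plus free-form metadata (`ligand`, `dose`, `x`, `R`).
#' @param reference Optional reference condition id for the ratios.
#' @return Object of class `response_set`.
#' @export
response_set <- function(conditions, reference = NULL) {
  stopifnot(is.list(conditions), length(conditions) >= 1)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("every condition must be named")
  }
  for (nm in names(conditions)) {
    cc <- conditions[[nm]]
    if (!is.null(cc$r)) {
      r <- as.matrix(cc$r)
      if (nrow(r) != ncol(r) || any(!is.finite(r))) {
        stop("condition ", nm, ": r must be a finite square matrix")
      }
      if (any(abs(diag(r) + 1) > 1e-12)) {
        stop("condition ", nm, ": diagonal of r must be -1")
      }
    }
    if (!is.null(cc$rho) && any(cc$rho <= 0)) {
      stop("condition ", nm, ": ligand response ratios must be positive")
    }
  }
  structure(list(conditions = conditions, reference = reference),
            class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> %d condition(s)%s\n", length(x$conditions),
              if (is.null(x$reference)) "" else
                sprintf(", reference '%s'", x$reference)))
  for (nm in names(x$conditions)) {
    cc <- x$conditions[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(c(
      if (!is.null(cc$r)) sprintf("r %dx%d", nrow(cc$r), ncol(cc$r)),
      if (!is.null(cc$rho)) sprintf("rho[%d]", length(cc$rho)),
      if (!is.null(cc$timecourse)) sprintf("timecourse[%d]",
                                           nrow(cc$timecourse)),
      if (!is.null(cc$pss_times)) sprintf("pss at t={%s}",
                                          paste(cc$pss_times, collapse = ","))
    ), collapse = ", ")))
  }
  invisible(x)
}

.euclid <- function(a, b) sqrt(sum((a - b)^2))

.match_conditions <- function(observed, simulated) {
  obs <- names(observed$conditions)
  sim <- names(simulated$conditions)
  miss <- setdiff(obs, sim)
  if (length(miss)) {
    stop("simulated response set is missing condition(s): ",
         paste(miss, collapse = ", "))
  }
  obs
}

#' Overall distance between observed and simulated response features
#'
#' Sum over conditions of the Euclidean distance between off-diagonal local
#' response coefficients, each weighted by the inverse observed-side norm
#' `n_r = sqrt(sum of squared off-diagonal r)`, plus, for conditions carrying
#' ligand response ratios, the Euclidean distance between ratio vectors
#' weighted by `1 / n_rho`. Diagonals of `r` are excluded: they are -1 by
#' construction on both sides and carry no information.
#'
#' @param observed,simulated [response_set()] objects over the same
#'   conditions (the simulated set may contain extra conditions).
#' @return Nonnegative scalar; zero iff all compared features coincide.
#' @export
overall_distance <- function(observed, simulated) {
  stopifnot(inherits(observed, "response_set"),
            inherits(simulated, "response_set"))
  total <- 0
  for (nm in .match_conditions(observed, simulated)) {
    oc <- observed$conditions[[nm]]
    sc <- simulated$conditions[[nm]]
    if (!is.null(oc$r)) {
      if (is.null(sc$r) || !all(dim(sc$r) == dim(oc$r))) {
        stop("condition ", nm, ": simulated r missing or of different shape")
      }
      ro <- offdiag(oc$r)
      n_r <- sqrt(sum(ro^2))
      if (n_r == 0) stop("condition ", nm, ": observed r norm is zero")
      total <- total + .euclid(ro, offdiag(sc$r)) / n_r
    }
    if (!is.null(oc$rho)) {
      if (is.null(sc$rho) || length(sc$rho) != length(oc$rho)) {
        stop("condition ", nm, ": simulated rho missing or of different length")
      }
      n_rho <- sqrt(sum(oc$rho^2))
      if (n_rho == 0) stop("condition ", nm, ": observed rho norm is zero")
      total <- total + .euclid(as.numeric(oc$rho), as.numeric(sc$rho)) / n_rho
    }
  }
  total
}

#' Augmented distance: response features plus kinetics
#'
#' Extends [overall_distance()] with two further per-condition blocks, each
#' normalised like the core blocks: (a) the Euclidean distance between
#' observed and simulated time courses, divided by the observed-side norm;
#' and (b) the Euclidean norm of the model's rate vectors at the
#' pseudo-steady-state times (times where concentrations transiently peak,
#' so all derivatives should vanish; the target is 0 and the block weight
#' is 1).
#'
#' @param observed,simulated [response_set()] objects; conditions with a
#'   `timecourse` on the observed side require a matching grid on the
#'   simulated side, and conditions with `pss_times` require simulated
#'   `rates`.
#' @return Nonnegative scalar.
#' @export
augmented_distance <- function(observed, simulated) {
  total <- overall_distance(observed, simulated)
  for (nm in .match_conditions(observed, simulated)) {
    oc <- observed$conditions[[nm]]
    sc <- simulated$conditions[[nm]]
    if (!is.null(oc$timecourse)) {
      if (is.null(sc$timecourse)) {
        stop("condition ", nm, ": simulated time course is missing")
      }
      m <- merge(oc$timecourse, sc$timecourse, by = c("time", "species"),
                 suffixes = c("_obs", "_sim"))
      if (nrow(m) != nrow(oc$timecourse)) {
        stop("condition ", nm, ": time-course grids do not match")
      }
      n_tc <- sqrt(sum(m$value_obs^2))
      if (n_tc == 0) stop("condition ", nm, ": observed time-course norm is 0")
      total <- total + .euclid(m$value_obs, m$value_sim) / n_tc
    }
    if (!is.null(oc$pss_times)) {
      if (is.null(sc$rates)) {
        stop("condition ", nm, ": simulated rates at pseudo-steady-state ",
             "times are missing")
      }
      total <- total + sqrt(sum(as.numeric(sc$rates)^2))
    }
  }
  total
}

#' Count the constraint points a response set provides
#'
#' Bookkeeping for parameter identifiability: each condition contributes its
#' off-diagonal local response coefficients (`N^2 - N`; the -1 diagonal is a
#' definition, not data), its ligand response ratios, one vanishing-rate
#' constraint per species per pseudo-steady-state time, and one point per
#' time-course measurement.
#'
#' @param rs A [response_set()].
#' @param n_species Number of network nodes (inferred from `r` when present).
#' @return Integer count of constraint points.
#' @export
feature_count <- function(rs, n_species = NULL) {
  stopifnot(inherits(rs, "response_set"))
  total <- 0L
  for (cc in rs$conditions) {
    n <- if (!is.null(cc$r)) nrow(cc$r) else n_species
    if (!is.null(cc$r)) total <- total + n * n - n
    if (!is.null(cc$rho)) total <- total + length(cc$rho)
    if (!is.null(cc$pss_times)) {
      if (is.null(n)) stop("n_species is needed to count rate constraints")
      total <- total + length(cc$pss_times) * n
    }
    if (!is.null(cc$timecourse)) total <- total + nrow(cc$timecourse)
  }
  as.integer(total)
}
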