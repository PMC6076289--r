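# Data-side modular response analysis: from replicate steady-state
# perturbation measurements to global response matrices, local response
# matrices and ligand response ratios.

.pert_cols <- c("condition_id", "ligand", "dose", "perturbation_target",
                "replicate", "species", "value")

.check_pert_schema <- function(dataset) {
  missing <- setdiff(.pert_cols, names(dataset))
  if (length(missing)) {
    stop("perturbation dataset is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(dataset)
}

#' Average replicate measurements of a perturbation dataset
#'
#' Collapses the replicate dimension by the arithmetic sample mean, per
#' (condition, perturbation target, species) cell, and records the replicate
#' count. Every cell of the (condition x perturbation x species) grid must be
#' present.
#'
#' @param dataset Long-form data.frame with columns `condition_id`, `ligand`,
#'   `dose`, `perturbation_target` (`"none"` for the unperturbed control),
#'   `replicate`, `species`, `value`.
#' @return data.frame with one row per cell: `condition_id`, `ligand`,
#'   `dose`, `perturbation_target`, `species`, `mean_value`, `n_replicates`.
#' @export
aggregate_replicates <- function(dataset) {
  .check_pert_schema(dataset)
  if (any(!is.finite(dataset$value))) stop("non-finite measurement values")
  ag <- stats::aggregate(
    value ~ condition_id + ligand + dose + perturbation_target + species,
    data = dataset,
    FUN = function(v) c(mean = mean(v), n = length(v))
  )
  out <- data.frame(
    condition_id = ag$condition_id, ligand = ag$ligand, dose = ag$dose,
    perturbation_target = ag$perturbation_target, species = ag$species,
    mean_value = ag$value[, "mean"],
    n_replicates = as.integer(ag$value[, "n"]),
    stringsAsFactors = FALSE
  )
  # completeness: every condition needs every (perturbation x species) cell
  species <- sort(unique(out$species))
  targets <- sort(unique(out$perturbation_target))
  gaps <- character(0)
  for (cid in unique(out$condition_id)) {
    sub <- out[out$condition_id == cid, ]
    want <- expand.grid(perturbation_target = targets, species = species,
                        stringsAsFactors = FALSE)
    have <- paste(sub$perturbation_target, sub$species)
    miss <- want[!(paste(want$perturbation_target, want$species) %in% have), ]
    if (nrow(miss)) {
      gaps <- c(gaps, sprintf("%s: %s/%s", cid, miss$perturbation_target,
                              miss$species))
    }
  }
  if (length(gaps)) {
    stop("incomplete perturbation grid; missing cells: ",
         paste(gaps, collapse = "; "))
  }
  out
}

#' Global response matrix from mean concentrations
#'
#' The global response coefficient of node i to a perturbation of node j is
#' the finite-perturbation approximation to the change in log concentration,
#' `R[i, j] = 2 * (x_i^j - x_i) / (x_i + x_i^j)`, where `x_i` and `x_i^j` are
#' the unperturbed and perturbed mean steady-state concentrations. The ratio
#' form makes R invariant to any common amplification of the measurements.
#'
#' @param unperturbed Named numeric vector of unperturbed mean concentrations,
#'   one per species (all strictly positive).
#' @param perturbed Numeric matrix, species x perturbation-target, of
#'   perturbed means; column order must follow the species order so that
#'   column j is the perturbation of node j (classical MRA: exactly one
#'   perturbation per node).
#' @param condition Optional condition label.
#' @return N x N matrix of class `global_response_matrix`.
#' @export
global_response_matrix <- function(unperturbed, perturbed, condition = NULL) {
  x <- as.numeric(unperturbed)
  perturbed <- as.matrix(perturbed)
  n <- length(x)
  if (!all(dim(perturbed) == c(n, n))) {
    stop("classical MRA needs exactly one perturbation per node: ",
         "expected a ", n, " x ", n, " matrix of perturbed means, got ",
         nrow(perturbed), " x ", ncol(perturbed))
  }
  if (any(x <= 0) || any(perturbed <= 0)) {
    stop("all concentrations must be strictly positive ",
         "(the log-ratio approximation is undefined otherwise)")
  }
  R <- 2 * (perturbed - x) / (perturbed + x)
  dn <- names(unperturbed)
  if (!is.null(dn)) dimnames(R) <- list(dn, dn)
  structure(R, class = c("global_response_matrix", "matrix"),
            condition = condition)
}

#' Local response matrix from a global response matrix
#'
#' Inverts the network-propagated (global) responses into direct-interaction
#' (local) response coefficients: `r = -(dg(R^-1))^-1 R^-1`, where `dg(.)`
#' keeps the diagonal. The sign is fixed so that the diagonal equals -1, the
#' defining normalisation of local response coefficients; the diagonal is
#' then set to -1 exactly.
#'
#' @param R Square invertible matrix of global response coefficients.
#' @param max_condition Condition-number bound above which R is treated as
#'   numerically singular.
#' @return A [local_response_matrix()].
#' @export
local_response_from_global <- function(R, max_condition = 1e8) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) stop("global response matrix must be square")
  if (any(!is.finite(R))) stop("global response matrix has non-finite entries")
  if (kappa(R, exact = TRUE) > max_condition) {
    stop("global response matrix is singular or ill-conditioned ",
         "(condition number > ", format(max_condition), "); ",
         "more or better-separated perturbations are needed")
  }
  Ri <- solve(R)
  r <- -Ri / diag(Ri) # row i scaled by 1/R^-1[i, i]
  local_response_matrix(r, condition = attr(R, "condition"))
}

#' Ligand response ratios between two stimulation conditions
#'
#' Per-species ratio of unperturbed steady-state mean concentrations between
#' a condition of interest and a reference condition,
#' `rho_i = x_i^j / x_i^k`. These ratios carry the between-condition
#' information that local response matrices (which are per-condition) do not,
#' and they cancel any species-wise amplification applied identically to both
#' conditions.
#'
#' @param means Named numeric vector of unperturbed means in the condition of
#'   interest.
#' @param reference_means Named numeric vector in the reference condition;
#'   names must match `means`.
#' @return Named numeric vector of ratios (strictly positive), class
#'   `ligand_response_ratios`.
#' @export
ligand_response_ratios <- function(means, reference_means) {
  if (is.null(reference_means)) stop("reference condition is missing")
  x <- as.numeric(means); xr <- as.numeric(reference_means)
  if (length(x) != length(xr)) stop("condition/reference species mismatch")
  if (!is.null(names(means)) && !is.null(names(reference_means))) {
    if (!identical(names(means), names(reference_means))) {
      xr <- as.numeric(reference_means[names(means)])
      if (any(is.na(xr))) stop("condition/reference species mismatch")
    }
  }
  if (any(x <= 0) || any(xr <= 0)) {
    stop("ligand response ratios need strictly positive means")
  }
  structure(stats::setNames(x / xr, names(means)),
            class = "ligand_response_ratios")
}

#' Estimate a full response set from a perturbation dataset
#'
#' The complete data-side pipeline: replicate means, one global response
#' matrix per condition (Eq.-5 form), its inversion to a local response
#' matrix, and ligand response ratios of every condition against a reference
#' condition.
#'
#' @param dataset Long-form perturbation data.frame (see
#'   [aggregate_replicates()]).
#' @param reference Condition id used as the denominator of the ligand
#'   response ratios; defaults to the condition with the smallest dose. The
#'   reference condition itself carries no ratios.
#' @param species_order Optional explicit species ordering (defaults to the
#'   order of first appearance, which for bundled simulators is the model's
#'   state order).
#' @return A [response_set()] whose condition elements carry `r`, `rho`,
#'   `ligand`, `dose`, and the unperturbed means `x`.
#' @export
estimate_response_set <- function(dataset, reference = NULL,
                                  species_order = NULL) {
  means <- aggregate_replicates(dataset)
  if (is.null(species_order)) species_order <- unique(dataset$species)
  conds <- unique(means$condition_id)
  info <- unique(means[, c("condition_id", "ligand", "dose")])
  if (is.null(reference)) {
    reference <- info$condition_id[which.min(info$dose)]
  }
  if (!(reference %in% conds)) {
    stop("reference condition '", reference, "' not present in the dataset")
  }
  one_condition <- function(cid) {
    sub <- means[means$condition_id == cid, ]
    ctrl <- sub[sub$perturbation_target == "none", ]
    x <- stats::setNames(ctrl$mean_value, ctrl$species)[species_order]
    if (any(is.na(x))) stop("missing unperturbed measurements in ", cid)
    targets <- setdiff(unique(sub$perturbation_target), "none")
    if (!setequal(targets, species_order)) {
      stop("classical MRA needs exactly one perturbation per node; ",
           "condition ", cid, " has perturbations {",
           paste(sort(targets), collapse = ", "), "} for nodes {",
           paste(species_order, collapse = ", "), "}")
    }
    pert <- sapply(species_order, function(tg) {
      s <- sub[sub$perturbation_target == tg, ]
      stats::setNames(s$mean_value, s$species)[species_order]
    })
    R <- global_response_matrix(x, pert, condition = cid)
    list(r = local_response_from_global(R), R = R, x = x,
         ligand = info$ligand[info$condition_id == cid][1],
         dose = info$dose[info$condition_id == cid][1])
  }
  per_cond <- stats::setNames(lapply(conds, one_condition), conds)
  xref <- per_cond[[reference]]$x
  for (cid in setdiff(conds, reference)) {
    per_cond[[cid]]$rho <- ligand_response_ratios(per_cond[[cid]]$x, xref)
  }
  response_set(per_cond, reference = reference)
}

#' Read a perturbation dataset from CSV
#'
#' @param path CSV file with the tidy schema of [aggregate_replicates()].
#' @return data.frame, schema-checked.
#' @export
read_perturbation_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_pert_schema(d)
  d
}

#' Write a perturbation dataset to CSV
#'
#' @param dataset Perturbation data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_perturbation_csv <- function(dataset, path) {
  .check_pert_schema(dataset)
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}
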