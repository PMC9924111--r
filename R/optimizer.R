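#' Beam-weight objective
#'
#' Two-sided quadratic homogeneity objective over the target structure plus a
#' one-sided hotspot penalty over the surrounding body:
#' `C(w) = alpha * sum_target(max(0, D_v(w) - Rx)^2)
#'       + beta * sum_target(max(0, Rx - D_v(w))^2)
#'       + gamma * sum_body(max(0, D_v(w) - T)^2)`
#' with `D(w) = sum_i w_i D_i` and `T` the hotspot dose level. The body term
#' is what lets the solver shift weight from the open fields into
#' hotspot-blocking subfields: whole-brain hotspots sit largely in the scalp
#' and skull outside the target, where a target-only cost would be flat in
#' the subfield-weight direction. Coverage itself is enforced by the
#' subsequent normalization step, not by a hard constraint inside the solver.
#' Weight bounds derive from the monitor-unit floor through the linear MU
#' map.
#'
#' @param rx_gy prescription dose in Gy.
#' @param overdose_weight,underdose_weight penalty weights alpha (default 1)
#'   and beta (default 10; coverage-dominant, so the solver does not trade
#'   target coverage away for hotspot reduction and the subsequent
#'   renormalization stays close to unity).
#' @param hotspot_weight penalty weight gamma of the body hotspot term
#'   (default 1; 0 disables it).
#' @param hotspot_gy hotspot dose level `T` in Gy (default `1.07 * rx_gy`).
#' @param lower,upper per-field weight bounds (recycled; defaults 0.05 and 100,
#'   the lower bound being 5 MU under the default 100 MU-per-unit-weight map).
#' @param subsample keep every k-th target voxel in the cost (default 1 =
#'   every voxel).
#' @return An object of class `fif_objective`.
#' @export
weight_objective <- function(rx_gy = 30, overdose_weight = 1,
                             underdose_weight = 10, hotspot_weight = 1,
                             hotspot_gy = 1.07 * rx_gy, lower = 0.05,
                             upper = 100, subsample = 1L) {
  if (overdose_weight < 0 || underdose_weight < 0 || hotspot_weight < 0) {
    stop("penalty weights must be non-negative", call. = FALSE)
  }
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds", call. = FALSE)
  structure(list(rx_gy = rx_gy, alpha = overdose_weight, beta = underdose_weight,
                 gamma = hotspot_weight, hotspot_gy = hotspot_gy,
                 lower = lower, upper = upper, subsample = as.integer(subsample)),
            class = "fif_objective")
}

# voxels-by-fields matrix of unit-weight doses inside a mask
dose_matrix <- function(field_doses, mask, subsample = 1L) {
  idx <- which(mask$mask)
  if (subsample > 1L) idx <- idx[seq(1L, length(idx), by = subsample)]
  vapply(field_doses, function(fd) fd$values[idx], numeric(length(idx)))
}

#' Objective cost for a weight vector
#'
#' @param weights numeric weights, one per column of `dose_mat`.
#' @param dose_mat voxels-by-fields matrix of unit-weight doses over the
#'   target.
#' @param objective an `fif_objective`.
#' @param body_mat optional voxels-by-fields matrix over the body, activating
#'   the hotspot term.
#' @return Non-negative scalar; 0 iff the weighted dose is exactly Rx on
#'   every target voxel and below the hotspot level on the body.
#' @export
fif_cost <- function(weights, dose_mat, objective, body_mat = NULL) {
  d <- as.numeric(dose_mat %*% weights) - objective$rx_gy
  c0 <- objective$alpha * sum(pmax(d, 0)^2) + objective$beta * sum(pmax(-d, 0)^2)
  if (!is.null(body_mat) && objective$gamma > 0) {
    h <- as.numeric(body_mat %*% weights) - objective$hotspot_gy
    c0 <- c0 + objective$gamma * sum(pmax(h, 0)^2)
  }
  c0
}

fif_cost_gradient <- function(weights, dose_mat, objective, body_mat = NULL) {
  d <- as.numeric(dose_mat %*% weights) - objective$rx_gy
  g <- 2 * (objective$alpha * pmax(d, 0) - objective$beta * pmax(-d, 0))
  out <- as.numeric(crossprod(dose_mat, g))
  if (!is.null(body_mat) && objective$gamma > 0) {
    h <- as.numeric(body_mat %*% weights) - objective$hotspot_gy
    out <- out + as.numeric(crossprod(body_mat, 2 * objective$gamma * pmax(h, 0)))
  }
  out
}

#' Optimize beam weights (bounded quasi-Newton)
#'
#' Minimizes the homogeneity cost over the weight box with the L-BFGS-B
#' solver, starting from the current weights and using the analytic gradient.
#' The result never worsens the plan: if the solver fails, or returns a
#' higher cost than the start, the starting weights are kept and a warning is
#' logged.
#'
#' @param field_doses list of unit-weight dose `fif_grid`s.
#' @param target `fif_mask` of the optimization target (the brain).
#' @param objective an `fif_objective`.
#' @param start starting weights (required; the optimizer refines the current
#'   plan rather than replanning).
#' @param body optional `fif_mask` over which the hotspot term is evaluated
#'   (body voxels outside the target).
#' @param control passed to [stats::optim()] (defaults: `factr = 1e7`,
#'   `maxit = 200`).
#' @return List with `weights`, `cost`, `start_cost`, `converged`, `message`.
#' @export
optimize_weights <- function(field_doses, target, objective, start,
                             body = NULL, control = list(factr = 1e7, maxit = 200)) {
  stopifnot(length(field_doses) >= 1L, length(start) == length(field_doses))
  D <- dose_matrix(field_doses, target, objective$subsample)
  B <- NULL
  if (!is.null(body) && objective$gamma > 0) {
    outside <- structure_mask(body$name, body$mask & !target$mask,
                              body$spacing, body$origin)
    B <- dose_matrix(field_doses, outside, objective$subsample)
  }
  lo <- rep_len(objective$lower, length(start))
  hi <- rep_len(objective$upper, length(start))
  start <- pmin(pmax(start, lo), hi)
  c0 <- fif_cost(start, D, objective, B)
  fit <- tryCatch(
    stats::optim(start, fn = fif_cost, gr = fif_cost_gradient,
                 dose_mat = D, objective = objective, body_mat = B,
                 method = "L-BFGS-B", lower = lo, upper = hi,
                 control = control),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$value) || fit$value > c0) {
    warning("weight optimization did not improve the plan; keeping starting weights",
            call. = FALSE)
    return(list(weights = start, cost = c0, start_cost = c0,
                converged = FALSE, message = "fallback to start"))
  }
  list(weights = fit$par, cost = fit$value, start_cost = c0,
       converged = fit$convergence == 0, message = fit$message)
}

# dose received by at least `coverage` of the masked voxels (exact order
# statistic, no binning): the largest d with frac(dose >= d) >= coverage
coverage_dose <- function(dose_values, coverage) {
  n <- length(dose_values)
  k <- min(n, max(1L, ceiling(coverage * n)))
  sort(dose_values, decreasing = TRUE)[k]
}

#' Normalize a plan to prescription coverage
#'
#' Rescales all field weights by one global scalar so that the stated volume
#' fraction of the target receives the stated dose level (clinical default:
#' 99.9% of the brain volume receives 100% of the prescription). The scalar is
#' the exact ratio of the target dose to the coverage quantile of the voxel
#' doses, not an iterative search. Monitor units rescale with the weights.
#'
#' When a minimum weight (the MU floor) is supplied and the global rescale
#' would push a field below it, the violating fields are pinned at the floor
#' and the remaining free weights are re-solved for the same coverage (a
#' projected normalization), so both the coverage target and the MU floor
#' hold after normalization.
#'
#' @param weights current field weights.
#' @param field_doses list of unit-weight dose grids.
#' @param target `fif_mask` (the brain).
#' @param coverage volume fraction (default 0.999).
#' @param dose_level_gy dose to be received by that fraction (default the
#'   30 Gy prescription).
#' @param min_weight optional weight floor applied after rescaling.
#' @return List with `weights`, `scale` (the applied global scalar) and
#'   `coverage_dose_gy` (achieved quantile, equals `dose_level_gy`).
#' @export
normalize_weights <- function(weights, field_doses, target, coverage = 0.999,
                              dose_level_gy = 30, min_weight = NULL) {
  if (coverage <= 0 || coverage > 1) {
    stop("coverage fraction must lie in (0, 1]", call. = FALSE)
  }
  D <- dose_matrix(field_doses, target)
  base <- as.numeric(D %*% weights)
  d_cov <- coverage_dose(base, coverage)
  if (!is.finite(d_cov) || d_cov <= 0) {
    stop("normalization error: target receives no dose", call. = FALSE)
  }
  s <- dose_level_gy / d_cov
  w <- s * weights
  if (!is.null(min_weight) && any(w < min_weight - 1e-12)) {
    fixed <- w < min_weight
    w[fixed] <- min_weight
    # rescale only the free weights to restore the coverage quantile
    d_fixed <- as.numeric(D[, fixed, drop = FALSE] %*% w[fixed])
    d_free <- as.numeric(D[, !fixed, drop = FALSE] %*% w[!fixed])
    if (any(!fixed) && any(d_free > 0)) {
      f <- function(t) coverage_dose(d_fixed + t * d_free, coverage) - dose_level_gy
      t_star <- tryCatch(stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root,
                         error = function(e) 1)
      w[!fixed] <- t_star * w[!fixed]
    }
  }
  list(weights = w, scale = s,
       coverage_dose_gy = coverage_dose(as.numeric(D %*% w), coverage))
}

#' Monitor units from weights
#'
#' Linear monitor-unit stand-in: `MU_i = weight_i * mu_ref`, the reference
#' default being 100 MU per unit weight. The optimizer's weight lower bound is
#' the configured minimum MU divided by `mu_ref`, so every delivered field
#' carries at least the floor (clinical default 5 MU).
#'
#' @param weights field weights.
#' @param mu_ref MU per unit weight (default 100).
#' @return Numeric MU per field.
#' @export
assign_mu <- function(weights, mu_ref = 100) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  weights * mu_ref
}
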