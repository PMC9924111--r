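#' Field-in-field configuration
#'
#' Clinical defaults of the forward-planned FIF loop: hotspots are any
#' disconnected volume larger than 1 cm^3 receiving 107% of the prescription
#' (30 Gy in 10 fractions); at most six subfields are added (two per
#' iteration, opposed and in parallel, so plans always carry an even number
#' of fields); the per-iteration block threshold steps down from the current
#' maximum hotspot percentage by a fixed 3-percentage-point decrement of the
#' prescription, never below the 107% target; every field delivers at least
#' 5 MU; plans are normalized so 99.9% of the brain volume receives 100% of
#' the prescription. All settings are configurable.
#'
#' @param rx_gy total prescription dose in Gy (default 30).
#' @param n_fractions number of fractions (default 10).
#' @param hotspot_fraction hotspot dose level as a fraction of Rx
#'   (default 1.07).
#' @param min_hotspot_volume_cm3 minimum qualifying hotspot component volume
#'   (default 1).
#' @param decrement_pct block-threshold decrement in percentage points of Rx
#'   (default 3).
#' @param max_subfields maximum number of subfields added (default 6; pairs
#'   are added two at a time so an even cap is natural).
#' @param max_iterations cap on FIF iterations (default `max_subfields / 2`).
#' @param min_mu minimum monitor units per delivered field (default 5).
#' @param mu_ref monitor units per unit weight (default 100).
#' @param coverage target coverage fraction for normalization (default 0.999).
#' @param dose_level normalization dose level as a fraction of Rx
#'   (default 1.0).
#' @param connectivity hotspot component connectivity, 26 or 6 (default 26).
#' @param block_per_component if `TRUE`, block only the largest qualifying
#'   component instead of the union of all supra-threshold body voxels
#'   (default `FALSE`: union).
#' @param overdose_weight,underdose_weight homogeneity penalty weights.
#' @param hotspot_weight penalty weight of the body hotspot objective term
#'   (see [weight_objective()]).
#' @return An object of class `fif_config`.
#' @export
fif_config <- function(rx_gy = 30, n_fractions = 10, hotspot_fraction = 1.07,
                       min_hotspot_volume_cm3 = 1, decrement_pct = 3,
                       max_subfields = 6, max_iterations = NULL, min_mu = 5,
                       mu_ref = 100, coverage = 0.999, dose_level = 1.0,
                       connectivity = 26, block_per_component = FALSE,
                       overdose_weight = 1, underdose_weight = 10,
                       hotspot_weight = 1) {
  if (rx_gy <= 0) stop("validation error: `rx_gy` must be positive", call. = FALSE)
  if (n_fractions < 1) stop("validation error: `n_fractions` must be >= 1", call. = FALSE)
  if (hotspot_fraction <= 1) stop("validation error: `hotspot_fraction` must exceed 1", call. = FALSE)
  if (min_hotspot_volume_cm3 < 0) stop("validation error: `min_hotspot_volume_cm3` must be >= 0", call. = FALSE)
  if (decrement_pct <= 0) stop("validation error: `decrement_pct` must be positive", call. = FALSE)
  if (max_subfields < 0) stop("validation error: `max_subfields` must be >= 0", call. = FALSE)
  if (min_mu < 0) stop("validation error: `min_mu` must be >= 0", call. = FALSE)
  if (mu_ref <= 0) stop("validation error: `mu_ref` must be positive", call. = FALSE)
  if (coverage <= 0 || coverage > 1) stop("validation error: `coverage` must lie in (0, 1]", call. = FALSE)
  if (dose_level <= 0) stop("validation error: `dose_level` must be positive", call. = FALSE)
  if (!connectivity %in% c(6, 26)) stop("validation error: `connectivity` must be 6 or 26", call. = FALSE)
  if (is.null(max_iterations)) max_iterations <- max_subfields %/% 2
  structure(
    list(rx_gy = rx_gy, n_fractions = n_fractions,
         hotspot_fraction = hotspot_fraction,
         min_hotspot_volume_cm3 = min_hotspot_volume_cm3,
         decrement_pct = decrement_pct, max_subfields = max_subfields,
         max_iterations = max_iterations, min_mu = min_mu, mu_ref = mu_ref,
         coverage = coverage, dose_level = dose_level,
         connectivity = connectivity, block_per_component = block_per_component,
         overdose_weight = overdose_weight, underdose_weight = underdose_weight,
         hotspot_weight = hotspot_weight),
    class = "fif_config"
  )
}

#' Select the per-iteration block threshold
#'
#' At the start of an iteration the maximum hotspot percentage is measured on
#' the normalized plan. If it is already at or below the target level the
#' loop stops; otherwise the iso-dose level to block is the maximum hotspot
#' percentage minus the fixed decrement, floored at the target level (a plan
#' with a 116% maximum hotspot and a 3-point decrement blocks the 113%
#' iso-dose volume; one at 108.5% blocks 107%).
#'
#' @param max_hotspot_pct current maximum hotspot, % of Rx.
#' @param decrement_pct decrement in percentage points of Rx (default 3).
#' @param target_pct target hotspot level, % of Rx (default 107).
#' @return List with `stop` (logical) and `threshold_pct` (`NA` when
#'   stopping).
#' @examples
#' select_block_threshold(116) # blocks 113%
#' select_block_threshold(107) # stop: target reached
#' @export
select_block_threshold <- function(max_hotspot_pct, decrement_pct = 3,
                                   target_pct = 107) {
  if (is.na(max_hotspot_pct) || max_hotspot_pct <= target_pct) {
    return(list(stop = TRUE, threshold_pct = NA_real_))
  }
  list(stop = FALSE,
       threshold_pct = max(max_hotspot_pct - decrement_pct, target_pct))
}

# ---- plan object -----------------------------------------------------------

new_plan <- function(fields, field_doses, rx_gy, n_fractions, mu_ref) {
  structure(
    list(fields = fields, field_doses = field_doses, rx_gy = rx_gy,
         n_fractions = n_fractions, mu_ref = mu_ref),
    class = "fif_plan"
  )
}

plan_weights <- function(plan) vapply(plan$fields, `[[`, numeric(1), "weight")

plan_set_weights <- function(plan, w) {
  for (i in seq_along(plan$fields)) {
    plan$fields[[i]]$weight <- w[i]
    plan$fields[[i]]$mu <- w[i] * plan$mu_ref
  }
  plan
}

#' Plan dose of an `fif_plan`
#' @param plan an `fif_plan`.
#' @return An `fif_grid`.
#' @export
plan_dose <- function(plan) compute_plan_dose(plan$field_doses, plan_weights(plan))

#' @export
print.fif_plan <- function(x, ...) {
  w <- plan_weights(x)
  cat(sprintf("<fif_plan> %d fields (%d subfields), Rx %g Gy / %d fx\n",
              length(x$fields), max(0L, length(x$fields) - 2L),
              x$rx_gy, x$n_fractions))
  cat(sprintf("  weights: %s\n", paste(sprintf("%.3f", w), collapse = ", ")))
  cat(sprintf("  MU:      %s\n", paste(sprintf("%.1f", w * x$mu_ref), collapse = ", ")))
  invisible(x)
}

#' Build the initial opposed-lateral plan
#'
#' Constructs the two-field parallel-opposed lateral plan: projects the brain
#' and blocked structures into each beam's BEV, builds the whole-brain
#' aperture for the first beam, mirrors it for the opposed beam, raycasts the
#' two beam transports, and initializes equal beam weights normalized to the
#' configured coverage.
#'
#' @param phantom list with `grid` and `masks` as returned by
#'   [make_head_phantom()] (or assembled from files).
#' @param config an `fif_config`.
#' @param geoms list of two opposed `fif_beam`s (default lateral 90/270 at
#'   SAD 1000).
#' @param params an `fif_engine_params`.
#' @param bev an `fif_bev` raster.
#' @param margin_mm aperture flash margin (default 7).
#' @param leaf_width MLC leaf width in mm (default 5).
#' @return List with `plan` (`fif_plan`), `transports`, `main_aperture`,
#'   `bev`, `params`, `config`.
#' @export
make_initial_plan <- function(phantom, config = fif_config(),
                              geoms = opposed_pair(), params = engine_params(),
                              bev = bev_grid(), margin_mm = 7, leaf_width = 5) {
  masks <- phantom$masks
  if (is.null(masks$brain) || !any(masks$brain$mask)) {
    stop("invalid plan: the brain mask is empty", call. = FALSE)
  }
  brain_bev <- project_to_bev(masks$brain, geoms[[1]], bev)
  blocked <- list()
  for (s in c("eye_L", "eye_R", "lens_L", "lens_R")) {
    if (!is.null(masks[[s]])) {
      blocked[[s]] <- project_to_bev(masks[[s]], geoms[[1]], bev)
    }
  }
  ap1 <- make_whole_brain_aperture(brain_bev, blocked, margin_mm, bev, leaf_width)
  ap2 <- mirror_aperture(ap1)
  transports <- list(
    make_beam_transport(phantom$grid, geoms[[1]], params, masks$body),
    make_beam_transport(phantom$grid, geoms[[2]], params, masks$body)
  )
  fd <- list(compute_field_dose(transports[[1]], ap1, params),
             compute_field_dose(transports[[2]], ap2, params))
  fields <- list(
    list(id = "main_1", beam = 1L, geometry = geoms[[1]], aperture = ap1,
         weight = 0.5, mu = 0.5 * config$mu_ref, role = "main"),
    list(id = "main_2", beam = 2L, geometry = geoms[[2]], aperture = ap2,
         weight = 0.5, mu = 0.5 * config$mu_ref, role = "main")
  )
  plan <- new_plan(fields, fd, config$rx_gy, config$n_fractions, config$mu_ref)
  nw <- normalize_weights(plan_weights(plan), fd, masks$brain,
                          coverage = config$coverage,
                          dose_level_gy = config$dose_level * config$rx_gy,
                          min_weight = config$min_mu / config$mu_ref)
  plan <- plan_set_weights(plan, nw$weights)
  list(plan = plan, transports = transports, main_aperture = ap1,
       bev = bev, params = params, config = config,
       geoms = geoms, leaf_width = leaf_width)
}

# ---- subfield construction -------------------------------------------------

# subtract a block BEV map from an aperture under the one-interval-per-row
# MLC constraint: per open leaf row, remove the block's u extent from the
# open interval and keep the larger remaining segment (tie -> left); rows
# fully covered close. Returns NULL when the block projection misses the
# aperture entirely (no-op).
subtract_block_from_aperture <- function(aperture, block_bev) {
  bev <- aperture$bev
  mlc <- aperture$mlc
  half <- bev$spacing / 2
  leaf_id <- floor(bev$v / aperture$leaf_width)
  any_change <- FALSE
  for (i in seq_len(nrow(mlc))) {
    if (!mlc$open[i]) next
    cols <- which(leaf_id == mlc$leaf[i])
    sub <- block_bev[, cols, drop = FALSE]
    if (!any(sub)) next
    uu <- bev$u[which(rowSums(sub) > 0)]
    b_min <- min(uu) - half
    b_max <- max(uu) + half
    if (b_max <= mlc$u_min[i] || b_min >= mlc$u_max[i]) next # misses this row
    any_change <- TRUE
    left <- c(mlc$u_min[i], min(b_min, mlc$u_max[i]))
    right <- c(max(b_max, mlc$u_min[i]), mlc$u_max[i])
    len_l <- max(0, left[2] - left[1])
    len_r <- max(0, right[2] - right[1])
    if (len_l <= 0 && len_r <= 0) {
      mlc$open[i] <- FALSE
      mlc$u_min[i] <- 0
      mlc$u_max[i] <- 0
    } else if (len_l >= len_r) {
      mlc$u_min[i] <- left[1]
      mlc$u_max[i] <- left[2]
    } else {
      mlc$u_min[i] <- right[1]
      mlc$u_max[i] <- right[2]
    }
  }
  if (!any_change) return(NULL)
  new_aperture(mlc, bev, aperture$leaf_width)
}

#' Create one opposed subfield pair blocking a hotspot region
#'
#' The block region is the set of body voxels at or above the block
#' threshold (by default the union over all such voxels; optionally only the
#' largest qualifying component). It is projected into the first beam's BEV;
#' the subfield aperture is the main aperture minus that projection under the
#' MLC leaf constraint, and the opposed subfield is its mirror so both open
#' onto the same anatomy.
#'
#' @param state a planning state as returned by [make_initial_plan()].
#' @param dose current plan dose `fif_grid`.
#' @param block_threshold_gy absolute block threshold in Gy.
#' @param body `fif_mask`.
#' @return List with `apertures` (length 2), `noop` (TRUE when the block
#'   projection does not intersect the aperture), `degenerate` (TRUE when the
#'   subtraction closes the whole aperture).
#' @export
make_subfield_pair <- function(state, dose, block_threshold_gy, body) {
  config <- state$config
  block <- body$mask & (dose$values >= block_threshold_gy)
  if (config$block_per_component && any(block)) {
    hs <- find_hotspots(dose, body, block_threshold_gy,
                        config$min_hotspot_volume_cm3, config$connectivity,
                        config$rx_gy)
    if (nrow(hs$components)) {
      biggest <- hs$components$component[which.max(hs$components$volume_cm3)]
      block <- hs$labels == biggest
    }
  }
  if (!any(block)) {
    return(list(apertures = NULL, noop = TRUE, degenerate = FALSE))
  }
  bm <- structure_mask("block", block, body$spacing, body$origin)
  block_bev <- project_to_bev(bm, state$geoms[[1]], state$bev)
  sub1 <- subtract_block_from_aperture(state$main_aperture, block_bev)
  if (is.null(sub1)) {
    return(list(apertures = NULL, noop = TRUE, degenerate = FALSE))
  }
  if (!any(sub1$open)) {
    return(list(apertures = NULL, noop = FALSE, degenerate = TRUE))
  }
  list(apertures = list(sub1, mirror_aperture(sub1)), noop = FALSE,
       degenerate = FALSE)
}

# ---- the FIF loop ----------------------------------------------------------

measure_state <- function(plan, masks, config) {
  dose <- plan_dose(plan)
  thr <- config$hotspot_fraction * config$rx_gy
  hs <- find_hotspots(dose, masks$body, thr, config$min_hotspot_volume_cm3,
                      config$connectivity, config$rx_gy)
  list(dose = dose, hotspots = hs,
       v_hot_cm3 = hs$supra_volume_cm3,
       max_pct = hs$max_pct,
       max_body_pct = 100 * max(dose$values[masks$body$mask]) / config$rx_gy)
}

normalize_plan_state <- function(plan, masks, config) {
  nw <- normalize_weights(plan_weights(plan), plan$field_doses, masks$brain,
                          coverage = config$coverage,
                          dose_level_gy = config$dose_level * config$rx_gy,
                          min_weight = config$min_mu / config$mu_ref)
  plan_set_weights(plan, nw$weights)
}

#' Run the iterative field-in-field loop
#'
#' Starting from the normalized equal-weight opposed pair, each iteration
#' (1) normalizes the plan, (2) measures the maximum hotspot percentage,
#' (3) selects the block threshold (maximum hotspot minus the decrement,
#' floored at the target) or stops if the target level is reached, (4) adds
#' an opposed subfield pair whose apertures block the supra-threshold region,
#' (5) computes the subfield doses from the cached beam transports,
#' (6) re-optimizes all beam weights, (7) renormalizes, and (8) accepts the
#' iteration only if the hotspot volume (total supra-threshold body volume at
#' the hotspot level) did not increase — otherwise the pair is reverted and
#' the loop stops. The loop also stops when the configured maximum number of
#' subfields has been added. Deterministic given its inputs.
#'
#' @param state planning state from [make_initial_plan()].
#' @param masks named mask list (needs `brain` and `body`).
#' @return An object of class `fif_result`: list with `plan` (final
#'   `fif_plan`), `log` (tibble of per-iteration records), `stop_reason`
#'   (`"target_reached"`, `"max_subfields"`, `"hotspot_increased"` or
#'   `"no_op"`), `initial` and `final` measurement summaries, and `config`.
#' @export
run_fif <- function(state, masks) {
  config <- state$config
  plan <- normalize_plan_state(state$plan, masks, config)
  m0 <- measure_state(plan, masks, config)
  initial <- m0
  target_pct <- 100 * config$hotspot_fraction
  log_rows <- list()
  stop_reason <- NULL
  iter <- 0L

  repeat {
    n_sub <- length(plan$fields) - 2L
    if (is.na(m0$max_pct) || m0$max_pct <= target_pct) {
      stop_reason <- "target_reached"
      break
    }
    if (n_sub >= config$max_subfields || iter >= config$max_iterations) {
      stop_reason <- "max_subfields"
      break
    }
    iter <- iter + 1L
    sel <- select_block_threshold(m0$max_pct, config$decrement_pct, target_pct)
    thr_gy <- sel$threshold_pct / 100 * config$rx_gy
    pair <- make_subfield_pair(state, m0$dose, thr_gy, masks$body)
    if (pair$noop) {
      stop_reason <- "no_op"
      break
    }
    if (pair$degenerate) {
      stop_reason <- "hotspot_increased" # unrealizable block: iteration rejected
      break
    }
    saved_plan <- plan
    k <- n_sub / 2 + 1
    fd_new <- list(
      compute_field_dose(state$transports[[1]], pair$apertures[[1]], state$params),
      compute_field_dose(state$transports[[2]], pair$apertures[[2]], state$params)
    )
    w_floor <- config$min_mu / config$mu_ref
    plan$fields <- c(plan$fields, list(
      list(id = sprintf("sub_%d_1", k), beam = 1L, geometry = state$geoms[[1]],
           aperture = pair$apertures[[1]], weight = w_floor,
           mu = config$min_mu, role = "subfield"),
      list(id = sprintf("sub_%d_2", k), beam = 2L, geometry = state$geoms[[2]],
           aperture = pair$apertures[[2]], weight = w_floor,
           mu = config$min_mu, role = "subfield")
    ))
    plan$field_doses <- c(plan$field_doses, fd_new)

    obj <- weight_objective(
      rx_gy = config$dose_level * config$rx_gy,
      overdose_weight = config$overdose_weight,
      underdose_weight = config$underdose_weight,
      hotspot_weight = config$hotspot_weight,
      hotspot_gy = config$hotspot_fraction * config$rx_gy,
      lower = w_floor, upper = 1e3
    )
    opt <- optimize_weights(plan$field_doses, masks$brain, obj,
                            start = plan_weights(plan), body = masks$body)
    plan <- plan_set_weights(plan, opt$weights)
    plan <- normalize_plan_state(plan, masks, config)
    m1 <- measure_state(plan, masks, config)

    accepted <- m1$v_hot_cm3 <= m0$v_hot_cm3 + 1e-9
    log_rows[[iter]] <- tibble::tibble(
      iteration = iter,
      n_fields = length(plan$fields),
      max_hotspot_pct_pre = m0$max_pct,
      max_body_pct_pre = m0$max_body_pct,
      block_threshold_pct = sel$threshold_pct,
      v_hotspot_cm3_before = m0$v_hot_cm3,
      v_hotspot_cm3_after = m1$v_hot_cm3,
      max_hotspot_pct_post = m1$max_pct,
      max_body_pct_post = m1$max_body_pct,
      cost_start = opt$start_cost,
      cost_end = opt$cost,
      accepted = accepted,
      stop_reason = NA_character_
    )
    if (!accepted) {
      plan <- saved_plan
      stop_reason <- "hotspot_increased"
      break
    }
    m0 <- m1
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else tibble::tibble(
    iteration = integer(), n_fields = integer(),
    max_hotspot_pct_pre = numeric(), max_body_pct_pre = numeric(),
    block_threshold_pct = numeric(), v_hotspot_cm3_before = numeric(),
    v_hotspot_cm3_after = numeric(), max_hotspot_pct_post = numeric(),
    max_body_pct_post = numeric(), cost_start = numeric(),
    cost_end = numeric(), accepted = logical(), stop_reason = character()
  )
  if (nrow(log)) log$stop_reason[nrow(log)] <- stop_reason
  final <- measure_state(plan, masks, config)
  structure(
    list(plan = plan, log = log, stop_reason = stop_reason,
         initial = initial[c("v_hot_cm3", "max_pct", "max_body_pct")],
         final = final[c("v_hot_cm3", "max_pct", "max_body_pct")],
         initial_dose = initial$dose, final_dose = final$dose,
         config = config),
    class = "fif_result"
  )
}

#' @export
print.fif_result <- function(x, ...) {
  cat(sprintf(
    "<fif_result> %d fields, stop: %s\n  max body dose %% of Rx: %.1f -> %.1f\n  V%g%%: %.1f -> %.1f cm^3\n",
    length(x$plan$fields), x$stop_reason,
    x$initial$max_body_pct, x$final$max_body_pct,
    100 * x$config$hotspot_fraction,
    x$initial$v_hot_cm3, x$final$v_hot_cm3
  ))
  invisible(x)
}

#' Tidy the per-iteration FIF log
#' @param x an `fif_result`.
#' @param ... unused.
#' @return The iteration-record tibble.
#' @export
tidy.fif_result <- function(x, ...) x$log

#' One-row summary of a FIF run
#' @param x an `fif_result`.
#' @param ... unused.
#' @export
glance.fif_result <- function(x, ...) {
  tibble::tibble(
    n_fields = length(x$plan$fields),
    n_subfields = length(x$plan$fields) - 2L,
    n_iterations = nrow(x$log),
    stop_reason = x$stop_reason,
    v_hotspot_cm3_initial = x$initial$v_hot_cm3,
    v_hotspot_cm3_final = x$final$v_hot_cm3,
    max_body_pct_initial = x$initial$max_body_pct,
    max_body_pct_final = x$final$max_body_pct
  )
}
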