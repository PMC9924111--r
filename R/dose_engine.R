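#' Dose engine parameters
#'
#' Parameters of the raycast megavoltage dose model. The model is an explicit
#' analytic stand-in for a clinical dose calculation: per voxel,
#' `dose = output * T(u, v) * (SAD / r)^2 * B(d)` where `T` is the aperture
#' transmission at the voxel's BEV projection (0/1, optionally Gaussian
#' blurred for a soft penumbra), `r` the distance to the source, and `B` a
#' depth-dose factor of the water-equivalent radiological depth `d` (line
#' integral of density along the ray): a saturating build-up
#' `(1 - exp(-k d / d_max)) / (1 - exp(-k))` up to the build-up depth
#' (matching the fast initial rise of a megavoltage depth-dose curve), then
#' exponential attenuation `exp(-mu * (d - d_max))`. Defaults are 6 MV-like
#' water values.
#'
#' @param mu effective linear attenuation coefficient in 1/cm beyond the
#'   build-up depth (default 0.028, the broad-field tissue-maximum-ratio
#'   slope of a 6 MV beam once the separately applied inverse-square factor
#'   is taken out; the narrow-beam primary coefficient ~0.046 is too steep
#'   here because the engine carries no explicit scatter model).
#' @param d_max build-up depth in cm (default 1.5).
#' @param inverse_square apply the inverse-square source falloff (default TRUE).
#' @param penumbra_sigma Gaussian blur sigma (mm) applied to the aperture
#'   transmission map; 0 (default) keeps a binary aperture so subset
#'   invariants are exact.
#' @param step_mm raycast integration step in mm (default 1).
#' @param buildup_rate dimensionless steepness `k` of the build-up rise
#'   (default 3: ~95% of the peak at two-thirds of the build-up depth, as for
#'   6 MV).
#' @param output dose (Gy) per unit beam weight at the build-up peak on the
#'   central axis; a pure scale absorbed by plan normalization (default 4).
#' @return An object of class `fif_engine_params`.
#' @export
engine_params <- function(mu = 0.028, d_max = 1.5, inverse_square = TRUE,
                          penumbra_sigma = 0, step_mm = 1, buildup_rate = 3,
                          output = 4) {
  if (mu <= 0) stop("parameter error: `mu` must be positive", call. = FALSE)
  if (d_max < 0) stop("parameter error: `d_max` must be non-negative", call. = FALSE)
  if (step_mm <= 0) stop("parameter error: `step_mm` must be positive", call. = FALSE)
  if (penumbra_sigma < 0) stop("parameter error: `penumbra_sigma` must be >= 0", call. = FALSE)
  if (buildup_rate <= 0) stop("parameter error: `buildup_rate` must be positive", call. = FALSE)
  structure(list(mu = mu, d_max = d_max, inverse_square = inverse_square,
                 penumbra_sigma = penumbra_sigma, step_mm = step_mm,
                 buildup_rate = buildup_rate, output = output),
            class = "fif_engine_params")
}

#' Precompute beam transport for one geometry
#'
#' Raycasts the radiological depth from the source to every computed voxel
#' and caches, per voxel, the depth, the inverse-square factor and the BEV
#' projection coordinates. Transport depends only on the density grid and the
#' beam geometry, never on the aperture, so all subfields of a beam share one
#' transport and weight optimization never re-raytraces.
#'
#' @param density density `fif_grid` (g/cm^3).
#' @param geom an `fif_beam`.
#' @param params an `fif_engine_params`.
#' @param within optional `fif_mask`; dose (and depth) are evaluated only for
#'   voxels inside it (typically the body), all others stay at zero dose.
#' @return An object of class `fif_transport`.
#' @export
make_beam_transport <- function(density, geom, params = engine_params(),
                                within = NULL) {
  stopifnot(inherits(density, "fif_grid"), inherits(geom, "fif_beam"))
  dims <- dim(density$values)
  compute <- if (is.null(within)) {
    array(TRUE, dims)
  } else {
    check_aligned(density, within, "density grid and mask")
    within$mask
  }
  depth <- array(
    .radiological_depth(as.vector(density$values), dims, density$spacing,
                        density$origin, geom$source, params$step_mm,
                        as.vector(compute)),
    dims
  )
  idx <- which(compute)
  ai <- arrayInd(idx, dims)
  pts <- sweep(sweep(ai - 1, 2, density$spacing, `*`), 2, density$origin, `+`)
  rel <- sweep(pts, 2, geom$source)
  r2 <- rowSums(rel^2)
  pr <- project_points(pts, geom)
  structure(
    list(geom = geom, dims = dims, spacing = density$spacing,
         origin = density$origin, idx = idx, depth_cm = depth[idx],
         isq = geom$sad^2 / r2, u = pr$u, v = pr$v),
    class = "fif_transport"
  )
}

# separable Gaussian blur of a matrix (reflective edges), sigma in pixels
gaussian_blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- ceiling(3 * sigma_px)
  w <- stats::dnorm(-k:k, sd = sigma_px)
  w <- w / sum(w)
  pad_filter <- function(x) { # along rows of a matrix
    n <- nrow(x)
    ix <- pmin(pmax(outer(seq_len(n), -k:k, `+`), 1), n)
    out <- x * 0
    for (j in seq_along(w)) out <- out + w[j] * x[ix[, j], , drop = FALSE]
    out
  }
  t(pad_filter(t(pad_filter(m))))
}

#' Compute one field's dose grid
#'
#' Evaluates the analytic dose model on a precomputed transport for a given
#' aperture; the result is the dose per unit beam weight.
#'
#' @param transport an `fif_transport` from [make_beam_transport()].
#' @param aperture an `fif_aperture` for the same beam.
#' @param params an `fif_engine_params`.
#' @return An `fif_grid` of dose per unit weight (Gy).
#' @export
compute_field_dose <- function(transport, aperture, params = engine_params()) {
  stopifnot(inherits(transport, "fif_transport"), inherits(aperture, "fif_aperture"))
  bev <- aperture$bev
  trans_map <- aperture$open * 1
  if (params$penumbra_sigma > 0) {
    trans_map <- gaussian_blur2d(trans_map, params$penumbra_sigma / bev$spacing)
  }
  iu <- pmin(pmax(round(transport$u / bev$spacing + (bev$n + 1) / 2), 1), bev$n)
  iv <- pmin(pmax(round(transport$v / bev$spacing + (bev$n + 1) / 2), 1), bev$n)
  tr <- trans_map[cbind(iu, iv)]
  d <- transport$depth_cm
  k <- params$buildup_rate
  B <- ifelse(d < params$d_max,
              (1 - exp(-k * d / params$d_max)) / (1 - exp(-k)),
              exp(-params$mu * (d - params$d_max)))
  dose_v <- params$output * tr * B
  if (params$inverse_square) dose_v <- dose_v * transport$isq
  vals <- array(0, transport$dims)
  vals[transport$idx] <- dose_v
  image_grid(vals, spacing = transport$spacing, origin = transport$origin)
}

#' Weighted plan dose
#'
#' Voxelwise weighted superposition of per-field unit-weight dose grids:
#' `D(w) = sum_i w_i * D_i`, exactly linear in the weights.
#'
#' @param field_doses list of aligned `fif_grid` dose grids (per unit weight).
#' @param weights numeric vector of non-negative field weights.
#' @return An `fif_grid` of plan dose (Gy).
#' @export
compute_plan_dose <- function(field_doses, weights) {
  if (length(field_doses) != length(weights)) {
    stop("one weight per field dose is required", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  ref <- field_doses[[1]]
  vals <- array(0, dim(ref$values))
  for (i in seq_along(field_doses)) {
    check_aligned(ref, field_doses[[i]], "field dose grids")
    vals <- vals + weights[i] * field_doses[[i]]$values
  }
  image_grid(vals, spacing = ref$spacing, origin = ref$origin)
}
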