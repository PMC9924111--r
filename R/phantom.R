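#' Synthetic head phantom specification
#'
#' Parameters of the reproducible head-like phantom used in place of patient
#' CT data: an ellipsoidal body of soft tissue wrapped in a higher-density
#' bone shell, a brain volume inside the shell, and small anterior eye/lens
#' structures. Under two opposed lateral 6 MV-like beams this geometry
#' produces the classic peripheral/skull hotspots that field-in-field
#' planning targets: lateral ray paths through the superior and peripheral
#' head are much shorter than through the midline, so once the plan is
#' normalized to brain coverage those regions ride above the prescription.
#'
#' Presets:
#' \describe{
#'   \item{`"default"`}{a realistically eccentric adult head; the initial
#'     opposed-lateral plan exhibits a substantial hotspot volume.}
#'   \item{`"mild"`}{a small head with a thin bone shell and generous
#'     clearance between the brain and the skull vertex, so lateral ray
#'     chords stay long everywhere the field is open; hotspots are modest
#'     and the field-in-field loop can reach the 107% target within the
#'     subfield budget.}
#'   \item{`"stress"`}{a wide head with a thick bone shell; a large hotspot
#'     volume persists past the subfield budget, exercising the
#'     maximum-subfield stopping rule.}
#' }
#'
#' @param body_semi_axes length-3, body ellipsoid semi-axes (x, y, z) in mm.
#' @param bone_thickness bone shell thickness in mm (must be smaller than the
#'   smallest body semi-axis).
#' @param brain_semi_axes length-3 semi-axes of the brain ellipsoid in mm, or
#'   `NULL` to derive them as
#'   `body_semi_axes - bone_thickness - brain_gap - abs(brain_center)`.
#' @param brain_gap gap in mm between the inner bone surface and the brain
#'   when `brain_semi_axes` is derived.
#' @param brain_center offset (mm) of the brain center from the head center;
#'   the slight posterior-superior default leaves anterior-inferior room for
#'   the orbits, as in a real head.
#' @param eye_radius,lens_radius sphere radii in mm.
#' @param eye_centers 2x3 matrix of eye centers (rows: left, right) in mm, or
#'   `NULL` for anterior-inferior placement scaled to the body.
#' @param densities named numeric: `air`, `soft`, `bone` in g/cm^3.
#' @param spacing voxel spacing in mm (length 3 or scalar).
#' @param padding_mm air margin around the body.
#' @param jitter_amp amplitude (mm) of the seeded sinusoidal surface jitter
#'   applied to the body/bone surface so that hotspot components are
#'   irregular; 0 disables it.
#' @param jitter_cycles integer number of angular cycles of the jitter.
#' @param seed integer seed for the jitter phases.
#' @param preset one of `"default"`, `"mild"`, `"stress"`; explicit arguments
#'   override preset values.
#' @return An object of class `fif_phantom_spec`.
#' @examples
#' spec <- phantom_spec(preset = "mild", spacing = 4)
#' @export
phantom_spec <- function(preset = c("default", "mild", "stress"),
                         body_semi_axes = NULL,
                         bone_thickness = NULL,
                         brain_semi_axes = NULL,
                         brain_gap = 4,
                         brain_center = c(0, 6, 14),
                         eye_radius = 12,
                         lens_radius = 4,
                         eye_centers = NULL,
                         densities = c(air = 0, soft = 1.0, bone = 1.6),
                         spacing = c(2, 2, 2),
                         padding_mm = 8,
                         jitter_amp = NULL,
                         jitter_cycles = 3L,
                         seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    default = list(body = c(80, 100, 85), bone = 6, brain = NULL, jitter = 2),
    mild    = list(body = c(66, 82, 110), bone = 3, brain = c(54, 64, 42), jitter = 0.5),
    stress  = list(body = c(84, 102, 82), bone = 8, brain = NULL, jitter = 2)
  )
  if (is.null(body_semi_axes)) body_semi_axes <- defaults$body
  if (is.null(bone_thickness)) bone_thickness <- defaults$bone
  if (is.null(brain_semi_axes)) brain_semi_axes <- defaults$brain
  if (is.null(jitter_amp)) jitter_amp <- defaults$jitter
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)

  body_semi_axes <- as.numeric(body_semi_axes)
  if (length(body_semi_axes) != 3L || any(body_semi_axes <= 0)) {
    stop("`body_semi_axes` must be three positive lengths (mm)", call. = FALSE)
  }
  if (bone_thickness <= 0 || bone_thickness >= min(body_semi_axes)) {
    stop("`bone_thickness` must be positive and smaller than the smallest body semi-axis",
         call. = FALSE)
  }
  if (any(densities < 0) || !all(c("air", "soft", "bone") %in% names(densities))) {
    stop("`densities` must be non-negative and name air, soft and bone", call. = FALSE)
  }
  brain_center <- as.numeric(brain_center)
  if (is.null(brain_semi_axes)) {
    brain_semi_axes <- body_semi_axes - bone_thickness - brain_gap - abs(brain_center)
  }
  brain_semi_axes <- as.numeric(brain_semi_axes)
  if (any(brain_semi_axes <= 0)) {
    stop("geometry error: brain does not fit inside the bone shell", call. = FALSE)
  }
  inner <- body_semi_axes - bone_thickness
  if (any(abs(brain_center) + brain_semi_axes > inner + 1e-9)) {
    stop("geometry error: brain extends past the inner bone surface", call. = FALSE)
  }
  if (is.null(eye_centers)) {
    eye_centers <- rbind(
      left  = c(+0.30, -0.70, -0.34) * body_semi_axes,
      right = c(-0.30, -0.70, -0.34) * body_semi_axes
    )
  }
  eye_centers <- matrix(as.numeric(eye_centers), nrow = 2)
  # the eye sphere must fit inside the body ellipsoid shrunk by its radius
  if (eye_radius >= min(body_semi_axes)) {
    stop("geometry error: eye sphere does not fit inside the body", call. = FALSE)
  }
  for (i in 1:2) {
    r2 <- sum((eye_centers[i, ] / (body_semi_axes - eye_radius))^2)
    if (r2 > 1) stop("geometry error: eye sphere does not fit inside the body", call. = FALSE)
  }
  structure(
    list(body_semi_axes = body_semi_axes, bone_thickness = bone_thickness,
         brain_semi_axes = brain_semi_axes, brain_gap = brain_gap,
         brain_center = brain_center,
         eye_radius = eye_radius, lens_radius = lens_radius,
         eye_centers = eye_centers, densities = densities,
         spacing = as.numeric(spacing), padding_mm = padding_mm,
         jitter_amp = jitter_amp, jitter_cycles = as.integer(jitter_cycles),
         seed = as.integer(seed), preset = preset),
    class = "fif_phantom_spec"
  )
}

# voxelwise inside-ellipsoid test with optional sinusoidal surface jitter;
# X, Y, Z are coordinate arrays (mm, centered on the ellipsoid center)
inside_ellipsoid <- function(X, Y, Z, semi, jitter = NULL) {
  r <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
  if (is.null(jitter) || jitter$amp == 0) return(r <= 1)
  theta <- atan2(Y, X)
  phi <- atan2(Z, sqrt(X^2 + Y^2))
  # relative radial perturbation, ~amp mm at the mean semi-axis scale
  pert <- jitter$amp / mean(semi) *
    sin(jitter$cycles * theta + jitter$phase[1]) *
    cos(jitter$cycles * phi + jitter$phase[2])
  r <= 1 + pert
}

#' Generate a synthetic head phantom
#'
#' Builds the density grid and the structure masks `body`, `bone`, `brain`,
#' `eye_L`, `eye_R`, `lens_L`, `lens_R` from a [phantom_spec()]. Generation is
#' pure: the same spec (including its seed) always yields identical output.
#' Mask containment holds by construction: brain, bone and eyes lie inside the
#' body, lenses inside the eyes, and the brain excludes the orbital spheres.
#'
#' @param spec an `fif_phantom_spec`.
#' @return A list with elements `grid` (density `fif_grid`, g/cm^3), `masks`
#'   (named list of `fif_mask`) and `spec`.
#' @examples
#' ph <- make_head_phantom(phantom_spec(preset = "mild", spacing = 6))
#' mask_volume_cm3(ph$masks$brain)
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "fif_phantom_spec"))
  sp <- spec$spacing
  half <- spec$body_semi_axes + spec$padding_mm
  dims <- pmax(2L, as.integer(ceiling(2 * half / sp)) + 1L)
  origin <- -(dims - 1) / 2 * sp # center the phantom at the world origin
  xs <- origin[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

  jitter <- NULL
  if (spec$jitter_amp > 0) {
    rng <- local({
      set.seed(spec$seed)
      stats::runif(2, 0, 2 * pi)
    })
    jitter <- list(amp = spec$jitter_amp, cycles = spec$jitter_cycles, phase = rng)
  }

  body <- inside_ellipsoid(X, Y, Z, spec$body_semi_axes, jitter)
  inner <- inside_ellipsoid(X, Y, Z, spec$body_semi_axes - spec$bone_thickness, jitter)
  inner <- inner & body
  bone <- body & !inner
  bc <- spec$brain_center
  brain_ell <- inside_ellipsoid(X - bc[1], Y - bc[2], Z - bc[3],
                                spec$brain_semi_axes)
  brain <- brain_ell & inner

  sphere <- function(center, radius) {
    (X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2 <= radius^2
  }
  eye_L <- sphere(spec$eye_centers[1, ], spec$eye_radius) & body
  eye_R <- sphere(spec$eye_centers[2, ], spec$eye_radius) & body
  # anterior pole of each eye holds the lens
  lens_off <- c(0, -(spec$eye_radius - spec$lens_radius), 0)
  lens_L <- sphere(spec$eye_centers[1, ] + lens_off, spec$lens_radius) & eye_L
  lens_R <- sphere(spec$eye_centers[2, ] + lens_off, spec$lens_radius) & eye_R
  brain <- brain & !eye_L & !eye_R

  dens <- spec$densities[["air"]] + array(0, dims)
  dens[body] <- spec$densities[["soft"]]
  dens[bone] <- spec$densities[["bone"]]

  grid <- image_grid(dens, spacing = sp, origin = origin)
  masks <- list(
    body = structure_mask("body", body, sp, origin),
    bone = structure_mask("bone", bone, sp, origin),
    brain = structure_mask("brain", brain, sp, origin),
    eye_L = structure_mask("eye_L", eye_L, sp, origin),
    eye_R = structure_mask("eye_R", eye_R, sp, origin),
    lens_L = structure_mask("lens_L", lens_L, sp, origin),
    lens_R = structure_mask("lens_R", lens_R, sp, origin)
  )
  list(grid = grid, masks = masks, spec = spec)
}
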