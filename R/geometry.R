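#' Beam geometry
#'
#' One external photon beam: gantry angle, isocenter, source-axis distance and
#' energy label. The gantry rotates in the axial (x-y) plane: 0 deg places the
#' source anterior, 90 deg at the patient's left (+x), 270 deg at the right.
#' Whole-brain plans here use the parallel-opposed lateral pair 90/270.
#'
#' The beam's-eye-view (BEV) frame is right-handed as seen from the source:
#' `v` runs along patient z (inferior to superior) and `u = v x axis`, so the
#' two members of an opposed pair see the same anatomy left-right mirrored.
#'
#' @param gantry_deg gantry angle in degrees.
#' @param isocenter world coordinates (mm) of the isocenter.
#' @param sad source-axis distance in mm (default 1000).
#' @param energy energy label, informational (default `"6 MV"`).
#' @return An object of class `fif_beam` with source position and BEV axes.
#' @examples
#' beam_geometry(90)
#' @export
beam_geometry <- function(gantry_deg, isocenter = c(0, 0, 0), sad = 1000,
                          energy = "6 MV") {
  if (sad <= 0) stop("SAD must be positive", call. = FALSE)
  th <- gantry_deg * pi / 180
  sdir <- c(sin(th), -cos(th), 0)          # unit vector isocenter -> source
  axis <- -sdir                            # beam travel direction
  v_hat <- c(0, 0, 1)
  u_hat <- c(v_hat[2] * axis[3] - v_hat[3] * axis[2],
             v_hat[3] * axis[1] - v_hat[1] * axis[3],
             v_hat[1] * axis[2] - v_hat[2] * axis[1])
  structure(
    list(gantry_deg = gantry_deg, isocenter = as.numeric(isocenter),
         sad = sad, energy = energy,
         source = as.numeric(isocenter) + sad * sdir,
         axis = axis, u_hat = u_hat, v_hat = v_hat),
    class = "fif_beam"
  )
}

#' Parallel-opposed lateral beam pair
#'
#' @inheritParams beam_geometry
#' @param gantries two gantry angles 180 degrees apart (default `c(90, 270)`).
#' @return List of two `fif_beam` objects sharing the isocenter.
#' @export
opposed_pair <- function(gantries = c(90, 270), isocenter = c(0, 0, 0),
                         sad = 1000, energy = "6 MV") {
  if (length(gantries) != 2L ||
      abs(((gantries[1] - gantries[2]) %% 360 + 360) %% 360 - 180) > 1e-6) {
    stop("opposed pair gantry angles must be 180 degrees apart", call. = FALSE)
  }
  lapply(gantries, beam_geometry, isocenter = isocenter, sad = sad, energy = energy)
}

#' BEV pixel raster at the isocenter plane
#'
#' A square pixel grid on the isocenter plane, symmetric about the beam axis
#' (the central axis maps to the center pixel), on which projections,
#' apertures and MLC shapes are represented.
#'
#' @param spacing pixel spacing in mm at the isocenter plane (default 2).
#' @param half_width half-extent in mm (default 150, i.e. a 30 cm field box).
#' @return An object of class `fif_bev` with pixel center coordinate vectors
#'   `u` and `v`.
#' @export
bev_grid <- function(spacing = 2, half_width = 150) {
  n <- 2L * as.integer(ceiling(half_width / spacing)) + 1L
  u <- (seq_len(n) - (n + 1) / 2) * spacing
  structure(list(u = u, v = u, spacing = spacing, n = n), class = "fif_bev")
}

# project world points (n x 3) through the source onto the isocenter plane;
# returns u, v (mm) by similar triangles: scale SAD / (distance along axis)
project_points <- function(pts, geom) {
  rel <- sweep(pts, 2, geom$source)
  t_axis <- rel %*% geom$axis
  if (any(t_axis <= 0)) {
    stop("geometry error: points at or behind the source cannot be projected",
         call. = FALSE)
  }
  rel_iso <- sweep(pts, 2, geom$isocenter)
  mag <- geom$sad / as.numeric(t_axis)
  list(u = as.numeric(rel_iso %*% geom$u_hat) * mag,
       v = as.numeric(rel_iso %*% geom$v_hat) * mag)
}

#' Project a structure mask into the beam's-eye-view
#'
#' Divergent projection of a 3D mask through the point source onto the
#' isocenter-plane raster: each mask voxel center is carried along its ray and
#' magnified by similar triangles (SAD over source distance); the BEV pixel
#' nearest to the projected point is set. An empty mask yields an empty map.
#'
#' @param mask an `fif_mask`.
#' @param geom an `fif_beam`.
#' @param bev an `fif_bev` raster.
#' @return Logical matrix indexed `[u, v]` over `bev$u` x `bev$v`.
#' @export
project_to_bev <- function(mask, geom, bev = bev_grid()) {
  stopifnot(inherits(mask, "fif_mask"), inherits(geom, "fif_beam"))
  out <- matrix(FALSE, length(bev$u), length(bev$v))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  # the source must lie outside the mask bounding box
  bb_lo <- apply(pts, 2, min) - mask$spacing / 2
  bb_hi <- apply(pts, 2, max) + mask$spacing / 2
  if (all(geom$source >= bb_lo & geom$source <= bb_hi)) {
    stop("geometry error: source lies inside the mask bounding box", call. = FALSE)
  }
  pr <- project_points(pts, geom)
  iu <- round(pr$u / bev$spacing + (bev$n + 1) / 2)
  iv <- round(pr$v / bev$spacing + (bev$n + 1) / 2)
  if (any(iu < 1 | iu > bev$n | iv < 1 | iv > bev$n)) {
    stop("BEV raster too small for this projection; increase `half_width`",
         call. = FALSE)
  }
  out[cbind(iu, iv)] <- TRUE
  out
}

# binary dilation of a BEV map by a disk of given radius (mm): shift-OR over
# all integer pixel offsets inside the disk
dilate_bev <- function(map, radius_mm, spacing) {
  if (radius_mm <= 0) return(map)
  r <- radius_mm / spacing
  k <- floor(r)
  out <- map
  nu <- nrow(map); nv <- ncol(map)
  for (du in -k:k) for (dv in -k:k) {
    if (du == 0 && dv == 0) next
    if (du * du + dv * dv > r * r) next
    su <- max(1, 1 - du):min(nu, nu - du)
    sv <- max(1, 1 - dv):min(nv, nv - dv)
    out[su + du, sv + dv] <- out[su + du, sv + dv] | map[su, sv]
  }
  out
}

#' Conform MLC leaves to a BEV region
#'
#' Realizes a BEV region with a multi-leaf collimator whose leaves travel
#' along the BEV u axis. Leaf rows partition the v axis into bands of
#' `leaf_width` mm (boundaries at integer multiples of the leaf width). Per
#' row, the open interval is the minimum-to-maximum u extent of the region
#' pixels in that band (over-cover rule); rows with no region pixels are
#' closed. An empty region closes every leaf pair.
#'
#' @param region logical matrix over `bev$u` x `bev$v`.
#' @param bev an `fif_bev`.
#' @param leaf_width leaf width in mm at the isocenter plane (default 5).
#' @return A tibble with one row per leaf pair: `leaf`, `v_min`, `v_max`,
#'   `u_min`, `u_max`, `open`. Closed pairs carry a zero-length interval.
#' @export
conform_mlc <- function(region, bev, leaf_width = 5) {
  leaf_id <- floor(bev$v / leaf_width)
  leaves <- sort(unique(leaf_id))
  half <- bev$spacing / 2
  rows <- lapply(leaves, function(lf) {
    cols <- which(leaf_id == lf)
    sub <- region[, cols, drop = FALSE]
    open <- any(sub)
    if (open) {
      uu <- bev$u[which(rowSums(sub) > 0)]
      u_min <- min(uu) - half
      u_max <- max(uu) + half
    } else {
      u_min <- 0; u_max <- 0
    }
    tibble::tibble(leaf = lf, v_min = lf * leaf_width, v_max = (lf + 1) * leaf_width,
                   u_min = u_min, u_max = u_max, open = open)
  })
  do.call(rbind, rows)
}

# rasterize an MLC table back onto the BEV pixel raster
rasterize_mlc <- function(mlc, bev) {
  out <- matrix(FALSE, length(bev$u), length(bev$v))
  for (i in seq_len(nrow(mlc))) {
    if (!mlc$open[i]) next
    cols <- which(bev$v >= mlc$v_min[i] & bev$v < mlc$v_max[i])
    rows <- which(bev$u >= mlc$u_min[i] & bev$u <= mlc$u_max[i])
    if (length(rows) && length(cols)) out[rows, cols] <- TRUE
  }
  out
}

new_aperture <- function(mlc, bev, leaf_width) {
  open <- rasterize_mlc(mlc, bev)
  jaw <- if (any(mlc$open)) {
    c(u_min = min(mlc$u_min[mlc$open]), u_max = max(mlc$u_max[mlc$open]),
      v_min = min(mlc$v_min[mlc$open]), v_max = max(mlc$v_max[mlc$open]))
  } else c(u_min = 0, u_max = 0, v_min = 0, v_max = 0)
  structure(
    list(open = open, mlc = mlc, jaw = jaw, bev = bev, leaf_width = leaf_width),
    class = "fif_aperture"
  )
}

#' @export
print.fif_aperture <- function(x, ...) {
  cat(sprintf("<fif_aperture> %d open leaf pairs, open area %.1f cm^2\n",
              sum(x$mlc$open), aperture_area_cm2(x)))
  invisible(x)
}

#' Open area of an aperture in cm^2
#' @param aperture an `fif_aperture`.
#' @export
aperture_area_cm2 <- function(aperture) {
  sum(aperture$open) * aperture$bev$spacing^2 / 100
}

#' Simplified whole-brain aperture
#'
#' Builds the main treatment aperture from BEV projections: the brain
#' projection is dilated by a flash margin, the union of blocked-structure
#' projections (eyes, lenses) is subtracted, and the result is conformed to
#' the MLC. Target coverage has priority over blocking: pixels of the brain
#' projection itself are never removed, only flash margin can be sacrificed
#' to a blocked structure. This is a deliberately simplified aperture
#' constructor standing in for clinical landmark-based field design.
#'
#' @param brain_bev logical BEV map of the brain.
#' @param blocked_bevs list of logical BEV maps to subtract (may be empty).
#' @param margin_mm dilation margin in mm (default 7).
#' @param bev an `fif_bev`.
#' @param leaf_width MLC leaf width in mm.
#' @return An `fif_aperture`.
#' @export
make_whole_brain_aperture <- function(brain_bev, blocked_bevs = list(),
                                      margin_mm = 7, bev = bev_grid(),
                                      leaf_width = 5) {
  region <- dilate_bev(brain_bev, margin_mm, bev$spacing)
  for (b in blocked_bevs) region <- region & !b
  if (!any(region & brain_bev)) {
    stop("degenerate aperture: blocking removed all open area", call. = FALSE)
  }
  region <- region | brain_bev
  # keep the largest connected open region so the aperture is one open field
  lab <- array(.cc_label3d(array(region, c(dim(region), 1L)),
                           c(dim(region), 1L), 26L), dim(region))
  if (max(lab) > 1L) {
    counts <- tabulate(lab[lab > 0])
    region <- lab == which.max(counts)
  }
  new_aperture(conform_mlc(region, bev, leaf_width), bev, leaf_width)
}

#' Mirror an aperture for the opposed beam
#'
#' The opposed member of a lateral pair sees the same anatomy left-right
#' mirrored in its BEV, so its aperture is the u-axis reflection of the
#' input. Mirroring twice returns the original aperture.
#'
#' @param aperture an `fif_aperture` defined for one beam of the pair.
#' @return The reflected `fif_aperture`.
#' @export
mirror_aperture <- function(aperture) {
  mlc <- aperture$mlc
  tmp <- mlc$u_min
  mlc$u_min <- ifelse(mlc$open, -mlc$u_max, 0)
  mlc$u_max <- ifelse(mlc$open, -tmp, 0)
  new_aperture(mlc, aperture$bev, aperture$leaf_width)
}

# is every open pixel of `a` also open in `b`?
aperture_subset_of <- function(a, b) !any(a$open & !b$open)
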