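#' Axis-aligned 3D image grid
#'
#' The universal voxel substrate of the planner: a 3D scalar field (density in
#' g/cm^3 or dose in Gy) with voxel spacing and world origin. Axes follow the
#' patient convention x = right to left, y = anterior to posterior,
#' z = inferior to superior. The world coordinate of voxel `(i, j, k)`
#' (1-based) is `origin + (c(i, j, k) - 1) * spacing`; world coordinates refer
#' to voxel centers.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `fif_grid`.
#' @examples
#' g <- image_grid(array(0, c(10, 10, 10)), spacing = c(2, 2, 2))
#' voxel_volume_cm3(g)
#' @export
image_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("grid values must be finite", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin),
    class = "fif_grid"
  )
}

#' @export
print.fif_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<fif_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  origin (%.1f, %.1f, %.1f) mm, value range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Named structure mask aligned to a grid
#'
#' A boolean voxel set (brain, body, bone, eye, lens, ...) co-registered with
#' an [image_grid()]: it carries the same shape, spacing and origin.
#'
#' @param name label string (e.g. `"brain"`).
#' @param mask 3D logical array.
#' @param spacing,origin grid metadata, as in [image_grid()]; usually taken
#'   from the reference grid.
#' @return An object of class `fif_mask`.
#' @export
structure_mask <- function(name, mask, spacing, origin = c(0, 0, 0)) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("`mask` must be a 3D logical array", call. = FALSE)
  }
  g <- image_grid(array(0, dim(mask)), spacing, origin) # reuse validation
  structure(
    list(name = as.character(name)[1], mask = mask,
         spacing = g$spacing, origin = g$origin),
    class = "fif_mask"
  )
}

#' @export
print.fif_mask <- function(x, ...) {
  cat(sprintf(
    "<fif_mask> '%s': %d voxels set (%.1f cm^3) on a %s grid\n",
    x$name, sum(x$mask), mask_volume_cm3(x),
    paste(dim(x$mask), collapse = " x ")
  ))
  invisible(x)
}

#' Voxel volume of a grid in cm^3
#' @param x an `fif_grid` or `fif_mask`.
#' @export
voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

#' Volume of a mask in cm^3 (voxel count times voxel volume)
#' @param mask an `fif_mask` or logical array (then `spacing` is required).
#' @param spacing voxel spacing in mm when `mask` is a bare array.
#' @export
mask_volume_cm3 <- function(mask, spacing = NULL) {
  if (inherits(mask, "fif_mask")) return(sum(mask$mask) * voxel_volume_cm3(mask))
  sum(mask) * prod(spacing) / 1000
}

# world coordinates of voxel centers along one axis (1, 2 or 3)
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(dim(grid$values)[axis]) - 1) * grid$spacing[axis]
}

# stop unless two grid-like objects share shape, spacing and origin
check_aligned <- function(a, b, what = "objects") {
  da <- if (!is.null(a$values)) dim(a$values) else dim(a$mask)
  db <- if (!is.null(b$values)) dim(b$values) else dim(b$mask)
  if (!identical(da, db) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop(sprintf("alignment error: %s do not share shape/spacing/origin", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

grid_affine <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read and write grids and masks as NIfTI
#'
#' Grids and masks persist as single-file NIfTI volumes; spacing and origin
#' are stored in the sform affine. `write_mask()` stores the mask as 0/1
#' integers; `read_mask()` restores it to logical and, when a reference grid
#' is supplied, fails with an alignment error on any shape/spacing/origin
#' mismatch.
#'
#' @param grid an `fif_grid`.
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @return `read_grid()` returns an `fif_grid`; writers return the path,
#'   invisibly.
#' @rdname grid_io
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fif_grid"))
  ni <- RNifti::asNifti(grid$values)
  ni <- RNifti::`sform<-`(ni, structure(grid_affine(grid$spacing, grid$origin), code = 2L))
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_grid <- function(path) {
  ni <- RNifti::readNifti(path)
  m <- RNifti::xform(ni)
  vals <- array(as.numeric(ni), dim = dim(ni))
  image_grid(vals, spacing = diag(m)[1:3], origin = m[1:3, 4])
}

#' @param mask an `fif_mask`.
#' @rdname grid_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "fif_mask"))
  ni <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)),
                        datatype = "uint8")
  ni <- RNifti::`sform<-`(ni, structure(grid_affine(mask$spacing, mask$origin), code = 2L))
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' @param name structure label to attach; defaults to the file stem.
#' @param reference optional `fif_grid` the mask must align with.
#' @rdname grid_io
#' @export
read_mask <- function(path, name = NULL, reference = NULL) {
  ni <- RNifti::readNifti(path)
  m <- RNifti::xform(ni)
  if (is.null(name)) name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  msk <- structure_mask(name, array(as.numeric(ni) != 0, dim = dim(ni)),
                        spacing = diag(m)[1:3], origin = m[1:3, 4])
  if (!is.null(reference)) check_aligned(msk, reference, sprintf("mask '%s' and grid", name))
  msk
}
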