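#' Find dose hotspots by 3D connected components
#'
#' A hotspot is a connected set of body voxels receiving at least the
#' threshold dose whose volume exceeds a minimum (clinical convention: any
#' disconnected volume larger than 1 cm^3 receiving 107% of the prescription).
#' Connectivity is 26-neighbor by default (faces, edges and corners) so
#' scattered peripheral components merge realistically; 6-neighbor is
#' available.
#'
#' @param dose dose `fif_grid` (Gy).
#' @param body `fif_mask` restricting the search (detection uses the body;
#'   reporting denominators may differ).
#' @param threshold_gy absolute dose threshold in Gy.
#' @param min_volume_cm3 components with volume less than or equal to this are
#'   discarded (default 1).
#' @param connectivity 26 (default) or 6.
#' @param rx_gy prescription dose used to express peaks as percentages.
#' @return An object of class `fif_hotspots`: a list with `components` (tibble
#'   with `component`, `n_voxels`, `volume_cm3`, `peak_gy`, `peak_pct`),
#'   `threshold_gy`, `max_pct` (peak dose of any qualifying component as % of
#'   Rx, `NA` if none), and `supra_volume_cm3` (total supra-threshold body
#'   volume, no minimum-volume filter).
#' @examples
#' g <- image_grid(array(30, c(8, 8, 8)), spacing = c(5, 5, 5))
#' body <- structure_mask("body", array(TRUE, c(8, 8, 8)), c(5, 5, 5))
#' find_hotspots(g, body, threshold_gy = 32.1, rx_gy = 30)
#' @export
find_hotspots <- function(dose, body, threshold_gy, min_volume_cm3 = 1,
                          connectivity = 26, rx_gy = 30) {
  stopifnot(inherits(dose, "fif_grid"), inherits(body, "fif_mask"))
  check_aligned(dose, body, "dose grid and body mask")
  vox_cm3 <- voxel_volume_cm3(dose)
  supra <- body$mask & (dose$values >= threshold_gy)
  dims <- dim(supra)
  empty <- tibble::tibble(component = integer(), n_voxels = integer(),
                          volume_cm3 = numeric(), peak_gy = numeric(),
                          peak_pct = numeric())
  res <- list(components = empty, threshold_gy = threshold_gy,
              max_pct = NA_real_, supra_volume_cm3 = sum(supra) * vox_cm3,
              connectivity = connectivity, rx_gy = rx_gy,
              labels = NULL)
  if (!any(supra)) return(structure(res, class = "fif_hotspots"))

  labels <- array(.cc_label3d(as.vector(supra), dims, as.integer(connectivity)),
                  dims)
  nlab <- max(labels)
  counts <- tabulate(labels[labels > 0L], nbins = nlab)
  peaks <- vapply(seq_len(nlab), function(l) max(dose$values[labels == l]),
                  numeric(1))
  vols <- counts * vox_cm3
  keep <- which(vols > min_volume_cm3)
  comp <- tibble::tibble(
    component = seq_along(keep),
    n_voxels = counts[keep],
    volume_cm3 = vols[keep],
    peak_gy = peaks[keep],
    peak_pct = 100 * peaks[keep] / rx_gy
  )
  # relabel kept components 1..k in raster order, everything else background
  relab <- integer(nlab)
  relab[keep] <- seq_along(keep)
  labels <- array(c(0L, relab)[labels + 1L], dims)
  res$components <- comp
  res$labels <- labels
  res$max_pct <- if (nrow(comp)) max(comp$peak_pct) else NA_real_
  structure(res, class = "fif_hotspots")
}

#' @export
print.fif_hotspots <- function(x, ...) {
  cat(sprintf(
    "<fif_hotspots> %d component(s) above %.2f Gy (> %s); supra-threshold volume %.1f cm^3\n",
    nrow(x$components), x$threshold_gy,
    if (is.na(x$max_pct)) "none qualify" else sprintf("max %.1f%% of Rx", x$max_pct),
    x$supra_volume_cm3
  ))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

#' @export
tidy.fif_hotspots <- function(x, ...) x$components
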