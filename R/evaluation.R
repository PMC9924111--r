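#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: for each dose bin edge, the fraction of the
#' structure volume receiving at least that dose. Starts at 1 at 0 Gy, is
#' non-increasing, and reaches 0 beyond the maximum dose. The default bin
#' width of 0.01 Gy supports comparisons at the 0.1-0.2 Gy scale typical of
#' target-coverage metrics.
#'
#' @param dose dose `fif_grid` (Gy).
#' @param mask non-empty `fif_mask`.
#' @param bin_width bin width in Gy (default 0.01).
#' @return An object of class `fif_dvh`: a tibble with columns `dose_gy` and
#'   `volume_fraction`, carrying attributes `structure`, `volume_cm3` and
#'   `bin_width`.
#' @examples
#' g <- image_grid(array(30, c(4, 4, 4)), spacing = c(5, 5, 5))
#' m <- structure_mask("brain", array(TRUE, c(4, 4, 4)), c(5, 5, 5))
#' dvh <- compute_dvh(g, m)
#' dose_at_volume(dvh, 0.95)
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(inherits(dose, "fif_grid"), inherits(mask, "fif_mask"))
  check_aligned(dose, mask, "dose grid and mask")
  x <- dose$values[mask$mask]
  if (length(x) == 0L) stop("empty mask: cannot compute a DVH", call. = FALSE)
  s <- sort(x)
  n <- length(s)
  edges <- seq(0, max(s) + bin_width, by = bin_width)
  # fraction of voxels with dose >= edge
  frac <- (n - findInterval(edges - 1e-9, s)) / n
  out <- tibble::tibble(dose_gy = edges, volume_fraction = frac)
  structure(out,
            structure = mask$name,
            volume_cm3 = mask_volume_cm3(mask),
            bin_width = bin_width,
            class = c("fif_dvh", class(out)))
}

#' Dose-at-volume (Dx) from a DVH
#'
#' The dose received by at least the given volume fraction: the largest dose
#' `d` on the cumulative DVH with `volume_fraction(d) >= fraction`, linearly
#' interpolated between bins. `dose_at_volume(dvh, 0.95)` is the D95%.
#'
#' @param dvh an `fif_dvh`.
#' @param fraction volume fraction in (0, 1].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, fraction) {
  if (any(fraction <= 0 | fraction > 1)) {
    stop("volume fraction must lie in (0, 1]; use the maximum dose for fraction 0",
         call. = FALSE)
  }
  f <- dvh$volume_fraction
  d <- dvh$dose_gy
  vapply(fraction, function(fr) {
    if (fr > f[1]) return(d[1])
    i <- max(which(f >= fr)) # f is non-increasing
    if (i == length(f) || f[i] == fr) return(d[i])
    # interpolate within the bin where the curve drops through fr
    d[i] + (d[i + 1] - d[i]) * (f[i] - fr) / (f[i] - f[i + 1])
  }, numeric(1))
}

#' Volume-at-dose (Vd) from a DVH
#'
#' The structure volume receiving at least the given dose, as both absolute
#' cm^3 and a fraction, linearly interpolated between bins.
#'
#' @param dvh an `fif_dvh`.
#' @param gy dose level in Gy.
#' @return A tibble with `dose_gy`, `fraction` and `cm3`.
#' @export
volume_at_dose <- function(dvh, gy) {
  f <- dvh$volume_fraction
  d <- dvh$dose_gy
  fr <- vapply(gy, function(g) {
    if (g <= d[1]) return(f[1])
    if (g >= d[length(d)]) return(0)
    stats::approx(d, f, xout = g, ties = "ordered")$y
  }, numeric(1))
  tibble::tibble(dose_gy = gy, fraction = fr,
                 cm3 = fr * attr(dvh, "volume_cm3"))
}

#' Quantitative plan metrics
#'
#' The standard whole-brain plan report: brain D99%/D95%/D1% (Gy), mean dose
#' to each eye, maximum dose to each lens, the maximum hotspot percentage
#' (100 x maximum body dose / Rx), and the hotspot volume V107% in cm^3 and
#' as a percentage of the brain structure (the brain volume is the
#' denominator even though detection runs over the body). Missing structures
#' are reported as `NA` with a note; remaining metrics are still computed.
#'
#' @param dose plan dose `fif_grid`.
#' @param masks named list of `fif_mask` (expects `brain`, `body`, `eye_L`,
#'   `eye_R`, `lens_L`, `lens_R`; any may be absent).
#' @param rx_gy prescription dose (default 30).
#' @param hotspot_fraction hotspot dose level as a fraction of Rx
#'   (default 1.07).
#' @param bin_width DVH bin width for the Dx metrics.
#' @param max_dose_cc if positive, maximum-dose metrics use the hottest
#'   `max_dose_cc` cm^3 (e.g. 0.03) instead of the single hottest voxel.
#' @return A tibble with columns `metric`, `structure`, `value`, `unit`,
#'   `note`.
#' @export
plan_metrics <- function(dose, masks, rx_gy = 30, hotspot_fraction = 1.07,
                         bin_width = 0.01, max_dose_cc = 0) {
  vox_cm3 <- voxel_volume_cm3(dose)
  row <- function(metric, structure, value, unit, note = NA_character_) {
    tibble::tibble(metric = metric, structure = structure, value = value,
                   unit = unit, note = note)
  }
  max_dose_of <- function(x) {
    if (max_dose_cc > 0) {
      k <- max(1L, ceiling(max_dose_cc / vox_cm3))
      mean(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))])
    } else max(x)
  }
  out <- list()
  if (!is.null(masks$brain) && any(masks$brain$mask)) {
    dvh <- compute_dvh(dose, masks$brain, bin_width)
    for (p in c(0.99, 0.95, 0.01)) {
      out[[length(out) + 1]] <- row(sprintf("D%g%%", 100 * p), "brain",
                                    dose_at_volume(dvh, p), "Gy")
    }
  } else {
    out[[length(out) + 1]] <- row("D99%", "brain", NA_real_, "Gy", "missing mask")
  }
  for (s in c("eye_L", "eye_R")) {
    if (!is.null(masks[[s]]) && any(masks[[s]]$mask)) {
      out[[length(out) + 1]] <- row("mean", s, mean(dose$values[masks[[s]]$mask]), "Gy")
    } else {
      out[[length(out) + 1]] <- row("mean", s, NA_real_, "Gy", "missing mask")
    }
  }
  for (s in c("lens_L", "lens_R")) {
    if (!is.null(masks[[s]]) && any(masks[[s]]$mask)) {
      out[[length(out) + 1]] <- row("max", s, max_dose_of(dose$values[masks[[s]]$mask]), "Gy")
    } else {
      out[[length(out) + 1]] <- row("max", s, NA_real_, "Gy", "missing mask")
    }
  }
  thr <- hotspot_fraction * rx_gy
  if (!is.null(masks$body) && any(masks$body$mask)) {
    body_dose <- dose$values[masks$body$mask]
    out[[length(out) + 1]] <- row("max_hotspot", "body",
                                  100 * max(body_dose) / rx_gy, "% of Rx")
    v107 <- sum(body_dose >= thr) * vox_cm3
    out[[length(out) + 1]] <- row(sprintf("V%g%%", 100 * hotspot_fraction),
                                  "body", v107, "cm^3")
    if (!is.null(masks$brain) && any(masks$brain$mask)) {
      out[[length(out) + 1]] <- row(sprintf("V%g%%", 100 * hotspot_fraction),
                                    "body", 100 * v107 / mask_volume_cm3(masks$brain),
                                    "% of brain")
    }
  } else {
    out[[length(out) + 1]] <- row("max_hotspot", "body", NA_real_, "% of Rx",
                                  "missing mask")
  }
  do.call(rbind, out)
}
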