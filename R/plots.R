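#' Plot a DVH curve
#'
#' @param object an `fif_dvh`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fif_dvh <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy,
                                       y = 100 * .data$volume_fraction)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = sprintf("DVH: %s", attr(object, "structure"))) +
    ggplot2::theme_minimal()
}

#' Overlaid DVH curves for several structures
#'
#' @param dose plan dose `fif_grid`.
#' @param masks named list of `fif_mask`.
#' @param bin_width DVH bin width in Gy.
#' @return A ggplot of the cumulative DVH per structure.
#' @export
plot_dvh <- function(dose, masks, bin_width = 0.01) {
  curves <- lapply(masks, function(m) {
    if (!any(m$mask)) return(NULL)
    d <- compute_dvh(dose, m, bin_width)
    tibble::tibble(structure = m$name, dose_gy = d$dose_gy,
                   volume_pct = 100 * d$volume_fraction)
  })
  df <- do.call(rbind, curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_gy, y = .data$volume_pct,
                                   color = .data$structure)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the FIF iteration trajectory
#'
#' Hotspot volume before/after each iteration and the block threshold
#' schedule of a finished run.
#'
#' @param object an `fif_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fif_result <- function(object, ...) {
  log <- object$log
  if (!nrow(log)) {
    df <- tibble::tibble(iteration = 0, v = object$initial$v_hot_cm3)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$v)) +
             ggplot2::geom_point() +
             ggplot2::labs(x = "Iteration", y = "Hotspot volume (cm^3)") +
             ggplot2::theme_minimal())
  }
  df <- tibble::tibble(
    iteration = c(0, log$iteration),
    v_hotspot_cm3 = c(log$v_hotspot_cm3_before[1], log$v_hotspot_cm3_after),
    max_body_pct = c(log$max_body_pct_pre[1], log$max_body_pct_post)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$v_hotspot_cm3)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "FIF iteration", y = "Hotspot volume (cm^3)",
                  title = "Hotspot volume across accepted iterations") +
    ggplot2::theme_minimal()
}
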