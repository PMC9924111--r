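default_run_config <- function() {
  list(
    phantom = list(preset = "default", spacing = 2, seed = 1),
    beams = list(gantries = c(90, 270), sad = 1000, energy = "6 MV"),
    engine = list(mu = 0.028, d_max = 1.5, inverse_square = TRUE,
                  penumbra_sigma = 0, step_mm = 1, buildup_rate = 3,
                  output = 4),
    aperture = list(margin_mm = 7, leaf_width = 5, bev_spacing = 2,
                    bev_half_width = 150),
    fif = list(rx_gy = 30, n_fractions = 10, hotspot_fraction = 1.07,
               min_hotspot_volume_cm3 = 1, decrement_pct = 3,
               max_subfields = 6, min_mu = 5, mu_ref = 100,
               coverage = 0.999, dose_level = 1.0, connectivity = 26,
               block_per_component = FALSE, overdose_weight = 1,
               underdose_weight = 10, hotspot_weight = 1),
    normalization = list(mode = "volume")
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("validation error: unknown key%s in `%s`: %s",
                 if (length(unknown) > 1) "s" else "", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(user)] <- user
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills every unset key with the clinical
#' defaults (107% hotspot level, 1 cm^3 minimum component, 3-point decrement,
#' six subfields, 5 MU floor, 99.9% coverage, 30 Gy in 10 fractions), rejects
#' unknown keys, and validates ranges before any computation. An empty or
#' absent file yields the full default configuration. Sections: `phantom`,
#' `beams`, `engine`, `aperture`, `fif`, `normalization`.
#'
#' The `normalization` mode `"point"` is exposed for completeness but not
#' implemented; only volume-based normalization is available.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A validated config list of class `fif_run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("validation error: config file '%s' does not exist", path),
           call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("validation error: unknown top-level key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- lapply(names(defaults), function(s) merge_section(defaults[[s]], user[[s]], s))
  names(cfg) <- names(defaults)

  f <- cfg$fif
  if (f$coverage <= 0 || f$coverage > 1) {
    stop("validation error: `fif.coverage` must lie in (0, 1]", call. = FALSE)
  }
  if (f$min_mu < 0) stop("validation error: `fif.min_mu` must be >= 0", call. = FALSE)
  if (f$rx_gy <= 0) stop("validation error: `fif.rx_gy` must be positive", call. = FALSE)
  if (f$max_subfields < 0) {
    stop("validation error: `fif.max_subfields` must be >= 0", call. = FALSE)
  }
  if (cfg$engine$mu <= 0) stop("validation error: `engine.mu` must be positive", call. = FALSE)
  if (cfg$beams$sad <= 0) stop("validation error: `beams.sad` must be positive", call. = FALSE)
  if (!cfg$normalization$mode %in% c("volume", "point")) {
    stop("validation error: `normalization.mode` must be 'volume' or 'point'",
         call. = FALSE)
  }
  if (cfg$normalization$mode == "point") {
    stop("normalization by point is not implemented; use mode 'volume'",
         call. = FALSE)
  }
  if (!cfg$phantom$preset %in% c("default", "mild", "stress")) {
    stop("validation error: `phantom.preset` must be one of default, mild, stress",
         call. = FALSE)
  }
  structure(cfg, class = c("fif_run_config", "list"))
}

#' Write a run configuration to YAML
#' @param config an `fif_run_config` (or compatible list).
#' @param path output file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_to_objects <- function(cfg) {
  ph_args <- cfg$phantom
  phantom_files <- ph_args$density
  ph_args$density <- NULL
  spec <- do.call(phantom_spec, ph_args)
  fifc <- do.call(fif_config, cfg$fif)
  eng <- do.call(engine_params, cfg$engine)
  geoms <- opposed_pair(cfg$beams$gantries, sad = cfg$beams$sad,
                        energy = cfg$beams$energy)
  bev <- bev_grid(cfg$aperture$bev_spacing, cfg$aperture$bev_half_width)
  list(spec = spec, fif = fifc, engine = eng, geoms = geoms, bev = bev,
       margin_mm = cfg$aperture$margin_mm, leaf_width = cfg$aperture$leaf_width)
}

# plan file: structured text with prescription, per-field geometry, MLC
# intervals, weight and MU
plan_to_list <- function(plan) {
  list(
    prescription = list(rx_gy = plan$rx_gy, n_fractions = plan$n_fractions),
    mu_per_unit_weight = plan$mu_ref,
    fields = lapply(plan$fields, function(f) {
      mlc <- f$aperture$mlc
      list(
        id = f$id, role = f$role,
        gantry_deg = f$geometry$gantry_deg, sad = f$geometry$sad,
        energy = f$geometry$energy,
        weight = round(f$weight, 8), mu = round(f$mu, 4),
        leaf_width_mm = f$aperture$leaf_width,
        mlc = lapply(seq_len(nrow(mlc)), function(i) list(
          leaf = mlc$leaf[i], v_min = mlc$v_min[i], v_max = mlc$v_max[i],
          u_min = round(mlc$u_min[i], 4), u_max = round(mlc$u_max[i], 4),
          open = mlc$open[i]
        ))
      )
    })
  )
}

#' Write a plan to a YAML plan file
#' @param plan an `fif_plan`.
#' @param path output file.
#' @export
write_plan <- function(plan, path) {
  yaml::write_yaml(plan_to_list(plan), path)
  invisible(path)
}

#' Run the end-to-end planning pipeline
#'
#' Orchestrates the full workflow: phantom generation, aperture construction,
#' initial equal-weight opposed-lateral plan, normalization, the iterative
#' FIF loop, and evaluation. Writes, under `out_dir`: the resolved
#' configuration (`config.yaml`), the final plan (`plan.yaml`), the
#' per-iteration log (`iteration_log.csv`), before/after metrics
#' (`metrics.csv`), and the initial and final dose grids plus the density and
#' masks as NIfTI. Deterministic given the configuration.
#'
#' @param config an `fif_run_config` from [load_config()].
#' @param out_dir output directory (created if needed).
#' @param write_grids write NIfTI dose/density/mask artifacts (default TRUE).
#' @return Invisibly, a list with `result` (`fif_result`), `metrics`
#'   (before/after tibble), `phantom` and `state`.
#' @export
run_pipeline <- function(config = load_config(), out_dir = NULL,
                         write_grids = TRUE) {
  obj <- config_to_objects(config)
  phantom <- make_head_phantom(obj$spec)
  state <- make_initial_plan(phantom, obj$fif, obj$geoms, obj$engine, obj$bev,
                             obj$margin_mm, obj$leaf_width)
  result <- run_fif(state, phantom$masks)

  metr <- function(dose, phase) {
    m <- plan_metrics(dose, phantom$masks, rx_gy = obj$fif$rx_gy,
                      hotspot_fraction = obj$fif$hotspot_fraction)
    m$phase <- phase
    m
  }
  metrics <- rbind(metr(result$initial_dose, "initial"),
                   metr(result$final_dose, "final"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    write_plan(result$plan, file.path(out_dir, "plan.yaml"))
    utils::write.csv(result$log, file.path(out_dir, "iteration_log.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (write_grids) {
      write_grid(phantom$grid, file.path(out_dir, "density.nii.gz"))
      write_grid(result$initial_dose, file.path(out_dir, "dose_initial.nii.gz"))
      write_grid(result$final_dose, file.path(out_dir, "dose_final.nii.gz"))
      mdir <- file.path(out_dir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (m in phantom$masks) {
        write_mask(m, file.path(mdir, paste0(m$name, ".nii.gz")))
      }
    }
  }
  invisible(list(result = result, metrics = metrics, phantom = phantom,
                 state = state))
}
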