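# shared fixtures: small grids, oracle implementations, cached preset runs

# uniform grid of a given value
uniform_grid <- function(value, dims = c(8, 8, 8), spacing = c(5, 5, 5)) {
  image_grid(array(value, dims), spacing = spacing)
}

full_mask <- function(name, dims = c(8, 8, 8), spacing = c(5, 5, 5)) {
  structure_mask(name, array(TRUE, dims), spacing = spacing)
}

# independent flood-fill connected-component oracle (pure R, breadth-first)
flood_fill_labels <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, dims)
  lab <- 0L
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        n <- ijk + offs[r, ]
        if (any(n < 1) || any(n > dims)) next
        li <- (n[3] - 1) * dims[1] * dims[2] + (n[2] - 1) * dims[1] + n[1]
        if (mask[li] && labels[li] == 0L) {
          labels[li] <- lab
          queue <- c(queue, li)
        }
      }
    }
  }
  labels
}

# homogeneous slab phantom for central-axis depth-dose checks: unit density
# everywhere, wide open aperture, beam along +x from gantry 270
slab_setup <- function(nx = 120, ny = 21, nz = 21, spacing = 2) {
  dims <- c(nx, ny, nz)
  origin <- c(0, -(ny - 1) / 2 * spacing, -(nz - 1) / 2 * spacing)
  grid <- image_grid(array(1, dims), spacing = rep(spacing, 3), origin = origin)
  geom <- beam_geometry(270, isocenter = c(0, 0, 0), sad = 1000)
  bev <- bev_grid(spacing = 2, half_width = 40)
  region <- matrix(TRUE, length(bev$u), length(bev$v))
  ap <- fifplan:::new_aperture(conform_mlc(region, bev, leaf_width = 5), bev, 5)
  list(grid = grid, geom = geom, bev = bev, aperture = ap, origin = origin,
       spacing = spacing)
}

# caches full-resolution preset runs so acceptance tests share one run each
.run_cache <- new.env(parent = emptyenv())

preset_run <- function(preset, mu = NULL) {
  key <- paste0(preset, "_", if (is.null(mu)) "default" else mu)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  params <- if (is.null(mu)) engine_params() else engine_params(mu = mu)
  phantom <- make_head_phantom(phantom_spec(preset = preset))
  state <- make_initial_plan(phantom, params = params)
  result <- run_fif(state, phantom$masks)
  out <- list(phantom = phantom, state = state, result = result)
  .run_cache[[key]] <- out
  out
}

# a coarse, fast phantom for unit-level pipeline checks
small_phantom <- function(spacing = 4, preset = "default", ...) {
  make_head_phantom(phantom_spec(preset = preset, spacing = spacing, ...))
}
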