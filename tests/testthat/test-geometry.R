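one_voxel_mask <- function(world, dims = c(111, 41, 61), spacing = 2) {
  origin <- -(dims - 1) / 2 * spacing
  ijk <- round((world - origin) / spacing) + 1
  m <- array(FALSE, dims)
  m[ijk[1], ijk[2], ijk[3]] <- TRUE
  structure_mask("pt", m, rep(spacing, 3), origin)
}

test_that("a voxel at the isocenter projects to the BEV origin", {
  geom <- beam_geometry(90)
  bev <- bev_grid(spacing = 2, half_width = 60)
  bb <- project_to_bev(one_voxel_mask(c(0, 0, 0)), geom, bev)
  center <- (bev$n + 1) / 2
  expect_true(bb[center, center])
  expect_equal(sum(bb), 1)
})

test_that("divergent magnification follows similar triangles", {
  # point 50 mm superior of the isocenter and 100 mm closer to the source
  # (SAD 1000) lands at 50 * 1000/900 = 55.6 mm on the isocenter plane
  geom <- beam_geometry(90, sad = 1000) # source at +x
  bev <- bev_grid(spacing = 2, half_width = 80)
  mask <- one_voxel_mask(c(100, 0, 50))
  bb <- project_to_bev(mask, geom, bev)
  hit <- which(bb, arr.ind = TRUE)
  expect_equal(nrow(hit), 1)
  v_mm <- bev$v[hit[1, 2]]
  expect_equal(v_mm, 50 * 1000 / 900, tolerance = bev$spacing / 2 / 55)
  u_mm <- bev$u[hit[1, 1]]
  expect_equal(u_mm, 0)
})

test_that("empty masks project to empty maps and interior sources error", {
  geom <- beam_geometry(90)
  bev <- bev_grid()
  empty <- structure_mask("none", array(FALSE, c(5, 5, 5)), c(2, 2, 2))
  expect_equal(sum(project_to_bev(empty, geom, bev)), 0)
  inside <- beam_geometry(90, sad = 10) # source 10 mm out: inside the box
  big <- structure_mask("big", array(TRUE, c(41, 41, 41)), c(2, 2, 2),
                        origin = c(-40, -40, -40))
  expect_error(project_to_bev(big, inside, bev), "geometry error")
})

test_that("projection is monotone in the mask", {
  set.seed(42)
  geom <- beam_geometry(270)
  bev <- bev_grid(spacing = 2, half_width = 80)
  for (i in 1:5) {
    a <- array(runif(20^3) < 0.1, c(20, 20, 20))
    b <- a | (array(runif(20^3) < 0.1, c(20, 20, 20)))
    ma <- structure_mask("a", a, c(2, 2, 2), c(-20, -20, -20))
    mb <- structure_mask("b", b, c(2, 2, 2), c(-20, -20, -20))
    pa <- project_to_bev(ma, geom, bev)
    pb <- project_to_bev(mb, geom, bev)
    expect_false(any(pa & !pb))
  }
})

test_that("MLC conformance reproduces an axis-aligned rectangle exactly", {
  bev <- bev_grid(spacing = 2, half_width = 50)
  region <- outer(bev$u >= -20 & bev$u <= 20, bev$v >= -10 & bev$v < 10, "&")
  mlc <- conform_mlc(region, bev, leaf_width = 5)
  open <- mlc[mlc$open, ]
  expect_equal(nrow(open), 4) # 20 mm of v extent / 5 mm leaves
  expect_true(all(open$u_min == -21)) # pixel center -20 minus half spacing
  expect_true(all(open$u_max == 21))
  expect_true(all(mlc$u_min[!mlc$open] == 0 & mlc$u_max[!mlc$open] == 0))
})

test_that("MLC conformance of a disk matches per-row extents within a pixel", {
  bev <- bev_grid(spacing = 2, half_width = 60)
  r <- 35
  region <- outer(bev$u, bev$v, function(u, v) u^2 + v^2 <= r^2)
  mlc <- conform_mlc(region, bev, leaf_width = 5)
  for (i in which(mlc$open)) {
    rows <- which(bev$v >= mlc$v_min[i] & bev$v < mlc$v_max[i])
    expected <- range(bev$u[rowSums(region[, rows, drop = FALSE]) > 0])
    expect_lte(abs(mlc$u_min[i] - (expected[1] - 1)), bev$spacing)
    expect_lte(abs(mlc$u_max[i] - (expected[2] + 1)), bev$spacing)
  }
  # over-cover rule: region is contained in the rasterized MLC open area
  ap <- fifplan:::new_aperture(mlc, bev, 5)
  expect_false(any(region & !ap$open))
})

test_that("empty regions close every leaf pair", {
  bev <- bev_grid(spacing = 2, half_width = 40)
  mlc <- conform_mlc(matrix(FALSE, bev$n, bev$n), bev, 5)
  expect_false(any(mlc$open))
})

test_that("whole-brain aperture area matches the dilated-disk analytic area", {
  bev <- bev_grid(spacing = 2, half_width = 110)
  disk <- outer(bev$u, bev$v, function(u, v) u^2 + v^2 <= 70^2)
  ap <- make_whole_brain_aperture(disk, list(), margin_mm = 7, bev = bev,
                                  leaf_width = 5)
  area <- aperture_area_cm2(ap)
  analytic <- pi * 7.7^2
  # one pixel ring of tolerance around the perimeter, plus leaf discretization
  ring <- 2 * pi * 7.7 * (2 * bev$spacing / 10)
  expect_lt(abs(area - analytic), ring)
})

test_that("blocking the whole target raises a degenerate-aperture error", {
  bev <- bev_grid(spacing = 2, half_width = 60)
  disk <- outer(bev$u, bev$v, function(u, v) u^2 + v^2 <= 40^2)
  everything <- matrix(TRUE, bev$n, bev$n)
  expect_error(make_whole_brain_aperture(disk, list(everything), 7, bev, 5),
               "degenerate aperture")
})

test_that("aperture mirroring is an involution and preserves area", {
  bev <- bev_grid(spacing = 2, half_width = 60)
  blob <- outer(bev$u, bev$v, function(u, v) (u - 25)^2 + (v + 10)^2 <= 15^2)
  ap <- make_whole_brain_aperture(blob, list(), 0, bev, 5)
  m <- mirror_aperture(ap)
  expect_equal(mirror_aperture(m)$open, ap$open)
  expect_equal(aperture_area_cm2(m), aperture_area_cm2(ap))
  # the off-center blob lands on the opposite side of the u axis
  expect_equal(m$open[bev$n:1, ], ap$open)
  expect_false(isTRUE(all.equal(m$open, ap$open)))
  # a u-symmetric aperture is its own mirror
  sym <- make_whole_brain_aperture(
    outer(bev$u, bev$v, function(u, v) u^2 + v^2 <= 30^2), list(), 0, bev, 5)
  expect_equal(mirror_aperture(sym)$open, sym$open)
})
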