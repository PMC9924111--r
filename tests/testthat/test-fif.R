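test_that("block threshold steps down by the decrement and floors at the target", {
  expect_equal(select_block_threshold(116)$threshold_pct, 113) # worked example
  expect_true(select_block_threshold(107)$stop)                # target reached
  expect_true(select_block_threshold(106.2)$stop)
  expect_true(select_block_threshold(NA_real_)$stop)
  expect_equal(select_block_threshold(108.5)$threshold_pct, 107) # floor rule
  expect_equal(select_block_threshold(120, decrement_pct = 5)$threshold_pct, 115)
  expect_equal(select_block_threshold(112, target_pct = 110)$threshold_pct, 110)
})

test_that("configuration defaults match the clinical settings and are validated", {
  cfg <- fif_config()
  expect_equal(cfg$rx_gy, 30)
  expect_equal(cfg$n_fractions, 10)
  expect_equal(cfg$hotspot_fraction, 1.07)
  expect_equal(cfg$min_hotspot_volume_cm3, 1)
  expect_equal(cfg$decrement_pct, 3)
  expect_equal(cfg$max_subfields, 6)
  expect_equal(cfg$min_mu, 5)
  expect_equal(cfg$coverage, 0.999)
  expect_equal(cfg$max_iterations, 3)
  expect_error(fif_config(coverage = 1.5), "coverage")
  expect_error(fif_config(max_subfields = -2), "max_subfields")
  expect_error(fif_config(connectivity = 18), "connectivity")
})

fif_state_4mm <- function() {
  if (is.null(.run_cache$state4)) {
    ph <- small_phantom(spacing = 4)
    .run_cache$state4 <- list(ph = ph, state = make_initial_plan(ph))
  }
  .run_cache$state4
}

test_that("an empty block projection is flagged as a no-op", {
  s4 <- fif_state_4mm()
  dose <- plan_dose(s4$state$plan)
  pair <- make_subfield_pair(s4$state, dose, block_threshold_gy = 1e6,
                             body = s4$ph$masks$body)
  expect_true(pair$noop)
  expect_null(pair$apertures)
})

test_that("subfield apertures subtract the block under the one-interval leaf rule", {
  s4 <- fif_state_4mm()
  main <- s4$state$main_aperture
  bev <- s4$state$bev
  # synthetic dose: hot sphere centered in the aperture interior
  dims <- dim(s4$ph$grid$values)
  org <- s4$ph$grid$origin; sp <- s4$ph$grid$spacing
  xs <- org[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- org[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- org[3] + (seq_len(dims[3]) - 1) * sp[3]
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  hot <- X^2 + Y^2 + Z^2 <= 25^2
  dose <- image_grid(array(ifelse(hot, 40, 30), dims), sp, org)
  pair <- make_subfield_pair(s4$state, dose, block_threshold_gy = 35,
                             body = s4$ph$masks$body)
  expect_false(pair$noop)
  sub <- pair$apertures[[1]]
  # strict subset of the main aperture
  expect_false(any(sub$open & !main$open))
  expect_lt(aperture_area_cm2(sub), aperture_area_cm2(main))
  # the opposed subfield is the exact u-reflection
  expect_equal(pair$apertures[[2]]$open, sub$open[bev$n:1, ])

  # independent per-row oracle: larger remaining segment after removing the
  # block interval from the main interval (tie -> left)
  bm <- structure_mask("blk", hot & s4$ph$masks$body$mask, sp, org)
  block_bev <- project_to_bev(bm, s4$state$geoms[[1]], bev)
  half <- bev$spacing / 2
  leaf_id <- floor(bev$v / main$leaf_width)
  for (i in which(main$mlc$open)) {
    cols <- which(leaf_id == main$mlc$leaf[i])
    got <- sub$mlc[i, ]
    uu <- bev$u[rowSums(block_bev[, cols, drop = FALSE]) > 0]
    if (!length(uu)) {
      expect_equal(got$u_min, main$mlc$u_min[i])
      expect_equal(got$u_max, main$mlc$u_max[i])
      next
    }
    b <- c(min(uu) - half, max(uu) + half)
    a <- c(main$mlc$u_min[i], main$mlc$u_max[i])
    if (b[2] <= a[1] || b[1] >= a[2]) {
      expect_equal(unlist(got[c("u_min", "u_max")], use.names = FALSE), a)
      next
    }
    left <- c(a[1], max(a[1], min(b[1], a[2])))
    right <- c(min(a[2], max(b[2], a[1])), a[2])
    want <- if (diff(left) >= diff(right)) left else right
    if (max(diff(left), diff(right)) <= 0) {
      expect_false(got$open)
    } else {
      expect_equal(unlist(got[c("u_min", "u_max")], use.names = FALSE), want)
    }
  }
})

test_that("a phantom with no initial hotspot adds zero subfields", {
  ph <- small_phantom(spacing = 4, preset = "mild")
  state <- make_initial_plan(ph, params = engine_params(mu = 0.018))
  pre <- find_hotspots(plan_dose(state$plan), ph$masks$body, 1.07 * 30,
                       rx_gy = 30)
  expect_equal(nrow(pre$components), 0) # scenario precondition
  res <- run_fif(state, ph$masks)
  expect_equal(length(res$plan$fields), 2)
  expect_equal(res$stop_reason, "target_reached")
  expect_equal(nrow(res$log), 0)
})

test_that("the loop reverts and stops when blocking would enlarge the hotspot", {
  ph <- make_head_phantom(phantom_spec(body_semi_axes = c(82, 100, 84),
                                       bone_thickness = 8, jitter_amp = 2,
                                       spacing = 4))
  state <- make_initial_plan(ph)
  res <- run_fif(state, ph$masks)
  expect_equal(res$stop_reason, "hotspot_increased")
  log <- tidy(res)
  last <- log[nrow(log), ]
  expect_false(last$accepted)
  expect_gt(last$v_hotspot_cm3_after, last$v_hotspot_cm3_before)
  # the rejected pair was removed again: field count matches accepted iterations
  expect_equal(length(res$plan$fields), 2 + 2 * sum(log$accepted))
  # reverted plan state reproduces the pre-iteration hotspot volume
  m <- find_hotspots(plan_dose(res$plan), ph$masks$body, 1.07 * 30, rx_gy = 30)
  expect_equal(m$supra_volume_cm3, last$v_hotspot_cm3_before, tolerance = 1e-9)
})

test_that("the loop is deterministic and keeps plans even with floored MU", {
  ph <- small_phantom(spacing = 4)
  run_once <- function() run_fif(make_initial_plan(ph), ph$masks)
  a <- run_once()
  b <- run_once()
  expect_identical(tidy(a), tidy(b))
  expect_identical(fifplan:::plan_weights(a$plan), fifplan:::plan_weights(b$plan))
  expect_equal(length(a$plan$fields) %% 2, 0)
  mu <- vapply(a$plan$fields, `[[`, numeric(1), "mu")
  expect_true(all(mu >= 5 - 1e-9))
  # every subfield aperture is a subset of the main aperture
  main <- a$plan$fields[[1]]$aperture
  for (f in a$plan$fields[-(1:2)]) {
    ap <- if (f$beam == 1L) f$aperture else mirror_aperture(f$aperture)
    expect_false(any(ap$open & !main$open))
  }
})

test_that("accepted iterations never increase hotspot volume or peak", {
  for (preset in c("default", "mild", "stress")) {
    log <- tidy(preset_run(preset)$result)
    acc <- log[log$accepted, ]
    if (!nrow(acc)) next
    expect_true(all(acc$v_hotspot_cm3_after <= acc$v_hotspot_cm3_before + 1e-9),
                label = paste(preset, "volume"))
    expect_true(all(acc$max_body_pct_post <= acc$max_body_pct_pre + 1e-9),
                label = paste(preset, "peak"))
    # block thresholds follow the decrement-with-floor schedule
    expect_equal(acc$block_threshold_pct,
                 pmax(acc$max_hotspot_pct_pre - 3, 107))
  }
})
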