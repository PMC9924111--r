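test_that("a uniform dose gives a step-function DVH", {
  dvh <- compute_dvh(uniform_grid(30), full_mask("brain"))
  expect_equal(dvh$volume_fraction[dvh$dose_gy <= 30], rep(1, sum(dvh$dose_gy <= 30)))
  expect_equal(dvh$volume_fraction[dvh$dose_gy > 30.005],
               rep(0, sum(dvh$dose_gy > 30.005)))
  expect_equal(dose_at_volume(dvh, 0.95), 30, tolerance = 0.011)
  expect_equal(volume_at_dose(dvh, 32.1)$fraction, 0)
  expect_equal(volume_at_dose(dvh, 0)$fraction, 1) # V(0 Gy) is 100%
})

test_that("two-voxel DVH lookups match hand computation", {
  dims <- c(2, 1, 1)
  dose <- image_grid(array(c(10, 20), dims), c(10, 10, 10))
  dvh <- compute_dvh(dose, full_mask("s", dims, c(10, 10, 10)))
  expect_equal(volume_at_dose(dvh, 15)$fraction, 0.5)
  expect_equal(dose_at_volume(dvh, 0.5), 20, tolerance = 0.011)   # D50%
  expect_equal(dose_at_volume(dvh, 1.0), 10, tolerance = 0.011)   # D100%
  expect_equal(attr(dvh, "volume_cm3"), 2)
  expect_error(dose_at_volume(dvh, 0), "fraction")
  expect_error(compute_dvh(dose, structure_mask("none", array(FALSE, dims),
                                                c(10, 10, 10))), "empty mask")
})

test_that("DVH is monotone and Dx/Vx are mutually consistent on random doses", {
  set.seed(21)
  for (rep in 1:5) {
    dims <- c(9, 8, 7)
    dose <- image_grid(array(runif(prod(dims), 0, 40), dims), c(3, 3, 3))
    mask <- structure_mask("s", array(runif(prod(dims)) < 0.6, dims), c(3, 3, 3))
    dvh <- compute_dvh(dose, mask)
    expect_true(all(diff(dvh$volume_fraction) <= 0))
    expect_equal(dvh$volume_fraction[1], 1)
    fr <- c(0.99, 0.9, 0.5, 0.1)
    dx <- dose_at_volume(dvh, fr)
    expect_true(all(diff(dx) >= 0)) # smaller fraction, larger dose
    for (f in fr) {
      v <- volume_at_dose(dvh, dose_at_volume(dvh, f))$fraction
      expect_gte(v, f - 0.02)
    }
  }
})

test_that("plan metrics report the clinical set with correct ordering", {
  run <- preset_run("default")
  m <- plan_metrics(run$result$final_dose, run$phantom$masks)
  get <- function(metric, structure) m$value[m$metric == metric & m$structure == structure]
  expect_lte(get("D99%", "brain"), get("D95%", "brain"))
  expect_lte(get("D95%", "brain"), get("D1%", "brain"))
  # V107 in cm^3 against a direct voxel-count oracle
  dose <- run$result$final_dose
  body <- run$phantom$masks$body
  v_direct <- sum(dose$values[body$mask] >= 1.07 * 30) * voxel_volume_cm3(dose)
  expect_equal(get("V107%", "body")[1], v_direct)
  # % of brain uses the brain volume as denominator
  expect_equal(get("V107%", "body")[2],
               100 * v_direct / mask_volume_cm3(run$phantom$masks$brain))
  expect_equal(get("max_hotspot", "body"),
               100 * max(dose$values[body$mask]) / 30)
  # eyes and lenses are spared relative to the prescription
  expect_lt(get("mean", "eye_L"), 15)
  expect_lt(get("max", "lens_L"), 15)
})

test_that("uniform prescription dose yields degenerate metrics", {
  dims <- c(6, 6, 6)
  masks <- list(brain = full_mask("brain", dims), body = full_mask("body", dims))
  m <- plan_metrics(uniform_grid(30, dims), masks)
  vals <- m$value[m$metric %in% c("D99%", "D95%", "D1%")]
  expect_lt(max(abs(vals - 30)), 0.011) # within one DVH bin
  expect_equal(m$value[m$metric == "max_hotspot"], 100)
  expect_equal(m$value[m$metric == "V107%" & m$unit == "cm^3"], 0)
})

test_that("missing masks are reported but do not break other metrics", {
  dims <- c(6, 6, 6)
  masks <- list(brain = full_mask("brain", dims), body = full_mask("body", dims))
  m <- plan_metrics(uniform_grid(30, dims), masks)
  expect_true(any(m$note == "missing mask", na.rm = TRUE)) # eyes, lenses absent
  expect_true(all(is.finite(m$value[m$structure == "brain"])))
})

test_that("maximum-dose metrics support a small-volume convention", {
  dims <- c(10, 1, 1)
  vals <- seq(10, 37, length.out = 10)
  dose <- image_grid(array(vals, dims), c(10, 10, 10)) # 1 cm^3 voxels
  masks <- list(lens_L = full_mask("lens_L", dims, c(10, 10, 10)),
                body = full_mask("body", dims, c(10, 10, 10)))
  hottest <- plan_metrics(dose, masks)$value
  smoothed <- plan_metrics(dose, masks, max_dose_cc = 2)$value
  i <- which(plan_metrics(dose, masks)$metric == "max")
  expect_equal(hottest[i][1], 37)
  expect_equal(smoothed[i][1], mean(sort(vals, decreasing = TRUE)[1:2]))
})

test_that("DVH and iteration plots build without error", {
  run <- preset_run("mild")
  dvh <- compute_dvh(run$result$final_dose, run$phantom$masks$brain)
  expect_s3_class(autoplot(dvh), "ggplot")
  expect_s3_class(autoplot(run$result), "ggplot")
  p <- plot_dvh(run$result$final_dose,
                run$phantom$masks[c("brain", "eye_L", "lens_L")])
  expect_s3_class(p, "ggplot")
})
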