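toy_objective <- function(...) {
  weight_objective(rx_gy = 30, overdose_weight = 1, underdose_weight = 1,
                   hotspot_weight = 0, ...)
}

test_that("cost is zero at exact prescription and counts single-voxel excess", {
  obj <- toy_objective()
  D <- matrix(c(30, 30, 30), ncol = 1) # one field delivering exactly Rx
  expect_equal(fif_cost(1, D, obj), 0)
  D2 <- matrix(31, ncol = 1) # one voxel at Rx + 1 Gy
  expect_equal(fif_cost(1, D2, obj), 1)
  # underdose side
  expect_equal(fif_cost(1, matrix(28, ncol = 1), obj), 4)
})

test_that("analytic gradient matches finite differences", {
  set.seed(5)
  obj <- weight_objective(rx_gy = 30, underdose_weight = 3, hotspot_weight = 2,
                          hotspot_gy = 32.1)
  D <- matrix(runif(50 * 3, 10, 40), 50, 3)
  B <- matrix(runif(30 * 3, 10, 40), 30, 3)
  w <- c(0.7, 0.5, 0.9)
  g <- fifplan:::fif_cost_gradient(w, D, obj, B)
  eps <- 1e-6
  for (i in 1:3) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    num <- (fif_cost(wp, D, obj, B) - fif_cost(wm, D, obj, B)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("L-BFGS-B matches an exhaustive grid search on a 2-field toy", {
  set.seed(7)
  dims <- c(50, 1, 1)
  fd1 <- image_grid(array(runif(50, 5, 25), dims), c(2, 2, 2))
  fd2 <- image_grid(array(runif(50, 5, 25), dims), c(2, 2, 2))
  target <- full_mask("brain", dims, c(2, 2, 2))
  obj <- toy_objective(lower = 0.05, upper = 3)
  D <- fifplan:::dose_matrix(list(fd1, fd2), target)
  grid_w <- seq(0.05, 3, length.out = 200)
  costs <- outer(grid_w, grid_w, Vectorize(function(a, b) fif_cost(c(a, b), D, obj)))
  best <- which(costs == min(costs), arr.ind = TRUE)[1, ]
  w_grid <- c(grid_w[best[1]], grid_w[best[2]])
  fit <- optimize_weights(list(fd1, fd2), target, obj, start = c(1, 1))
  res <- (3 - 0.05) / 199 # grid resolution
  expect_lt(max(abs(fit$weights - w_grid)), res)
  expect_lte(fit$cost, costs[best[1], best[2]] + 1e-9)
})

test_that("optimization never increases the cost from its start", {
  set.seed(9)
  dims <- c(40, 1, 1)
  fds <- lapply(1:4, function(i) image_grid(array(runif(40, 5, 20), dims), c(2, 2, 2)))
  target <- full_mask("brain", dims, c(2, 2, 2))
  obj <- toy_objective(lower = 0.01, upper = 10)
  for (rep in 1:5) {
    start <- runif(4, 0.1, 3)
    D <- fifplan:::dose_matrix(fds, target)
    fit <- optimize_weights(fds, target, obj, start = start)
    expect_lte(fit$cost, fif_cost(pmin(pmax(start, 0.01), 10), D, obj) + 1e-9)
    expect_true(all(fit$weights >= 0.01 - 1e-12 & fit$weights <= 10 + 1e-12))
  }
})

test_that("a binding lower bound is returned exactly at the bound", {
  dims <- c(20, 1, 1)
  # field 1 alone is perfect; field 2 can only overdose part of the target,
  # so its optimum sits below the floor and the bound binds
  fd1 <- image_grid(array(30, dims), c(2, 2, 2))
  fd2 <- image_grid(array(rep(c(0, 10), each = 10), dims), c(2, 2, 2))
  target <- full_mask("brain", dims, c(2, 2, 2))
  obj <- toy_objective(lower = 0.05, upper = 5)
  fit <- optimize_weights(list(fd1, fd2), target, obj, start = c(1, 0.5))
  expect_equal(fit$weights[2], 0.05)
})

test_that("symmetric phantoms keep equal weights through optimization", {
  set.seed(3)
  dims <- c(30, 1, 1)
  a <- runif(30, 10, 20)
  fd1 <- image_grid(array(a, dims), c(2, 2, 2))
  fd2 <- image_grid(array(rev(a), dims), c(2, 2, 2)) # mirrored twin
  target <- full_mask("brain", dims, c(2, 2, 2))
  obj <- toy_objective(lower = 0.01, upper = 10)
  fit <- optimize_weights(list(fd1, fd2), target, obj, start = c(1, 1))
  expect_equal(fit$weights[1], fit$weights[2], tolerance = 1e-5)
})

test_that("normalization applies the exact closed-form scale", {
  dims <- c(10, 10, 10)
  fd <- uniform_grid(28, dims) # uniform 28 Gy per unit weight
  brain <- full_mask("brain", dims)
  nw <- normalize_weights(1, list(fd), brain, coverage = 0.999,
                          dose_level_gy = 30)
  expect_equal(nw$scale, 30 / 28)
  expect_equal(nw$weights, 30 / 28)
  expect_equal(nw$coverage_dose_gy, 30)
})

test_that("normalization is idempotent and supports the renormalization band", {
  run <- preset_run("mild")
  plan <- run$result$plan
  brain <- run$phantom$masks$brain
  w1 <- fifplan:::plan_weights(plan)
  nw <- normalize_weights(w1, plan$field_doses, brain, coverage = 0.999,
                          dose_level_gy = 30, min_weight = 0.05)
  expect_equal(nw$scale, 1, tolerance = 1e-9)
  expect_equal(nw$weights, w1, tolerance = 1e-9)
  # renormalization to a lower dose level (99.5% of Rx) scales down exactly
  renorm <- normalize_weights(w1, plan$field_doses, brain, coverage = 0.999,
                              dose_level_gy = 0.995 * 30)
  expect_equal(renorm$weights / w1, rep(0.995, length(w1)), tolerance = 1e-9)
})

test_that("zero target dose raises a normalization error", {
  dims <- c(5, 5, 5)
  fd <- uniform_grid(0, dims)
  brain <- full_mask("brain", dims)
  expect_error(normalize_weights(1, list(fd), brain), "normalization error")
})

test_that("the MU floor survives normalization via the projected rescale", {
  dims <- c(10, 1, 1)
  # a plan that must be scaled down: small field at the floor would dip below
  fd1 <- image_grid(array(60, dims), c(2, 2, 2))
  fd2 <- image_grid(array(1, dims), c(2, 2, 2))
  brain <- full_mask("brain", dims, c(2, 2, 2))
  nw <- normalize_weights(c(1, 0.06), list(fd1, fd2), brain,
                          coverage = 0.999, dose_level_gy = 30,
                          min_weight = 0.05)
  expect_gte(min(nw$weights), 0.05 - 1e-12)
  D <- fifplan:::dose_matrix(list(fd1, fd2), brain)
  expect_equal(fifplan:::coverage_dose(as.numeric(D %*% nw$weights), 0.999), 30,
               tolerance = 1e-6)
})

test_that("monitor units scale linearly with weight and respect the map", {
  expect_equal(assign_mu(1.0, mu_ref = 100), 100)
  expect_equal(assign_mu(c(0.5, 2), 100), c(50, 200))
  w <- c(0.3, 0.8)
  expect_equal(assign_mu(2 * w), 2 * assign_mu(w))
  expect_error(assign_mu(-1), "non-negative")
})
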