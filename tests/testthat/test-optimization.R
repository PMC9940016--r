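# Influence matrix consistency, nonnegative least squares, coverage
# normalization, MU conversion and minimum-MU filtering.

test_that("influence entries equal single-beamlet engine doses", {
  m <- fixture_model()
  plan <- toy_plan(m, collimated = TRUE)
  grid <- toy_grid(plan, m)
  infl <- build_influence_matrix(plan, m, grid)
  co <- grid_coords(grid)
  vox_index <- function(v) {
    cbind(match(v$x_mm, co$x), match(v$y_mm, co$y), match(v$z_mm, co$z))
  }
  idx <- vox_index(infl$voxels)
  for (bi in c(1, 20, nrow(plan$spots))) {
    w <- rep(0, nrow(plan$spots)); w[bi] <- 1
    dd <- compute_dose(plan, m, grid, weights = w)
    direct <- dd$values[idx]
    expect_lt(max(abs(direct - infl$A[, bi])) / max(direct), 1e-10)
  }
  # matrix-vector product with all-ones weights = composite dose
  dall <- compute_dose(plan, m, grid, weights = rep(1, nrow(plan$spots)))
  expect_equal(as.vector(infl$A %*% rep(1, nrow(plan$spots))),
               dall$values[idx], tolerance = 1e-10)
})

test_that("subsampling stride changes the optimized PTV mean dose by < 1%", {
  m <- fixture_model()
  plan <- toy_plan(m, collimated = FALSE)
  grid <- toy_grid(plan, m)
  mean_ptv <- function(stride) {
    infl <- build_influence_matrix(plan, m, grid, stride_mm = stride)
    opt <- optimize_weights(infl, 5)
    d <- compute_dose(plan, m, grid, weights = opt$weights)
    s <- normalize_coverage(d, plan$ptv, 5)
    mean(dcpt:::ptv_doses(d, plan$ptv)) * s
  }
  expect_equal(mean_ptv(2), mean_ptv(1), tolerance = 0.01)
})

test_that("NNLS solves identity, recovery and active-constraint cases", {
  # identity system
  opt <- optimize_weights(diag(6), prescription_gy = 5)
  expect_equal(opt$weights, rep(5, 6), tolerance = 1e-9)
  # seeded synthetic recovery with independent columns
  set.seed(20230220)
  A <- matrix(runif(40 * 8), 40, 8)
  w_true <- runif(8, 0.5, 2)
  b <- as.vector(A %*% w_true)
  opt <- optimize_weights(A, target = b, max_sweeps = 50000, tol = 1e-14)
  expect_lt(max(abs(opt$weights - w_true)) / max(w_true), 1e-6)
  # two collinear-ish columns forcing a negative unconstrained optimum
  A2 <- cbind(c(1, 1), c(1, 1.01))
  b2 <- c(1, 0.5)
  opt2 <- optimize_weights(A2, target = b2, max_sweeps = 10000)
  expect_true(any(opt2$weights == 0))
  expect_true(all(opt2$weights >= 0))
  expect_error(optimize_weights(matrix(0, 3, 3), target = rep(1, 3)),
               "all-zero")
})

test_that("NNLS agrees with an independent active-set reference solver", {
  skip_if_not_installed("pracma")
  set.seed(99)
  for (i in 1:5) {
    A <- matrix(rnorm(30 * 7), 30, 7)
    b <- rnorm(30)
    mine <- optimize_weights(A, target = b, max_sweeps = 50000, tol = 1e-14)
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(mine$weights, ref, tolerance = 1e-6)
  }
})

test_that("the NNLS residual never exceeds simple feasible comparison points", {
  set.seed(3)
  A <- matrix(runif(60 * 10), 60, 10)
  b <- runif(60, 0, 2)
  opt <- optimize_weights(A, target = b)
  resid <- function(w) sum((A %*% w - b)^2)
  uniform <- rep(sum(crossprod(A, b)) / sum(crossprod(A)), 10)
  expect_lte(2 * opt$objective, resid(pmax(uniform, 0)) + 1e-9)
  expect_lte(2 * opt$objective, resid(rep(0, 10)) + 1e-9)
  expect_true(all(opt$weights >= 0))
  g <- glance(opt)
  expect_equal(g$n_beamlets, 10)
})

test_that("coverage normalization hits the requested volume fraction", {
  ptv <- ptv_spec(side_mm = 6, center_depth_cm = 3)
  g <- dose_grid(c(-5, -5, 0.5), 1, c(11, 11, 40))
  co <- grid_coords(g)
  # uniform 4 Gy inside the PTV
  sel_x <- abs(co$x) <= 3; sel_z <- abs(co$z - 30) <= 3
  g$values[sel_x, sel_x, sel_z] <- 4
  expect_equal(normalize_coverage(g, ptv, 5, coverage = 0.9), 1.25)
  expect_equal(normalize_coverage(g, ptv, 5, coverage = 0.5), 1.25)
  # random dose field: scaled coverage lands within one quantile step
  set.seed(12)
  g$values[sel_x, sel_x, sel_z] <- runif(sum(sel_x)^2 * sum(sel_z), 2, 8)
  s <- normalize_coverage(g, ptv, 5, coverage = 0.9)
  d <- dcpt:::ptv_doses(g, ptv) * s
  n <- length(d)
  expect_gte(mean(d >= 5), 0.9 - 1 / n)
  expect_lte(mean(d >= 5), 0.9 + 1 / n)
  # already-satisfying dose
  g$values[sel_x, sel_x, sel_z] <- 5
  expect_equal(normalize_coverage(g, ptv, 5), 1)
  g$values[] <- 0
  expect_error(normalize_coverage(g, ptv, 5), "zero")
})

test_that("protons to MU conversion is linear and invertible", {
  calib <- list(d_meas_ref = 0.01, d_mc_ref = 1e-9)
  expect_equal(protons_to_mu(2e7, calib), 2)    # 1e7 protons per MU
  expect_equal(protons_to_mu(0, calib), 0)
  mu <- protons_to_mu(3.123e7, calib)
  expect_equal(mu * calib$d_meas_ref / calib$d_mc_ref, 3.123e7,
               tolerance = 1e-12)
  expect_error(protons_to_mu(1, list(d_meas_ref = 0, d_mc_ref = 1e-9)),
               "positive")
  m <- fixture_model()
  tab <- calibration_reference(m, c(80, 120, 160))
  expect_true(all(tab$d_mc_ref > 0))
})

test_that("the minimum-MU filter removes spots and empty layers", {
  m <- fixture_model()
  plan <- toy_plan(m)
  plan$spots$mu <- 1
  # untouched when the floor is zero
  expect_equal(nrow(apply_min_mu(plan, min_mu = 0)$plan$spots),
               nrow(plan$spots))
  # toy 3-spot layer pattern 0.04 / 0.06 / 0.04: one spot survives
  plan$spots$mu <- 1
  l1 <- which(plan$spots$layer_index == 1)
  plan$spots$mu[l1] <- rep(c(0.04, 0.06, 0.04), length.out = length(l1))
  filt <- apply_min_mu(plan, 0.05)
  expect_true(1 %in% filt$plan$layers$layer_index)
  expect_equal(sum(filt$plan$spots$layer_index == 1), sum(plan$spots$mu[l1] >= 0.05))
  # a fully sub-threshold layer is dropped and reported
  plan$spots$mu[plan$spots$layer_index == 2] <- 0.01
  filt2 <- apply_min_mu(plan, 0.05)
  expect_false(2 %in% filt2$plan$layers$layer_index)
  expect_true(filt2$report$layer_dropped[filt2$report$layer_index == 2])
  plan$spots$mu <- 0.001
  expect_error(apply_min_mu(plan, 0.05), "every spot")
})
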