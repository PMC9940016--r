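# Composite dose engine: linearity, zero behaviour, single-beamlet shape,
# and the engine <-> metric consistency on a Gaussian-blurred edge.

test_that("zero weights give an all-zero grid and weights act linearly", {
  m <- fixture_model()
  plan <- toy_plan(m, collimated = FALSE)
  grid <- toy_grid(plan, m)
  d0 <- compute_dose(plan, m, grid)
  expect_true(all(d0$values == 0))
  set.seed(7)
  w <- runif(nrow(plan$spots))
  d1 <- compute_dose(plan, m, grid, weights = w)
  d2 <- compute_dose(plan, m, grid, weights = 2 * w)
  expect_true(all(d1$values >= 0))
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  expect_error(compute_dose(plan, m, grid, weights = -w), "nonnegative")
})

test_that("a single uncollimated beamlet has the predicted Gaussian lateral shape", {
  m <- fixture_model()
  plan <- toy_plan(m, collimated = FALSE)
  grid <- toy_grid(plan, m)
  w <- rep(0, nrow(plan$spots))
  i <- which(plan$spots$layer_index == 1 & plan$spots$spot_x_mm == 0 &
               plan$spots$spot_y_mm == 0)
  w[i] <- 1e8
  dose <- compute_dose(plan, m, grid, weights = w)
  z <- 20.5
  prof <- extract_profile(dose, "x", at_mm = 0, depth_mm = z)
  E <- plan$layers$energy_mev[1]
  st <- beamlet_sigma_total(E, z / 10, m, tsd_cm = plan$tsd_cm)$sigma_total_mm
  mag <- (m$virtual_sad_x_mm + z) / m$virtual_sad_x_mm
  pred <- dnorm(prof$position_mm, 0, st * mag)
  sel <- abs(prof$position_mm) < 12
  ratio <- prof$value[sel] / max(prof$value)
  pref <- pred[sel] / max(pred)
  expect_lt(max(abs(ratio - pref)), 2e-3)
})

test_that("an 80-20 width of a Gaussian-blurred step edge equals 1.6832 sigma", {
  # engine <-> metric consistency anchor, checked analytically
  for (sig in c(1, 2, 3.5)) {
    p <- erf_edge_profile(sig, step_mm = 0.02)
    w <- penumbra_80_20(p, "right", normalization = "max")
    expect_equal(w, 1.6832 * sig, tolerance = 1e-3)
  }
})

test_that("collimated composite dose never exceeds the uncollimated one", {
  m <- fixture_model()
  pc <- toy_plan(m, collimated = TRUE)
  pu <- toy_plan(m, collimated = FALSE)
  # halo excluded for the pure-collimation comparison
  m0 <- fixture_model(trimmer_halo_weight = 0)
  grid <- toy_grid(pc, m0)
  set.seed(11)
  w <- runif(nrow(pc$spots)) * 1e7
  dc <- compute_dose(pc, m0, grid, weights = w)
  du <- compute_dose(pu, m0, grid, weights = w)
  expect_true(all(dc$values <= du$values * (1 + 1e-12) + 1e-18))
})

test_that("dose grids and planes survive a text round trip", {
  g <- dose_grid(c(-2, -2, 0.5), 1, c(5, 5, 4),
                 array(runif(100), dim = c(5, 5, 4)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_dose_grid(g, path)
  g2 <- read_dose_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$origin_mm, g$origin_mm)
  pl <- dose_plane(seq(-3, 3), seq(-2, 2), matrix(runif(35), 7, 5))
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_plane(pl, path2)
  pl2 <- read_plane(path2)
  expect_equal(pl2$values, pl$values, tolerance = 1e-9)
  expect_equal(pl2$y_mm, pl$y_mm)
})

test_that("beam model configuration round trips and rejects unknown keys", {
  m <- fixture_model(trimmer_halo_weight = 0.05)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_beam_model(m, path)
  m2 <- read_beam_model(path)
  expect_equal(m2$trimmer_halo_weight, 0.05)
  expect_equal(m2$sigma_air_table, m$sigma_air_table)
  writeLines(c(readLines(path), "mystery_knob: 3"), path)
  expect_error(read_beam_model(path), "unknown beam model keys")
})
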