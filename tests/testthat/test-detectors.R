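# Detector simulators: chamber-array volume averaging with shifted-merge
# sampling, film-like resampling with noise, multilayer chamber depth dose,
# and setup perturbations.

edge_plane <- function(sigma_mm, step = 1, half = 30) {
  x <- seq(-half, half, by = step)
  v <- outer(pnorm((15 - x) / sigma_mm) * pnorm((x + 15) / sigma_mm),
             pnorm((15 - x) / sigma_mm) * pnorm((x + 15) / sigma_mm))
  dose_plane(x, x, v)
}

test_that("a flat field passes through the chamber array unchanged", {
  x <- seq(-30, 30)
  pl <- dose_plane(x, x, matrix(2.5, length(x), length(x)))
  out <- simulate_matrixx(pl)
  expect_equal(as.vector(out$values), rep(2.5, length(out$values)),
               tolerance = 1e-9)
  tiny <- dose_plane(seq(-3, 3), seq(-3, 3), matrix(1, 7, 7))
  expect_error(simulate_matrixx(tiny), "pitch")
})

test_that("the disc kernel matches a brute-force area-integration oracle", {
  r <- matrixx_model()$disc_radius_mm
  k <- dcpt:::disc_kernel(r, 1)
  # oracle: fraction of each 1 mm pixel inside the disc by dense sampling
  half <- (nrow(k) - 1) / 2
  offs <- seq(-0.4995, 0.4995, by = 0.001)
  oracle <- matrix(0, nrow(k), ncol(k))
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      cx <- i - half - 1; cy <- j - half - 1
      oracle[i, j] <- mean(outer((cx + offs)^2, (cy + offs)^2, `+`) <= r^2)
    }
  }
  oracle <- oracle / sum(oracle)
  expect_lt(max(abs(k - oracle)), 1e-4)
  # step response of the convolution against direct integration
  x <- seq(-20, 20)
  step_pl <- dose_plane(x, x, outer(as.numeric(x <= 0), rep(1, length(x))))
  conv <- dcpt:::convolve2d(step_pl$values, k)
  oracle_step <- vapply(x, function(xc) {
    pix_x <- outer(xc + (-half:half), rep(1, 2 * half + 1))
    sum(oracle * (pix_x <= 0))
  }, numeric(1))
  expect_lt(max(abs(conv[, 21] - oracle_step)), 2e-3)
})

test_that("volume averaging widens penumbras, more so for sharp edges", {
  widths <- vapply(c(1.2, 2.2, 3.5), function(sig) {
    pl <- edge_plane(sig)
    true_w <- penumbra_80_20(extract_profile(pl, "x", at_mm = 0), "right")
    meas <- simulate_matrixx(pl)
    meas_w <- penumbra_80_20(extract_profile(meas, "x", at_mm = 0), "right")
    c(true_w, meas_w)
  }, numeric(2))
  expect_true(all(widths[2, ] >= widths[1, ]))           # never narrows
  widening <- widths[2, ] - widths[1, ]
  expect_true(all(diff(widening) < 0))  # discrepancy grows as edges sharpen
})

test_that("chamber-array signal is conserved for pitch-resolvable fields", {
  # a broad smooth field the 7.6 mm lattice can resolve: the kernel is
  # normalized and the merge/interpolation must preserve the mean signal
  x <- seq(-30, 30)
  pl <- dose_plane(x, x, outer(dnorm(x, 0, 12), dnorm(x, 1, 12)) / dnorm(0)^2)
  out <- simulate_matrixx(pl)
  sel_in <- abs(pl$x_mm) <= max(out$x_mm)
  m_in <- mean(pl$values[sel_in, sel_in])
  expect_equal(mean(out$values), m_in, tolerance = 0.01)
})

test_that("film simulation is exact at zero noise and unbiased with noise", {
  pl <- edge_plane(2, step = 1, half = 20)
  out0 <- simulate_film(pl, film_model(pixel_pitch_mm = 0.5, noise_sd = 0))
  expect_equal(out0$values[out0$x_mm == 0.5, out0$y_mm == 0.5],
               dcpt:::interp_plane(pl, 0.5, 0.5), tolerance = 1e-12)
  on_lattice <- out0$values[match(pl$x_mm, out0$x_mm),
                            match(pl$y_mm, out0$y_mm)]
  expect_equal(on_lattice, pl$values, tolerance = 1e-12)
  # seeded ensemble mean converges to the noiseless resample
  fm <- film_model(pixel_pitch_mm = 1, noise_sd = 0.01)
  ref <- simulate_film(pl, film_model(pixel_pitch_mm = 1, noise_sd = 0), 1)
  acc <- 0
  for (s in 1:100) acc <- acc + simulate_film(pl, fm, seed = s)$values
  expect_lt(mean(abs(acc / 100 - ref$values)) / max(pl$values), 0.002)
})

test_that("film preserves penumbra to sub-voxel accuracy", {
  pl <- edge_plane(1.3, step = 0.5, half = 25)
  true_w <- penumbra_80_20(extract_profile(pl, "x", at_mm = 0), "right")
  f <- simulate_film(pl, film_model(pixel_pitch_mm = 0.3, noise_sd = 0), 1)
  film_w <- penumbra_80_20(extract_profile(f, "x", at_mm = 0), "right")
  expect_lt(abs(film_w - true_w), 0.2)
})

test_that("the multilayer chamber recovers depth-dose structure", {
  m <- fixture_model()
  # separable field narrower than the aperture: output proportional to the
  # central-axis depth dose
  g <- dose_grid(c(-20, -20, 0.5), 1, c(41, 41, 60))
  co <- grid_coords(g)
  lat <- outer(dnorm(co$x, 0, 3), dnorm(co$y, 0, 3))
  dd <- bragg_depth_dose(80, co$z / 10, m)
  for (k in seq_along(co$z)) g$values[, , k] <- lat * dd[k]
  zp <- simulate_zebra(g)
  expect_equal(zp$position_mm[2] - zp$position_mm[1], 2)
  axis_dd <- dd[match(zp$position_mm, co$z)]
  sel <- axis_dd > 1e-3 * max(dd)
  ratio <- zp$value[sel] / axis_dd[sel]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  # rectangular SOBP width recovered within one 2 mm sample
  g2 <- g
  sob <- ifelse(co$z >= 20 & co$z <= 45, 1, ifelse(co$z < 20, 0.4, 0))
  for (k in seq_along(co$z)) g2$values[, , k] <- lat * sob[k]
  sm <- sobp_metrics(simulate_zebra(g2))
  expect_equal(sm$width_cm, 2.5, tolerance = 0.2)
  narrow <- dose_grid(c(-5, -5, 0.5), 1, c(11, 11, 20))
  expect_error(simulate_zebra(narrow), "aperture")
})

test_that("setup perturbations compose and invert", {
  pl <- edge_plane(2, step = 1, half = 25)
  expect_equal(perturb_setup(pl, 0, c(0, 0))$values, pl$values,
               tolerance = 1e-12)
  # two successive perturbations compose as a single rigid transform
  a <- perturb_setup(perturb_setup(pl, 0, c(2, 0)), 0, c(1, -1))
  b <- perturb_setup(pl, 0, c(3, -1))
  interior <- abs(pl$x_mm) <= 18
  expect_lt(max(abs(a$values[interior, interior] -
                      b$values[interior, interior])), 1e-9)
  expect_warning(perturb_setup(pl, 5, c(0, 0)), "search window")
})
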