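# Profile extraction, penumbra, SOBP metrics, gamma analysis,
# surface-enhancement report and rigid registration.

test_that("profile extraction interpolates linearly and preserves integrals", {
  x <- seq(-10, 10); y <- seq(-8, 8)
  pl <- dose_plane(x, y, outer(dnorm(x, 0, 3), dnorm(y, 1, 2)))
  p <- extract_profile(pl, "x", at_mm = 1)
  expect_equal(p$value, dnorm(x, 0, 3) * dnorm(1, 1, 2), tolerance = 1e-6)
  # off-lattice position on a linear field is the mean of the neighbours
  lin <- dose_plane(x, y, outer(x, y, function(a, b) 2 * a + b))
  p2 <- extract_profile(lin, "y", at_mm = 0.5)
  expect_equal(p2$value, 2 * 0.5 + y, tolerance = 1e-12)
  # resampling to half-step changes the integral by < 0.1%
  p3 <- extract_profile(pl, "x", at_mm = 1, step_mm = 0.5)
  expect_equal(sum(p$value) * 1, sum(p3$value) * 0.5, tolerance = 1e-3)
  expect_error(extract_profile(pl, "x", at_mm = 50), "outside")
})

test_that("penumbra of analytic edges matches closed forms", {
  # error-function edge: 1.6832 sigma to 0.1%
  p <- erf_edge_profile(2, step_mm = 0.02)
  expect_equal(penumbra_80_20(p, "right"), 3.3664, tolerance = 1e-3)
  expect_equal(penumbra_80_20(p, "right", normalization = "max"),
               3.3664, tolerance = 1e-3)
  # linear ramp over L = 10 mm: 80-20 width is 0.6 L
  x <- seq(-30, 30, by = 0.1)
  v <- pmin(pmax((10 - x) / 10, 0), 1)
  ramp <- dose_profile(x, v)
  expect_equal(penumbra_80_20(ramp, "right", normalization = "max"), 6,
               tolerance = 1e-6)
  # left and right sides agree for a symmetric field
  sym <- dose_profile(x, pnorm((x + 12) / 1.5) * pnorm((12 - x) / 1.5))
  expect_equal(penumbra_80_20(sym, "left"), penumbra_80_20(sym, "right"),
               tolerance = 1e-9)
  flat <- dose_profile(x, rep(1, length(x)))
  expect_error(penumbra_80_20(flat, "right"), "plateau|20%")
})

test_that("edge horns do not fool the penumbra search", {
  # plateau with a horn just inside a sharp edge: the width must measure
  # the outer falloff, not the horn's inner slope
  x <- seq(-30, 30, by = 0.25)
  v <- pnorm((15 - x) / 0.6) * pnorm((x + 15) / 0.6) +
    1.2 * dnorm(x, 13, 1.2) + 1.2 * dnorm(x, -13, 1.2)
  p <- dose_profile(x, v)
  w <- penumbra_80_20(p, "right")
  expect_lt(w, 2.5)
})

test_that("SOBP metrics recover rectangular and tilted plateaus", {
  z <- seq(0.5, 120.5, by = 1)
  rect <- ifelse(z >= 45 & z <= 75, 1, ifelse(z < 45, 0.3, 0))
  # soften the distal cliff over one sample for the interpolation
  p <- dose_profile(z, rect)
  sm <- sobp_metrics(p)
  expect_equal(sm$range_cm, 7.5, tolerance = 0.1)
  expect_equal(sm$width_cm, 3.0, tolerance = 0.15)
  expect_lt(sm$flatness, 1e-9)
  # +1% linear tilt across the plateau gives the closed-form flatness
  tilt <- rect * (1 + 0.01 * (z - 45) / 30)
  sm2 <- sobp_metrics(dose_profile(z, tilt))
  expect_equal(sm2$flatness, 0.01 / (2 + 0.01), tolerance = 0.05)
  expect_error(sobp_metrics(dose_profile(z[1:2], c(0, 0))), "plateau|90%")
})

test_that("gamma analysis passes identity and uniform-rescale cases", {
  x <- seq(-20, 20, by = 1.5)
  pl <- dose_plane(x, x, outer(pnorm((12 - abs(x)) / 3),
                               pnorm((12 - abs(x)) / 3)))
  g <- gamma_2d(pl, pl)
  expect_equal(g$pass_rate_pct, 100)
  resc <- pl
  resc$values <- pl$values * 1.019
  g2 <- gamma_2d(pl, resc, norm_value = max(resc$values))
  expect_equal(g2$pass_rate_pct, 100)
  expect_error(gamma_2d(pl, dose_plane(x, x, pl$values * 0 + 1e-9),
                        norm_value = 1),
               "no evaluable")
})

test_that("gamma on a shifted edge matches a brute-force oracle and fails symmetry", {
  x <- seq(-24, 24, by = 2)
  edge <- function(x0) outer(pnorm((x0 - x) / 3), rep(1, length(x)))
  ref <- dose_plane(x, x, edge(8))
  ev <- dose_plane(x, x, edge(3))   # 5 mm rigid shift
  crit <- gamma_criteria()
  g <- gamma_2d(ref, ev, crit, norm_value = 1)
  expect_lt(g$pass_rate_pct, 100)
  # exhaustive-search oracle on a 0.1 mm lattice
  fine <- seq(-24, 24, by = 0.1)
  fref <- outer(fine, fine, function(a, b) {
    dcpt:::interp_plane(ref, a, b)
  })
  oracle_gamma <- function(xe, ye, de) {
    keep <- abs(fine - xe) <= 8
    keepy <- abs(fine - ye) <= 8
    dd2 <- (fref[keep, keepy] - de)^2 / 0.02^2
    dist2 <- outer((fine[keep] - xe)^2, (fine[keepy] - ye)^2, `+`) / 2^2
    sqrt(min(dd2 + dist2))
  }
  pass <- 0; n <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      de <- ev$values[i, j]
      if (de < 0.05) next
      n <- n + 1
      if (oracle_gamma(x[i], x[j], de) <= 1) pass <- pass + 1
    }
  }
  expect_equal(g$pass_rate_pct, 100 * pass / n, tolerance = 0.01)
  # thresholding breaks reference/evaluated symmetry
  g_swapped <- gamma_2d(ev, ref, crit, norm_value = 1)
  expect_false(isTRUE(all.equal(g$pass_rate_pct, g_swapped$pass_rate_pct)))
})

test_that("surface enhancement reports constructed horns exactly", {
  ptv <- ptv_spec(side_mm = 30, center_depth_cm = 6)
  g <- dose_grid(c(-25, -25, 0.5), 1, c(51, 51, 12))
  co <- grid_coords(g)
  base <- 3 * outer(pnorm(16 - abs(co$x)), pnorm(16 - abs(co$y)))
  for (k in seq_len(12)) g$values[, , k] <- base
  # collimated copy: +3%-of-prescription bumps at the four horn points
  # (x = +/-12 on the y = 0 profile, y = +/-12 on the x = 0 profile)
  gc <- g
  bump <- 0.15
  vals <- gc$values
  for (k in seq_len(12)) {
    sl <- vals[, , k]
    sl[, co$y == 0] <- sl[, co$y == 0] +
      bump * (exp(-(co$x - 12)^2 / 2) + exp(-(co$x + 12)^2 / 2))
    sl[co$x == 0, ] <- sl[co$x == 0, ] +
      bump * (exp(-(co$y - 12)^2 / 2) + exp(-(co$y + 12)^2 / 2))
    vals[, , k] <- sl
  }
  gc$values <- vals
  rep_ <- surface_enhancement(g, gc, ptv, prescription_gy = 5, depth_mm = 5)
  expect_equal(rep_$enhancement_pct, 3, tolerance = 0.2)
  expect_equal(rep_$enhancement_sd,
               sqrt(rep_$uncollimated_sd^2 + rep_$collimated_sd^2),
               tolerance = 1e-9)
  # identical grids: zero enhancement
  rep0 <- surface_enhancement(g, g, ptv, prescription_gy = 5)
  expect_equal(rep0$enhancement_pct, 0)
  expect_equal(rep0$enhancement_sd, 0)
  shallow <- dose_grid(c(-25, -25, 8.5), 1, c(51, 51, 4))
  expect_error(surface_enhancement(shallow, shallow, ptv), "depth")
})

test_that("rigid registration recovers applied transforms", {
  x <- seq(-24, 24)
  blob <- outer(pnorm((12 - abs(x)) / 2), pnorm((10 - abs(x)) / 2)) +
    0.3 * outer(dnorm(x, 5, 3), dnorm(x, -4, 3)) / dnorm(0)^2 +
    0.2 * outer(dnorm(x, -7, 2.5), dnorm(x, 6, 2.5)) / dnorm(0)^2
  pl <- dose_plane(x, x, blob)
  reg0 <- register_2d(pl, pl)
  expect_lt(abs(reg0$rotation_deg), 0.05)
  expect_lt(abs(reg0$shift_x_mm), 0.05)
  pert <- perturb_setup(pl, rotation_deg = 1.0, shift_mm = c(2, -1.5))
  reg <- register_2d(pert, pl)
  expect_equal(reg$rotation_deg, 1.0, tolerance = 0.1)
  expect_equal(reg$shift_x_mm, 2.0, tolerance = 0.1)
  expect_equal(reg$shift_y_mm, -1.5, tolerance = 0.1)
  # unchanged under 1% multiplicative dose noise
  pert_n <- perturb_setup(pl, rotation_deg = 1.0, shift_mm = c(2, -1.5),
                          noise_sd = 0.01, seed = 7)
  reg_n <- register_2d(pert_n, pl)
  expect_equal(reg_n$shift_x_mm, reg$shift_x_mm, tolerance = 0.1)
  expect_equal(reg_n$rotation_deg, reg$rotation_deg, tolerance = 0.1)
})

test_that("registration shift recovery is unbiased over random transforms", {
  x <- seq(-21, 21, by = 3)
  blob <- outer(pnorm((12 - abs(x)) / 2.5), pnorm((10 - abs(x)) / 2.5)) +
    0.2 * outer(dnorm(x, 4, 4), dnorm(x, -5, 4)) / dnorm(0)^2
  pl <- dose_plane(x, x, blob)
  set.seed(2024)
  err <- t(vapply(1:100, function(i) {
    tr <- c(runif(1, -1.5, 1.5), runif(1, -4, 4), runif(1, -4, 4))
    pert <- perturb_setup(pl, tr[1], tr[2:3])
    reg <- register_2d(pert, pl, rotation_window_deg = 2,
                       shift_window_mm = 5)
    c(reg$shift_x_mm - tr[2], reg$shift_y_mm - tr[3])
  }, numeric(2)))
  expect_lt(abs(mean(err[, 1])), 0.05)
  expect_lt(abs(mean(err[, 2])), 0.05)
})
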