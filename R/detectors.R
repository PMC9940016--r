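# Synthetic measurement stage: simulators for the three dosimeters used to
# validate collimated deliveries (2D ionization-chamber array with
# shifted-merge acquisition, radiochromic-film-like high-resolution planar
# sampling, multilayer ionization chamber depth dose), plus rigid setup
# perturbations. Simulated measurements are written in the same plane and
# profile formats as engine output, so the analysis stage is agnostic to
# real versus simulated provenance.

#' Ionization-chamber array model (MatriXX-like)
#'
#' 2D array of vented parallel-plate chambers on a square pitch. The
#' effective resolution is doubled by merging a second acquisition shifted
#' by half a pitch in both directions; the merged samples are interpolated
#' to a fine output grid. The chamber sensitive volume is modelled as a
#' uniform disc whose radius follows from the active volume and chamber
#' height as `sqrt(V / (pi h))`.
#'
#' @param pitch_mm Center-to-center chamber spacing (mm).
#' @param chamber_volume_mm3 Active volume per chamber (mm^3).
#' @param chamber_height_mm Plate separation (mm).
#' @param shift_mm Shift of the merged second acquisition (mm; half pitch).
#' @param output_spacing_mm Interpolated output grid spacing (mm).
#' @return A list of class `dcpt_matrixx_model` (includes the derived
#'   `disc_radius_mm`).
#' @export
matrixx_model <- function(pitch_mm = 7.6, chamber_volume_mm3 = 32,
                          chamber_height_mm = 2, shift_mm = pitch_mm / 2,
                          output_spacing_mm = 1.5) {
  r <- sqrt(chamber_volume_mm3 / (pi * chamber_height_mm))
  if (pitch_mm <= 2 * r) {
    stop("chamber discs overlap: pitch must exceed the disc diameter",
         call. = FALSE)
  }
  structure(list(pitch_mm = pitch_mm,
                 chamber_volume_mm3 = chamber_volume_mm3,
                 chamber_height_mm = chamber_height_mm,
                 disc_radius_mm = r, shift_mm = shift_mm,
                 output_spacing_mm = output_spacing_mm),
            class = "dcpt_matrixx_model")
}

# Uniform-disc convolution kernel discretized on the plane lattice; pixel
# weights are the disc indicator averaged over nsub x nsub sub-pixels.
disc_kernel <- function(radius_mm, spacing_mm, nsub = 64L) {
  half <- ceiling(radius_mm / spacing_mm) + 1L
  offs <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * spacing_mm
  k <- matrix(0, 2 * half + 1, 2 * half + 1)
  for (i in seq_len(2 * half + 1)) {
    for (j in seq_len(2 * half + 1)) {
      cx <- (i - half - 1) * spacing_mm
      cy <- (j - half - 1) * spacing_mm
      sub <- outer(cx + offs, cy + offs, function(a, b) a^2 + b^2)
      k[i, j] <- mean(sub <= radius_mm^2)
    }
  }
  k / sum(k)
}

# 2D convolution with edge replication (keeps a flat field flat).
convolve2d <- function(values, kernel) {
  kh <- (nrow(kernel) - 1) / 2
  nx <- nrow(values); ny <- ncol(values)
  pad <- function(idx, n) pmin(pmax(idx, 1), n)
  out <- matrix(0, nx, ny)
  for (di in -kh:kh) {
    for (dj in -kh:kh) {
      w <- kernel[di + kh + 1, dj + kh + 1]
      if (w == 0) next
      out <- out + w * values[pad(seq_len(nx) + di, nx),
                              pad(seq_len(ny) + dj, ny)]
    }
  }
  out
}

#' Simulate an ionization-chamber array measurement
#'
#' Convolves the input plane with the uniform-disc chamber kernel, samples
#' it on the chamber lattice twice (nominal and half-pitch-shifted), merges
#' the two acquisitions and interpolates to the fine output grid. The
#' merged quincunx lattice becomes a regular square lattice in the frame
#' rotated 45 degrees, where bilinear interpolation is well defined.
#' Volume averaging widens penumbras; it can never narrow them.
#'
#' @param plane A [dose_plane()] with spacing at or below 1 mm.
#' @param model A [matrixx_model()].
#' @return A [dose_plane()] on the output grid (restricted to the region
#'   covered by the merged samples).
#' @export
simulate_matrixx <- function(plane, model = matrixx_model()) {
  sp <- plane$x_mm[2] - plane$x_mm[1]
  if (sp > 1 + 1e-9) stop("input plane must be at or below 1 mm resolution",
                          call. = FALSE)
  if (diff(range(plane$x_mm)) < model$pitch_mm ||
      diff(range(plane$y_mm)) < model$pitch_mm) {
    stop("plane smaller than one chamber pitch", call. = FALSE)
  }
  conv <- dose_plane(plane$x_mm, plane$y_mm,
                     convolve2d(plane$values, disc_kernel(model$disc_radius_mm, sp)))
  # chamber positions: nominal lattice centred on the axis + shifted lattice
  p <- model$pitch_mm
  s <- model$shift_mm
  kx <- seq(ceiling((min(plane$x_mm) + s) / p), floor((max(plane$x_mm) - s) / p))
  ky <- seq(ceiling((min(plane$y_mm) + s) / p), floor((max(plane$y_mm) - s) / p))
  # rotated-frame integer coordinates: u = x + y, v = x - y (units of pitch)
  # nominal chambers (i p, j p) -> (i + j, i - j): u+v even;
  # shifted (i p + s, j p + s) -> (i + j + 1, i - j): u+v odd. Union = all
  # integer (u, v) with x, y inside the sampled area.
  if (abs(model$shift_mm - p / 2) > 1e-9) {
    stop("shifted-merge sampling requires a half-pitch shift", call. = FALSE)
  }
  uv <- tidyr::expand_grid(u = seq(min(kx) + min(ky), max(kx) + max(ky)),
                           v = seq(min(kx) - max(ky), max(kx) - min(ky)))
  uv$x <- (uv$u + uv$v) / 2 * p
  uv$y <- (uv$u - uv$v) / 2 * p
  keep <- uv$x >= min(plane$x_mm) & uv$x <= max(plane$x_mm) &
    uv$y >= min(plane$y_mm) & uv$y <= max(plane$y_mm)
  uv <- uv[keep, ]
  uv$value <- interp_plane(conv, uv$x, uv$y)
  # bilinear interpolation on the regular (u, v) lattice
  us <- sort(unique(uv$u)); vs <- sort(unique(uv$v))
  zm <- matrix(NA_real_, length(us), length(vs))
  zm[cbind(match(uv$u, us), match(uv$v, vs))] <- uv$value
  uvplane <- dose_plane(us, vs, zm)
  out_sp <- model$output_spacing_mm
  # output region: half a pitch in from the sampled hull (rotated-frame
  # corner nodes outside the hull fall back to the nearest sample)
  margin <- p / 2
  ox <- seq(ceiling((min(uv$x) + margin) / out_sp) * out_sp,
            floor((max(uv$x) - margin) / out_sp) * out_sp, by = out_sp)
  oy <- seq(ceiling((min(uv$y) + margin) / out_sp) * out_sp,
            floor((max(uv$y) - margin) / out_sp) * out_sp, by = out_sp)
  og <- tidyr::expand_grid(y = oy, x = ox)
  vals <- interp_plane(uvplane, (og$x + og$y) / p, (og$x - og$y) / p)
  if (anyNA(vals)) {
    # corner nodes of the rotated lattice outside the cartesian hull:
    # fall back to the nearest valid node value
    miss <- which(is.na(vals))
    for (m in miss) {
      d2 <- (uv$x - og$x[m])^2 + (uv$y - og$y[m])^2
      vals[m] <- uv$value[which.min(d2)]
    }
  }
  dose_plane(ox, oy, matrix(vals, length(ox)))
}

#' Film-like detector model
#'
#' High-resolution planar detector used for relative dosimetry: the dose
#' plane is resampled to the pixel pitch and multiplicative Gaussian noise
#' is applied. Quenching is off by default (relative use only).
#'
#' @param pixel_pitch_mm Pixel spacing (mm).
#' @param noise_sd Multiplicative noise sigma (fraction; 0.01 = 1%).
#' @return A list of class `dcpt_film_model`.
#' @export
film_model <- function(pixel_pitch_mm = 0.3, noise_sd = 0.01) {
  stopifnot(pixel_pitch_mm > 0, noise_sd >= 0)
  structure(list(pixel_pitch_mm = pixel_pitch_mm, noise_sd = noise_sd),
            class = "dcpt_film_model")
}

#' Simulate a film measurement
#'
#' Bilinear resampling to the pixel pitch followed by seeded multiplicative
#' Gaussian noise. The expectation over seeds equals the resampled input
#' (the simulator is unbiased).
#'
#' @param plane A [dose_plane()].
#' @param model A [film_model()].
#' @param seed Integer RNG seed for the noise.
#' @return A [dose_plane()] on the pixel lattice.
#' @export
simulate_film <- function(plane, model = film_model(), seed = 1) {
  px <- seq(min(plane$x_mm), max(plane$x_mm), by = model$pixel_pitch_mm)
  py <- seq(min(plane$y_mm), max(plane$y_mm), by = model$pixel_pitch_mm)
  og <- tidyr::expand_grid(y = py, x = px)
  vals <- interp_plane(plane, og$x, og$y)
  if (model$noise_sd > 0) {
    vals <- withr::with_seed(seed,
      vals * (1 + stats::rnorm(length(vals), 0, model$noise_sd)))
  }
  dose_plane(px, py, matrix(vals, length(px)))
}

#' Multilayer ionization chamber model (Zebra-like)
#'
#' Stack of parallel-plate chambers measuring depth dose in one shot; each
#' chamber integrates laterally over a circular aperture.
#'
#' @param n_channels Number of chambers.
#' @param depth_resolution_mm Effective sampling step along the beam axis.
#' @param aperture_diameter_mm Lateral aperture (mm).
#' @return A list of class `dcpt_zebra_model`.
#' @export
zebra_model <- function(n_channels = 180, depth_resolution_mm = 2,
                        aperture_diameter_mm = 25) {
  structure(list(n_channels = n_channels,
                 depth_resolution_mm = depth_resolution_mm,
                 aperture_diameter_mm = aperture_diameter_mm),
            class = "dcpt_zebra_model")
}

#' Simulate a multilayer ionization chamber depth-dose measurement
#'
#' Integrates the dose laterally over the circular aperture at every grid
#' depth, then samples the resulting curve every `depth_resolution_mm`.
#'
#' @param dose A [dose_grid()] covering the depth span of interest.
#' @param model A [zebra_model()].
#' @return A [dose_profile()] along z (arbitrary integral units).
#' @export
simulate_zebra <- function(dose, model = zebra_model()) {
  co <- grid_coords(dose)
  r <- model$aperture_diameter_mm / 2
  if (max(abs(co$x)) < r || max(abs(co$y)) < r) {
    stop("aperture extends outside the dose grid", call. = FALSE)
  }
  inside <- outer(co$x, co$y, function(x, y) x^2 + y^2 <= r^2)
  raw <- vapply(seq_along(co$z),
                function(k) sum(dose$values[, , k][inside]),
                numeric(1))
  n_max <- min(model$n_channels,
               floor((max(co$z) - co$z[1]) / model$depth_resolution_mm) + 1)
  zq <- co$z[1] + (seq_len(n_max) - 1) * model$depth_resolution_mm
  vals <- stats::approx(co$z, raw, xout = zq)$y
  dose_profile(zq, vals, axis = "z")
}

#' Apply a rigid setup perturbation to a measured plane
#'
#' Resamples the plane under a rotation about the beam axis plus a lateral
#' shift (bilinear interpolation; points leaving the field of view take the
#' nearest-edge value). The perturbation is the inverse operation of
#' [register_2d()]: registering a perturbed plane against the original
#' recovers the transform.
#'
#' @param plane A [dose_plane()].
#' @param rotation_deg Rotation (degrees, counter-clockwise).
#' @param shift_mm Length-2 lateral shift (mm).
#' @param noise_sd Optional multiplicative noise sigma applied after the
#'   transform.
#' @param seed RNG seed for the optional noise.
#' @return A [dose_plane()] on the original lattice.
#' @export
perturb_setup <- function(plane, rotation_deg = 0, shift_mm = c(0, 0),
                          noise_sd = 0, seed = 1) {
  if (abs(rotation_deg) > 3 || any(abs(shift_mm) > 10)) {
    warning("perturbation outside the registration search window",
            call. = FALSE)
  }
  xg <- matrix(plane$x_mm, length(plane$x_mm), length(plane$y_mm))
  yg <- matrix(plane$y_mm, length(plane$x_mm), length(plane$y_mm),
               byrow = TRUE)
  th <- -rotation_deg * pi / 180
  xq <- cos(th) * (xg - shift_mm[1]) - sin(th) * (yg - shift_mm[2])
  yq <- sin(th) * (xg - shift_mm[1]) + cos(th) * (yg - shift_mm[2])
  xq <- pmin(pmax(xq, min(plane$x_mm)), max(plane$x_mm))
  yq <- pmin(pmax(yq, min(plane$y_mm)), max(plane$y_mm))
  vals <- interp_plane(plane, as.vector(xq), as.vector(yq))
  if (noise_sd > 0) {
    vals <- withr::with_seed(seed,
      vals * (1 + stats::rnorm(length(vals), 0, noise_sd)))
  }
  dose_plane(plane$x_mm, plane$y_mm, matrix(vals, length(plane$x_mm)))
}
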