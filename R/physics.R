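# Analytical single-beamlet physics: range-energy power law, Bragg depth
# dose with range straggling, Highland multiple Coulomb scattering, and the
# range-shifter angular scatter model.

PROTON_MASS_MEV <- 938.272
WATER_X0_CM <- 36.08          # radiation length of water, cm
PE_X0_CM <- 44.77 / 0.94      # polyethylene: 44.77 g/cm^2 at 0.94 g/cm^3
# Gy per (MeV/mm stopping power) per (1/mm^2 planar fluence density) in water
DOSE_PER_PROTON_GY <- 1.602e-7

# Effective Gaussian range spread (cm): straggling plus the range-projected
# beam energy spread, in quadrature.
range_sigma_cm <- function(energy_mev, model) {
  R <- range_from_energy(energy_mev, model)
  sqrt((model$straggling_coeff * R^0.935)^2 +
         (model$p * R * (model$energy_spread_frac %||% 0))^2)
}

pv_mev <- function(energy_mev) {
  energy_mev * (energy_mev + 2 * PROTON_MASS_MEV) /
    (energy_mev + PROTON_MASS_MEV)
}

#' Water-equivalent range from beam energy
#'
#' Power law `R = alpha * E^p` with the model constants.
#'
#' @param energy_mev Beam energy (MeV), positive.
#' @param model A [beam_model()].
#' @return Range in cm of water; strictly increasing in energy.
#' @export
range_from_energy <- function(energy_mev, model) {
  if (any(energy_mev <= 0)) stop("energy must be positive", call. = FALSE)
  model$alpha * energy_mev^model$p
}

#' Beam energy from water-equivalent range
#'
#' Inverse of [range_from_energy()]: `E = (R / alpha)^(1/p)`.
#'
#' @param range_cm Water-equivalent range (cm), positive.
#' @param model A [beam_model()].
#' @return Energy in MeV.
#' @export
energy_from_range <- function(range_cm, model) {
  if (any(range_cm <= 0)) stop("range must be positive", call. = FALSE)
  (range_cm / model$alpha)^(1 / model$p)
}

#' Lateral spread in water from multiple Coulomb scattering
#'
#' Highland scattering accumulated over the slowing-down trajectory:
#' `sigma^2(z) = (14.1/X0) * f^2 * int_0^z (z-u)^2 / pv(u)^2 du` with the
#' logarithmic correction `f = 1 + 0.038 ln(z/X0)` evaluated on the total
#' path. The integral is evaluated by trapezoidal quadrature on a 0.5 mm
#' step (refined automatically for very shallow depths).
#'
#' @param energy_mev Beam energy at the water surface (MeV).
#' @param depth_cm Water depth (cm), in `[0, range]`.
#' @param model A [beam_model()].
#' @return Lateral sigma (mm); zero at the surface, strictly increasing.
#' @export
mcs_sigma <- function(energy_mev, depth_cm, model) {
  R <- range_from_energy(energy_mev, model)
  if (any(depth_cm < 0) || any(depth_cm > R + 1e-9)) {
    stop("depth must lie within [0, range]", call. = FALSE)
  }
  vapply(depth_cm, function(z) {
    if (z <= 0) return(0)
    n <- max(64L, ceiling(z / 0.05) + 1L)
    u <- seq(0, z, length.out = n)
    resid <- pmax(R - u, 1e-9)
    Eu <- energy_from_range(resid, model)
    integrand <- (z - u)^2 / pv_mev(Eu)^2
    I <- sum((integrand[-1] + integrand[-n]) / 2) * (u[2] - u[1])
    f <- 1 + 0.038 * log(z / WATER_X0_CM)
    10 * sqrt(14.1^2 * f^2 * I / WATER_X0_CM)
  }, numeric(1))
}

#' Analytical Bragg depth-dose curve
#'
#' Mass stopping power of the power-law range-energy relation,
#' `S(r) = dE/dr` at residual range `r`, convolved with a Gaussian range
#' kernel combining straggling (`c * R^0.935`, cm) with the range-projected
#' beam energy spread of the delivery system. The returned values
#' are the expected stopping power (MeV/cm) at each depth, i.e. dose per
#' proton per unit planar fluence up to a constant.
#'
#' @param energy_mev Beam energy (MeV).
#' @param depth_cm Water depths (cm), nonnegative; may be a vector.
#' @param model A [beam_model()].
#' @return Expected stopping power (MeV/cm) at each depth; nonnegative, with
#'   a single global maximum just proximal to the nominal range and zero
#'   beyond `R + 4 sigma`.
#' @export
bragg_depth_dose <- function(energy_mev, depth_cm, model) {
  if (any(depth_cm < 0)) stop("depth must be nonnegative", call. = FALSE)
  R <- range_from_energy(energy_mev, model)
  sig <- range_sigma_cm(energy_mev, model)
  p <- model$p
  # E[S(R' - z)] over R' ~ N(R, sig), S(r) = r^(1/p - 1) / (p alpha^(1/p))
  vapply(depth_cm, function(z) {
    if (z > R + 4 * sig) return(0)
    lo <- max(z, R - 5 * sig)
    hi <- R + 5 * sig
    r <- seq(lo, hi, length.out = 257L)
    resid <- pmax(r - z, 1e-12)
    S <- resid^(1 / p - 1) / (p * model$alpha^(1 / p))
    w <- stats::dnorm(r, R, sig)
    f <- S * w
    sum((f[-1] + f[-length(f)]) / 2) * (r[2] - r[1])
  }, numeric(1))
}

#' Angular scatter induced by the range shifter
#'
#' Highland angle accumulated through the polyethylene slab, with the energy
#' degraded linearly in water-equivalent depth across the slab. Optionally
#' reports the halo parameters that the engine attaches to trimmer-edge
#' scatter (configuration on the [beam_model()]).
#'
#' @param energy_mev Beam energy entering the shifter (MeV); must retain a
#'   positive residual range after the slab.
#' @param model A [beam_model()].
#' @return A tibble with columns `theta_mrad` (Gaussian angular sigma),
#'   `halo_weight` and `halo_sigma_scale`.
#' @export
range_shifter_scatter <- function(energy_mev, model) {
  R <- range_from_energy(energy_mev, model)
  if (any(R - model$rs_wet_cm <= 0)) {
    stop("residual range after the range shifter must be positive",
         call. = FALSE)
  }
  theta <- vapply(energy_mev, function(E) {
    R1 <- range_from_energy(E, model)
    t_cm <- model$rs_thickness_cm
    n <- 512L
    u <- seq(0, t_cm, length.out = n)
    wet <- model$rs_wet_cm * u / t_cm
    Eu <- energy_from_range(pmax(R1 - wet, 1e-9), model)
    integrand <- 1 / pv_mev(Eu)^2
    I <- sum((integrand[-1] + integrand[-n]) / 2) * (u[2] - u[1])
    f <- 1 + 0.038 * log(t_cm / PE_X0_CM)
    1000 * sqrt(14.1^2 * f^2 * I / PE_X0_CM)
  }, numeric(1))
  tibble::tibble(
    theta_mrad = theta,
    halo_weight = model$trimmer_halo_weight,
    halo_sigma_scale = model$trimmer_halo_sigma_scale
  )
}

#' Upstream/downstream lateral sigma decomposition of a beamlet
#'
#' Splits the lateral spread of a beamlet at water depth `z` into the sigma
#' of the fluence arriving at the trimmer plane (`sigma_up`: in-air spot
#' sigma projected from the isocenter plane to the trimmer plane, plus the
#' range-shifter scatter accumulated over the shifter-to-trimmer drift) and
#' the post-trimmer blur (`sigma_down`: angular spread times the
#' trimmer-to-point drift, in quadrature with in-water multiple Coulomb
#' scattering). The uncollimated total sigma is the quadrature sum of the
#' two components.
#'
#' @param energy_mev Nominal beam energy (MeV).
#' @param z_cm Water depth (cm).
#' @param model A [beam_model()].
#' @param tsd_cm Trimmer-to-surface distance (cm).
#' @param use_range_shifter Logical; include the range-shifter scatter.
#' @param axis `"x"` or `"y"` (selects the virtual SAD).
#' @return Tibble with columns `sigma_up_mm`, `sigma_down_mm`,
#'   `sigma_total_mm`, `theta_mrad` (effective post-trimmer angular sigma).
#' @export
beamlet_sigma_total <- function(energy_mev, z_cm, model, tsd_cm = 5,
                                use_range_shifter = FALSE, axis = "x") {
  sad <- if (identical(axis, "y")) model$virtual_sad_y_mm else model$virtual_sad_x_mm
  s_air <- sigma_air(energy_mev, model)
  tsd_mm <- tsd_cm * 10
  sigma_up <- s_air * (sad - tsd_mm) / sad
  theta_div <- s_air / sad * 1000  # mrad
  theta_rs <- 0
  if (use_range_shifter) {
    theta_rs <- range_shifter_scatter(energy_mev, model)$theta_mrad
    sigma_up <- sqrt(sigma_up^2 +
                       (theta_rs / 1000 * model$rs_exit_to_trimmer_mm)^2)
  }
  theta <- sqrt(theta_div^2 + theta_rs^2)
  e_surf <- surface_energy(energy_mev, model, use_range_shifter)
  drift_mm <- tsd_mm + z_cm * 10
  sigma_down <- sqrt((theta / 1000 * drift_mm)^2 +
                       mcs_sigma(e_surf, z_cm, model)^2)
  tibble::tibble(
    sigma_up_mm = sigma_up,
    sigma_down_mm = sigma_down,
    sigma_total_mm = sqrt(sigma_up^2 + sigma_down^2),
    theta_mrad = theta
  )
}

# Energy at the phantom surface (after the range shifter when present).
surface_energy <- function(energy_mev, model, use_range_shifter) {
  if (!use_range_shifter) return(energy_mev)
  R <- range_from_energy(energy_mev, model)
  energy_from_range(pmax(R - model$rs_wet_cm, 1e-9), model)
}

#' Lateral fluence profile of a trimmer-collimated beamlet
#'
#' A Gaussian fluence of sigma `sigma_up` centered at `center_mm`, truncated
#' to the aperture `[edge_lo_mm, edge_hi_mm]` at the trimmer plane, then
#' convolved with a Gaussian blur of sigma `sigma_down`. Closed form via the
#' Gaussian product identity:
#' `f(x) = N(x; c, sqrt(su^2+sd^2)) * [Phi((e_hi - m)/s) - Phi((e_lo - m)/s)]`
#' with `m = (c sd^2 + x su^2) / (su^2 + sd^2)` and `s = su sd /
#' sqrt(su^2 + sd^2)`. Retracted blades are `-Inf`/`Inf` edges, recovering
#' the pure Gaussian. Values are probability densities (1/mm) of the
#' unit-fluence beamlet; collimation removes fluence, so the profile never
#' exceeds the uncollimated one.
#'
#' @param x_mm Evaluation positions (mm); vectorized.
#' @param center_mm Spot center (mm).
#' @param edge_lo_mm,edge_hi_mm Aperture edges (mm), `edge_lo_mm <= edge_hi_mm`.
#' @param sigma_up_mm,sigma_down_mm Upstream / downstream sigmas (mm), positive.
#' @return Fluence density (1/mm) at each `x_mm`.
#' @export
collimated_lateral_profile <- function(x_mm, center_mm,
                                       edge_lo_mm = -Inf, edge_hi_mm = Inf,
                                       sigma_up_mm, sigma_down_mm) {
  stopifnot(sigma_up_mm > 0, sigma_down_mm > 0)
  st2 <- sigma_up_mm^2 + sigma_down_mm^2
  st <- sqrt(st2)
  base <- stats::dnorm(x_mm, center_mm, st)
  if (!is.finite(edge_lo_mm) && !is.finite(edge_hi_mm)) return(base)
  s <- sigma_up_mm * sigma_down_mm / st
  m <- (center_mm * sigma_down_mm^2 + x_mm * sigma_up_mm^2) / st2
  base * (stats::pnorm((edge_hi_mm - m) / s) - stats::pnorm((edge_lo_mm - m) / s))
}
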