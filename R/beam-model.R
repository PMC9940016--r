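#' Beam model for the analytical pencil-beam engine
#'
#' Bundles every machine- and physics-level constant the dose engine needs:
#' the in-air spot size versus energy, virtual source distances for the two
#' scanning axes, the range-energy power law, range straggling, the
#' range-shifter slab, and the trimmer geometry of the dynamic collimation
#' system (DCS).
#'
#' The in-air spot sigma table and the virtual source-axis distances (SADs)
#' are representative values for a dedicated-nozzle PBS system and are
#' configuration, not measured machine data; absolute uncollimated spot sizes
#' therefore carry a soft uncertainty of roughly +/- 0.7 mm. The range-energy
#' power law `R = alpha * E^p` (R in cm of water, E in MeV) with the classic
#' constants `alpha = 0.0022`, `p = 1.77` reproduces the catalog energy
#' ranges to about 1 percent.
#'
#' @param sigma_air_table Data frame with columns `energy_mev` and `sigma_mm`:
#'   the in-air spot sigma at the isocenter plane, strictly increasing in
#'   energy and with positive sigmas.
#' @param virtual_sad_x_mm,virtual_sad_y_mm Distance (mm) from the effective
#'   scanning source to the isocenter plane, per lateral axis.
#' @param alpha,p Range-energy power law constants (`R = alpha * E^p`).
#' @param straggling_coeff Range straggling coefficient `c` in
#'   `sigma_range = c * R^0.935` (cm).
#' @param energy_spread_frac Relative beam energy spread (sigma_E / E) of
#'   the delivery system; broadens each Bragg peak in range by
#'   `p * R * energy_spread_frac` in quadrature with straggling. Without it
#'   the 3 mm layer spacing would leave unphysical depth-dose ripple.
#' @param rs_wet_cm Water-equivalent thickness of the range shifter (cm).
#' @param rs_thickness_cm Physical polyethylene thickness of the shifter (cm).
#' @param rs_exit_to_trimmer_mm Air drift from the shifter exit face to the
#'   trimmer plane (mm).
#' @param trimmer_thickness_mm Physical trimmer blade thickness (mm); metadata
#'   carried for writers, the engine treats blades as a full stop.
#' @param trimmer_halo_weight Fraction (in `[0, 1)`) of the fluence
#'   intercepted by an engaged blade that is re-emitted as a shallow scatter
#'   halo.
#' @param trimmer_halo_sigma_scale Lateral sigma of the halo as a multiple
#'   (> 1) of the local edge sigma.
#' @param halo_residual_range_cm Effective residual range (cm) of the halo
#'   protons; the halo depth-dose decays as `exp(-z / range)`.
#'
#' @return An object of class `dcpt_beam_model` (a named list).
#' @examples
#' model <- beam_model()
#' range_from_energy(100, model)
#' @export
beam_model <- function(sigma_air_table = default_sigma_air_table(),
                       virtual_sad_x_mm = 2000,
                       virtual_sad_y_mm = 1900,
                       alpha = 0.0022,
                       p = 1.77,
                       straggling_coeff = 0.012,
                       energy_spread_frac = 0.007,
                       rs_wet_cm = 4.1,
                       rs_thickness_cm = 4.0,
                       rs_exit_to_trimmer_mm = 100,
                       trimmer_thickness_mm = 50,
                       trimmer_halo_weight = 0.03,
                       trimmer_halo_sigma_scale = 3,
                       halo_residual_range_cm = 2) {
  sigma_air_table <- tibble::as_tibble(sigma_air_table)
  model <- structure(
    list(
      sigma_air_table = sigma_air_table,
      virtual_sad_x_mm = virtual_sad_x_mm,
      virtual_sad_y_mm = virtual_sad_y_mm,
      alpha = alpha,
      p = p,
      straggling_coeff = straggling_coeff,
      energy_spread_frac = energy_spread_frac,
      rs_wet_cm = rs_wet_cm,
      rs_thickness_cm = rs_thickness_cm,
      rs_exit_to_trimmer_mm = rs_exit_to_trimmer_mm,
      trimmer_thickness_mm = trimmer_thickness_mm,
      trimmer_halo_weight = trimmer_halo_weight,
      trimmer_halo_sigma_scale = trimmer_halo_sigma_scale,
      halo_residual_range_cm = halo_residual_range_cm
    ),
    class = "dcpt_beam_model"
  )
  validate_beam_model(model)
}

#' @export
print.dcpt_beam_model <- function(x, ...) {
  cat("<dcpt_beam_model>\n")
  cat(sprintf("  range-energy: R = %g * E^%g (cm, MeV)\n", x$alpha, x$p))
  cat(sprintf("  sigma_air: %d-point table over %g-%g MeV\n",
              nrow(x$sigma_air_table),
              min(x$sigma_air_table$energy_mev),
              max(x$sigma_air_table$energy_mev)))
  cat(sprintf("  virtual SAD x/y: %g / %g mm\n",
              x$virtual_sad_x_mm, x$virtual_sad_y_mm))
  cat(sprintf("  range shifter: %g cm WET (%g cm polyethylene)\n",
              x$rs_wet_cm, x$rs_thickness_cm))
  invisible(x)
}

#' Default in-air spot sigma table
#'
#' Four anchor points (70-160 MeV), linearly interpolated in energy.
#' Representative of a dedicated-nozzle system; configuration, not data.
#'
#' @return Tibble with columns `energy_mev`, `sigma_mm`.
#' @export
default_sigma_air_table <- function() {
  tibble::tibble(
    energy_mev = c(70, 100, 130, 160),
    sigma_mm = c(5.4, 4.3, 3.7, 3.2)
  )
}

validate_beam_model <- function(model) {
  tab <- model$sigma_air_table
  if (!all(c("energy_mev", "sigma_mm") %in% names(tab))) {
    stop("sigma_air_table must have columns energy_mev and sigma_mm",
         call. = FALSE)
  }
  if (nrow(tab) < 2 || any(diff(tab$energy_mev) <= 0)) {
    stop("sigma_air_table energies must be strictly increasing", call. = FALSE)
  }
  if (any(tab$sigma_mm <= 0)) stop("in-air sigmas must be positive", call. = FALSE)
  if (model$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (model$p <= 1 || model$p >= 2.5) stop("p must lie in (1, 2.5)", call. = FALSE)
  if (model$rs_wet_cm < 0) stop("rs_wet_cm must be nonnegative", call. = FALSE)
  if (model$trimmer_halo_weight < 0 || model$trimmer_halo_weight >= 1) {
    stop("trimmer_halo_weight must lie in [0, 1)", call. = FALSE)
  }
  if (model$trimmer_halo_sigma_scale <= 1) {
    stop("trimmer_halo_sigma_scale must exceed 1", call. = FALSE)
  }
  model
}

#' Interpolated in-air spot sigma at the isocenter plane
#'
#' @param energy_mev Beam energy (MeV); must lie within the table domain.
#' @param model A [beam_model()].
#' @return Sigma (mm) at the isocenter plane.
#' @export
sigma_air <- function(energy_mev, model) {
  tab <- model$sigma_air_table
  rng <- range(tab$energy_mev)
  if (any(energy_mev < rng[1] - 1e-9) || any(energy_mev > rng[2] + 1e-9)) {
    stop(sprintf("energy outside sigma_air table domain [%g, %g] MeV",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(tab$energy_mev, tab$sigma_mm, xout = energy_mev, rule = 2)$y
}

# ---- beam model configuration files -----------------------------------------

beam_model_scalar_fields <- c(
  "virtual_sad_x_mm", "virtual_sad_y_mm", "alpha", "p", "straggling_coeff",
  "energy_spread_frac", "rs_wet_cm", "rs_thickness_cm", "rs_exit_to_trimmer_mm",
  "trimmer_thickness_mm", "trimmer_halo_weight", "trimmer_halo_sigma_scale",
  "halo_residual_range_cm"
)

#' Write a beam model configuration file
#'
#' The configuration is YAML whose keys are exactly the [beam_model()] fields;
#' `sigma_air_table` is a list of `{energy_mev, sigma_mm}` records.
#'
#' @param model A [beam_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "dcpt_beam_model"))
  out <- model[beam_model_scalar_fields]
  out$sigma_air_table <- purrr::pmap(model$sigma_air_table, list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a beam model configuration file
#'
#' Unknown keys are rejected so that typos in configuration files fail loudly.
#'
#' @param path Path to a YAML file written by [write_beam_model()] or by hand.
#' @return A [beam_model()].
#' @export
read_beam_model <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c(beam_model_scalar_fields, "sigma_air_table")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown beam model keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$sigma_air_table)) {
    raw$sigma_air_table <- dplyr::bind_rows(
      lapply(raw$sigma_air_table, tibble::as_tibble)
    )
  }
  do.call(beam_model, raw)
}
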