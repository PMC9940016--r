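# Plan generation for cubic water-phantom targets: spot lattice placement,
# energy layer selection, divergence-matched trimmer positioning, and the
# four-plan catalog.

TRIMMER_TRAVEL_MM <- 75
TSD_RANGE_CM <- c(5, 18.15)

#' Cubic planning target volume specification
#'
#' The optimization target: a water-submerged cube centered on the beam axis.
#'
#' @param side_mm Cube side length (mm).
#' @param center_depth_cm Depth of the cube center below the phantom
#'   surface (cm).
#' @param lateral_margin_mm,depth_margin_mm Spot-placement expansion of the
#'   cube, lateral and in range (mm).
#' @return An object of class `dcpt_ptv`.
#' @export
ptv_spec <- function(side_mm = 30, center_depth_cm,
                     lateral_margin_mm = 2.5, depth_margin_mm = 2.5) {
  if (side_mm <= 0) stop("side_mm must be positive", call. = FALSE)
  proximal_cm <- center_depth_cm - side_mm / 20 - depth_margin_mm / 10
  if (proximal_cm <= 0) {
    stop("target is not fully submerged: depth - side/2 - margin must be > 0",
         call. = FALSE)
  }
  structure(
    list(side_mm = side_mm, center_depth_cm = center_depth_cm,
         lateral_margin_mm = lateral_margin_mm,
         depth_margin_mm = depth_margin_mm),
    class = "dcpt_ptv"
  )
}

#' Place the candidate spot lattice for a target
#'
#' A square lattice centered on the beam axis covering the laterally expanded
#' target: the lattice always contains (0, 0) and extends symmetrically to
#' the smallest index `k` with `k * spacing >= side/2 + margin` (cover rule).
#' The same lattice is reused for every energy layer. For the catalog cubes
#' (30 mm side, 2.5 mm margin, 3 mm spacing) this yields a 13 x 13 lattice,
#' 169 spots per layer and 2028 candidate beamlets over 12 layers.
#'
#' @param ptv A [ptv_spec()].
#' @param spacing_mm Lateral in-plane spot spacing (mm).
#' @return Tibble with columns `spot_x_mm`, `spot_y_mm`, ordered row-major by
#'   y then x.
#' @export
place_spots <- function(ptv, spacing_mm = 3) {
  if (spacing_mm <= 0) stop("spacing must be positive", call. = FALSE)
  half <- ptv$side_mm / 2 + ptv$lateral_margin_mm
  # cover rule: smallest k with k * spacing >= expanded half-width; a spacing
  # wider than the whole expanded target collapses to the axial spot alone
  k <- if (spacing_mm >= 2 * half) 0L else ceiling(half / spacing_mm - 1e-9)
  pos <- seq(-k, k) * spacing_mm
  tidyr::expand_grid(spot_y_mm = pos, spot_x_mm = pos)[, c("spot_x_mm", "spot_y_mm")]
}

#' Select the energy layers covering a target in depth
#'
#' The distal required water range is `center + side/2 + depth margin`, the
#' proximal one `center - side/2 - depth margin`; with a range shifter the
#' shifter WET is added to both (the beam must penetrate the slab first).
#' Layers are equally spaced in range with `n = floor(span/nominal) + 1`
#' (11 layers when the span divides exactly; the floor rule is the
#' documented tie-break), ordered distal to proximal, and converted to
#' energies through the range-energy power law.
#'
#' @param ptv A [ptv_spec()].
#' @param model A [beam_model()].
#' @param nominal_spacing_mm Nominal layer spacing in range (mm).
#' @param use_range_shifter Logical.
#' @return Tibble with columns `layer_index` (1 = distal), `range_cm`
#'   (total water-equivalent range including the shifter), `energy_mev`.
#' @export
select_energy_layers <- function(ptv, model, nominal_spacing_mm = 3,
                                 use_range_shifter = FALSE) {
  offset <- if (use_range_shifter) model$rs_wet_cm else 0
  distal <- ptv$center_depth_cm + ptv$side_mm / 20 + ptv$depth_margin_mm / 10
  proximal <- ptv$center_depth_cm - ptv$side_mm / 20 - ptv$depth_margin_mm / 10
  if (proximal + offset <= 0) {
    stop("proximal required range is nonpositive; use the range shifter",
         call. = FALSE)
  }
  span_mm <- (distal - proximal) * 10
  n <- floor(span_mm / nominal_spacing_mm + 1e-9) + 1L
  ranges <- seq(distal + offset, proximal + offset, length.out = n)
  tibble::tibble(
    layer_index = seq_len(n),
    range_cm = ranges,
    energy_mev = energy_from_range(ranges, model)
  )
}

#' Position the trimmer blades for one energy layer
#'
#' Each medial blade edge, expressed at the isocenter plane, is placed so the
#' ray from the virtual source through the physical edge crosses the lateral
#' target boundary at the layer's nominal Bragg-peak depth:
#' `edge_iso = boundary * SAD / (SAD + depth)` (the phantom surface sits at
#' the isocenter plane). Edges beyond the blade travel are retracted.
#'
#' @param layer_range_cm Total water range of the layer (cm); the Bragg-peak
#'   depth is the in-water part (shifter WET subtracted when present).
#' @param ptv A [ptv_spec()].
#' @param model A [beam_model()].
#' @param use_range_shifter Logical.
#' @param engaged Logical; `FALSE` retracts all four blades (uncollimated).
#' @return Tibble with one row: `x1_mm, x2_mm, y1_mm, y2_mm` (medial edges at
#'   the isocenter plane) and `retracted_x1, ..., retracted_y2` flags.
#' @export
position_trimmers <- function(layer_range_cm, ptv, model,
                              use_range_shifter = FALSE, engaged = TRUE) {
  half <- ptv$side_mm / 2
  offset <- if (use_range_shifter) model$rs_wet_cm else 0
  depth_mm <- (layer_range_cm - offset) * 10
  ex <- half * model$virtual_sad_x_mm / (model$virtual_sad_x_mm + depth_mm)
  ey <- half * model$virtual_sad_y_mm / (model$virtual_sad_y_mm + depth_mm)
  out <- tibble::tibble(
    x1_mm = -ex, x2_mm = ex, y1_mm = -ey, y2_mm = ey,
    retracted_x1 = !engaged, retracted_x2 = !engaged,
    retracted_y1 = !engaged, retracted_y2 = !engaged
  )
  for (col in c("x1_mm", "x2_mm", "y1_mm", "y2_mm")) {
    flag <- sub("^([xy])(\\d)_mm$", "retracted_\\1\\2", col)
    beyond <- abs(out[[col]]) > TRIMMER_TRAVEL_MM
    if (any(beyond)) {
      message("trimmer edge beyond travel; blade retracted: ", col)
      out[[flag]] <- out[[flag]] | beyond
    }
  }
  out
}

#' The four-plan cubic-target catalog
#'
#' @return Tibble with columns `name`, `center_depth_cm`, `use_range_shifter`.
#' @export
plan_catalog <- function() {
  tibble::tibble(
    name = c("C3-D5-RS", "C3-D6-NRS", "C3-D10-NRS", "C3-D15-NRS"),
    center_depth_cm = c(5, 6, 10, 15),
    use_range_shifter = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' Build a treatment plan for a catalog target or a user-defined cube
#'
#' Assembles the spot lattice, energy layers and per-layer trimmer states
#' into a `dcpt_plan`. Collimated and uncollimated variants share spots and
#' energies and differ only in the trimmer states.
#'
#' @param name One of the [plan_catalog()] names, or any name when `ptv` is
#'   supplied explicitly.
#' @param model A [beam_model()].
#' @param tsd_cm Trimmer-to-surface distance (cm), within 5-18.15.
#' @param collimated Logical; engage the trimmer blades.
#' @param ptv Optional [ptv_spec()] overriding the catalog geometry.
#' @param use_range_shifter Logical, only used with an explicit `ptv`.
#' @param prescription_gy Prescribed uniform target dose (Gy).
#' @param spot_spacing_mm,layer_spacing_mm Lattice and layer spacings (mm).
#' @return An object of class `dcpt_plan`: a list with elements `name`,
#'   `ptv`, `use_range_shifter`, `tsd_cm`, `collimated`, `prescription_gy`,
#'   `layers` (tibble: layer + trimmer columns) and `spots` (tibble:
#'   `layer_index`, `spot_x_mm`, `spot_y_mm`, `weight`, `mu`).
#' @export
build_plan <- function(name, model, tsd_cm = 5, collimated = TRUE,
                       ptv = NULL, use_range_shifter = FALSE,
                       prescription_gy = 5,
                       spot_spacing_mm = 3, layer_spacing_mm = 3) {
  if (tsd_cm < TSD_RANGE_CM[1] || tsd_cm > TSD_RANGE_CM[2]) {
    stop(sprintf("tsd_cm must lie in [%g, %g]", TSD_RANGE_CM[1],
                 TSD_RANGE_CM[2]), call. = FALSE)
  }
  if (is.null(ptv)) {
    cat_tab <- plan_catalog()
    row <- cat_tab[cat_tab$name == name, ]
    if (nrow(row) == 0) {
      stop("unknown plan name '", name, "'; valid catalog names: ",
           paste(cat_tab$name, collapse = ", "), call. = FALSE)
    }
    ptv <- ptv_spec(center_depth_cm = row$center_depth_cm)
    use_range_shifter <- row$use_range_shifter
  }
  layers <- select_energy_layers(ptv, model,
                                 nominal_spacing_mm = layer_spacing_mm,
                                 use_range_shifter = use_range_shifter)
  trims <- dplyr::bind_rows(lapply(layers$range_cm, position_trimmers,
                                   ptv = ptv, model = model,
                                   use_range_shifter = use_range_shifter,
                                   engaged = collimated))
  layers <- dplyr::bind_cols(layers, trims)
  lattice <- place_spots(ptv, spacing_mm = spot_spacing_mm)
  spots <- tidyr::expand_grid(layer_index = layers$layer_index, lattice)
  spots$weight <- 0
  spots$mu <- 0
  structure(
    list(name = name, ptv = ptv, use_range_shifter = use_range_shifter,
         tsd_cm = tsd_cm, collimated = collimated,
         prescription_gy = prescription_gy,
         layers = layers, spots = spots),
    class = "dcpt_plan"
  )
}

#' @export
print.dcpt_plan <- function(x, ...) {
  cat(sprintf("<dcpt_plan> %s: %d layers x %d spots = %d beamlets\n",
              x$name, nrow(x$layers), nrow(x$spots) / nrow(x$layers),
              nrow(x$spots)))
  cat(sprintf("  %s, %s, TSD %g cm, Rx %g Gy\n",
              if (x$collimated) "collimated" else "uncollimated",
              if (x$use_range_shifter) "range shifter" else "no range shifter",
              x$tsd_cm, x$prescription_gy))
  cat(sprintf("  energies %.1f-%.1f MeV (distal to proximal)\n",
              max(x$layers$energy_mev), min(x$layers$energy_mev)))
  invisible(x)
}

#' @rdname build_plan
#' @param x A `dcpt_plan`.
#' @param ... Unused.
#' @export
tidy.dcpt_plan <- function(x, ...) {
  dplyr::left_join(x$spots,
                   x$layers[, c("layer_index", "energy_mev", "range_cm")],
                   by = "layer_index")
}

# ---- plan serialization -----------------------------------------------------

#' Write / read a plan as structured JSON
#'
#' A lossless round trip for the full plan object (geometry, layers, trimmer
#' states, spot weights and MUs).
#'
#' @param plan A `dcpt_plan`.
#' @param path File path.
#' @return `path` (writer) or a `dcpt_plan` (reader).
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "dcpt_plan"))
  out <- list(
    name = plan$name,
    ptv = unclass(plan$ptv),
    use_range_shifter = plan$use_range_shifter,
    tsd_cm = plan$tsd_cm,
    collimated = plan$collimated,
    prescription_gy = plan$prescription_gy,
    layers = plan$layers,
    spots = plan$spots
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(name = raw$name,
         ptv = structure(as.list(raw$ptv), class = "dcpt_ptv"),
         use_range_shifter = raw$use_range_shifter,
         tsd_cm = raw$tsd_cm,
         collimated = raw$collimated,
         prescription_gy = raw$prescription_gy,
         layers = tibble::as_tibble(raw$layers),
         spots = tibble::as_tibble(raw$spots)),
    class = "dcpt_plan"
  )
}
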