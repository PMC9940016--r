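# Delivery-file operations: a documented plain-text PBS layer definition
# (PLD) dialect and the per-layer trimmer motion sequence with
# pause-after-layer semantics.
#
# PLD dialect (comma-separated, one record per line):
#   pld,1.0
#   plan,<name>,tsd_cm,<tsd>,range_shifter,<Y|N>,prescription_gy,<rx>
#   layer,<index>,energy_mev,<E>,nspots,<n>,cum_mu,<cumulative MU>
#   spot,<x_mm>,<y_mm>,<mu>         (nspots lines, row-major by y then x)
# Layers appear distal to proximal (strictly decreasing energy). MU values
# are written with 6 significant digits; the per-layer cum_mu field is a
# cumulative checksum over the file as written, so the file total equals the
# sum of the printed spot MUs exactly.

fmt6 <- function(x) sprintf("%.6g", x)

#' Write a plan to a PLD delivery file
#'
#' Refuses plans that have not been minimum-MU filtered (any spot below
#' 0.05 MU) or that carry no spots. Output is deterministic: layers distal
#' to proximal, spots row-major by y then x, fixed 6-significant-digit
#' formatting.
#'
#' @param plan A `dcpt_plan` with optimized, filtered MU values.
#' @param path Output file path.
#' @param min_mu Deliverable minimum (MU) used for the refusal check.
#' @return `path`, invisibly.
#' @export
write_pld <- function(plan, path, min_mu = 0.05) {
  stopifnot(inherits(plan, "dcpt_plan"))
  if (nrow(plan$spots) == 0) {
    stop("refusing to write an empty plan", call. = FALSE)
  }
  if (any(plan$spots$mu < min_mu - 1e-9)) {
    stop("plan contains spots below the minimum MU; run the minimum-MU ",
         "filter before writing a PLD", call. = FALSE)
  }
  layers <- plan$layers[order(-plan$layers$energy_mev), ]
  lines <- c(
    "pld,1.0",
    sprintf("plan,%s,tsd_cm,%s,range_shifter,%s,prescription_gy,%s",
            plan$name, fmt6(plan$tsd_cm),
            if (plan$use_range_shifter) "Y" else "N",
            fmt6(plan$prescription_gy))
  )
  cum <- 0
  for (li in seq_len(nrow(layers))) {
    layer <- layers[li, ]
    sp <- plan$spots[plan$spots$layer_index == layer$layer_index, ]
    sp <- sp[order(sp$spot_y_mm, sp$spot_x_mm), ]
    mu_printed <- as.numeric(fmt6(sp$mu))
    cum <- cum + sum(mu_printed)
    lines <- c(
      lines,
      sprintf("layer,%d,energy_mev,%s,nspots,%d,cum_mu,%s",
              layer$layer_index, fmt6(layer$energy_mev), nrow(sp), fmt6(cum)),
      sprintf("spot,%s,%s,%s", fmt6(sp$spot_x_mm), fmt6(sp$spot_y_mm),
              fmt6(sp$mu))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLD delivery file
#'
#' Lossless parse of the documented dialect with validation: layer energies
#' must be strictly decreasing, MU values nonnegative, and spot counts
#' consistent; malformed lines are reported with their line numbers.
#'
#' @param path Path to a PLD file.
#' @return A list of class `dcpt_pld`: `name`, `tsd_cm`,
#'   `use_range_shifter`, `prescription_gy`, `layers` (tibble
#'   `layer_index`, `energy_mev`, `n_spots`, `cum_mu`), `spots` (tibble
#'   `layer_index`, `spot_x_mm`, `spot_y_mm`, `mu`).
#' @export
read_pld <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) {
    stop(sprintf("PLD parse error at line %d: %s", i, why), call. = FALSE)
  }
  if (length(lines) < 2 || !startsWith(lines[1], "pld,")) {
    bad(1, "missing pld header")
  }
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 8 || hdr[1] != "plan") bad(2, "malformed plan record")
  layers <- list()
  spots <- list()
  current <- NULL
  n_expected <- 0
  n_seen <- 0
  for (i in seq_along(lines)[-(1:2)]) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (f[1] == "layer") {
      if (n_seen != n_expected) bad(i, "previous layer has missing spots")
      if (length(f) != 8) bad(i, "malformed layer record")
      current <- tibble::tibble(layer_index = as.integer(f[2]),
                                energy_mev = as.numeric(f[4]),
                                n_spots = as.integer(f[6]),
                                cum_mu = as.numeric(f[8]))
      if (any(is.na(current))) bad(i, "non-numeric layer fields")
      layers[[length(layers) + 1]] <- current
      n_expected <- current$n_spots
      n_seen <- 0
    } else if (f[1] == "spot") {
      if (is.null(current)) bad(i, "spot before any layer")
      if (length(f) != 4) bad(i, "malformed spot record")
      v <- as.numeric(f[2:4])
      if (any(is.na(v))) bad(i, "non-numeric spot fields")
      if (v[3] < 0) bad(i, "negative MU")
      spots[[length(spots) + 1]] <- tibble::tibble(
        layer_index = current$layer_index,
        spot_x_mm = v[1], spot_y_mm = v[2], mu = v[3])
      n_seen <- n_seen + 1
    } else {
      bad(i, paste0("unknown record type '", f[1], "'"))
    }
  }
  if (n_seen != n_expected) bad(length(lines), "final layer has missing spots")
  layers <- dplyr::bind_rows(layers)
  if (nrow(layers) == 0) stop("PLD contains no layers", call. = FALSE)
  if (any(diff(layers$energy_mev) >= 0)) {
    stop("PLD validation error: layer energies must be strictly decreasing",
         call. = FALSE)
  }
  structure(
    list(name = hdr[2], tsd_cm = as.numeric(hdr[4]),
         use_range_shifter = identical(hdr[6], "Y"),
         prescription_gy = as.numeric(hdr[8]),
         layers = layers, spots = dplyr::bind_rows(spots)),
    class = "dcpt_pld"
  )
}

#' Export the per-layer trimmer motion sequence
#'
#' One record per delivered layer with the four medial edge positions at the
#' isocenter plane, the per-blade retraction flags, and the
#' pause-after-layer flag (always set: the trimmers are repositioned while
#' the delivery pauses between energy layers, one trimmer state per layer).
#' Uncollimated plans export all-retracted records.
#'
#' @param plan A `dcpt_plan` (post-filtering for delivered counts).
#' @param path Optional output path (comma-separated text); when `NULL` the
#'   sequence is only returned.
#' @return Tibble with columns `layer_index`, `energy_mev`, `x1_mm`,
#'   `x2_mm`, `y1_mm`, `y2_mm`, `retracted_x1` ... `retracted_y2`,
#'   `pause_after_layer`.
#' @export
export_trimmer_sequence <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "dcpt_plan"))
  seq_tab <- plan$layers[order(-plan$layers$energy_mev),
                         c("layer_index", "energy_mev", "x1_mm", "x2_mm",
                           "y1_mm", "y2_mm", "retracted_x1", "retracted_x2",
                           "retracted_y1", "retracted_y2")]
  seq_tab$pause_after_layer <- TRUE
  if (!is.null(path)) {
    utils::write.csv(seq_tab, path, row.names = FALSE, quote = FALSE)
  }
  seq_tab
}

#' @rdname export_trimmer_sequence
#' @export
read_trimmer_sequence <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
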