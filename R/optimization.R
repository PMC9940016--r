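# Nonnegative least-squares spot-weight optimization, 90% coverage
# normalization, protons->MU conversion and minimum-MU filtering.

#' Build the influence matrix for a plan
#'
#' Rows are sampled optimization voxels, columns are the candidate beamlets
#' in the row order of `plan$spots`; entries are Gy per proton, evaluated
#' with the exact arithmetic of [compute_dose()] (same voxel averaging,
#' collimation and halo terms), so an influence column equals the
#' single-beamlet composite dose at the sampled voxels. Three voxel zones
#' are sampled: the prescription target (the PTV expanded by the depth
#' margin, so the spread-out Bragg peak is driven flat across the full
#' layer span and the proximal/distal layers placed in that margin carry
#' deliverable weight); the lateral expansion ring (zero least-squares
#' weight: covered by spot placement but neither prescribed nor penalized,
#' since the trimmed field edge sits at the PTV surface); and a shell
#' beyond the margins with a zero-dose objective at reduced weight to
#' discourage edge overdose.
#'
#' @param plan A `dcpt_plan`.
#' @param model A [beam_model()].
#' @param grid A [dose_grid()]; defaults to [default_grid()]. The sampled
#'   voxels are a sub-lattice of this grid.
#' @param stride_mm Sampling stride (mm) of the voxel sub-lattice.
#' @param shell_mm Width of the zero-dose shell around the PTV (mm).
#' @param shell_weight Relative least-squares weight of shell voxels.
#' @return List with elements `A` (matrix), `voxels` (tibble with `x_mm`,
#'   `y_mm`, `z_mm`, `in_ptv`, `zone`), `row_weight`, `plan`, `grid`.
#' @export
build_influence_matrix <- function(plan, model, grid = NULL, stride_mm = 2,
                                   shell_mm = 5, shell_weight = 0.1) {
  if (is.null(grid)) grid <- default_grid(plan, model)
  co <- grid_coords(grid)
  ptv <- plan$ptv
  half <- ptv$side_mm / 2
  zc <- ptv$center_depth_cm * 10
  # stride-s sub-lattice anchored so a sample row hits `anchor` (the beam
  # axis laterally, the proximal target boundary in depth)
  pick <- function(coord, lo, hi, anchor) {
    idx <- which(coord >= lo - 1e-9 & coord <= hi + 1e-9)
    if (length(idx) == 0) stop("empty optimization voxel set", call. = FALSE)
    s <- max(1L, round(stride_mm / grid$spacing_mm))
    ia <- idx[which.min(abs(coord[idx] - anchor))]
    sort(unique(c(seq(ia, max(idx), by = s), seq(ia, min(idx), by = -s))))
  }
  lat_margin <- ptv$lateral_margin_mm
  dep_margin <- ptv$depth_margin_mm
  ix <- pick(co$x, -half - lat_margin - shell_mm, half + lat_margin + shell_mm, 0)
  iy <- pick(co$y, -half - lat_margin - shell_mm, half + lat_margin + shell_mm, 0)
  iz <- pick(co$z, zc - half - dep_margin - shell_mm,
             zc + half + dep_margin + shell_mm, zc - half - dep_margin)
  xs <- co$x[ix]; ys <- co$y[iy]; zs <- co$z[iz]
  voxels <- tidyr::expand_grid(z_mm = zs, y_mm = ys, x_mm = xs)
  voxels <- voxels[, c("x_mm", "y_mm", "z_mm")]
  voxels$in_ptv <- abs(voxels$x_mm) <= half + 1e-9 &
    abs(voxels$y_mm) <= half + 1e-9 &
    abs(voxels$z_mm - zc) <= half + 1e-9
  in_target <- abs(voxels$x_mm) <= half + 1e-9 &
    abs(voxels$y_mm) <= half + 1e-9 &
    abs(voxels$z_mm - zc) <= half + dep_margin + 1e-9
  in_margin <- !in_target &
    abs(voxels$x_mm) <= half + lat_margin + 1e-9 &
    abs(voxels$y_mm) <= half + lat_margin + 1e-9 &
    abs(voxels$z_mm - zc) <= half + dep_margin + 1e-9
  voxels$zone <- ifelse(in_target, "target",
                        ifelse(in_margin, "margin", "shell"))

  xs_all <- sort(unique(plan$spots$spot_x_mm))
  ys_all <- sort(unique(plan$spots$spot_y_mm))
  nvx <- length(xs); nvy <- length(ys)
  rep_x <- rep(seq_len(nvx), times = nvy)
  rep_y <- rep(seq_len(nvy), each = nvx)
  A <- matrix(0, nrow(voxels), nrow(plan$spots))
  hs <- model$trimmer_halo_sigma_scale
  for (li in seq_len(nrow(plan$layers))) {
    layer <- plan$layers[li, ]
    ctx <- layer_context(layer, plan, model)
    sel <- which(plan$spots$layer_index == layer$layer_index)
    sp <- plan$spots[sel, ]
    sxi <- match(sp$spot_x_mm, xs_all)
    syi <- match(sp$spot_y_mm, ys_all)
    idd <- layer_idd(ctx$energy_mev, model, plan$use_range_shifter, zs,
                     voxel_mm = grid$spacing_mm)
    sd_x <- layer_sigma_down(ctx, zs, "x", model)
    sd_y <- layer_sigma_down(ctx, zs, "y", model)
    halo_on <- any(is.finite(unlist(ctx$edges))) &&
      model$trimmer_halo_weight > 0
    idd_ent <- layer_idd(ctx$energy_mev, model, plan$use_range_shifter,
                         co$z[1], voxel_mm = grid$spacing_mm)
    fx <- list(lo = intercepted_fraction(xs_all, ctx$edges$x[["lo"]],
                                         ctx$sigma_up_iso[["x"]], "lo"),
               hi = intercepted_fraction(xs_all, ctx$edges$x[["hi"]],
                                         ctx$sigma_up_iso[["x"]], "hi"))
    fy <- list(lo = intercepted_fraction(ys_all, ctx$edges$y[["lo"]],
                                         ctx$sigma_up_iso[["y"]], "lo"),
               hi = intercepted_fraction(ys_all, ctx$edges$y[["hi"]],
                                         ctx$sigma_up_iso[["y"]], "hi"))
    for (k in seq_along(zs)) {
      z <- zs[k]
      if (idd[k] <= 0 && z > ctx$r_ent_mm) next
      m_x <- (ctx$sad[["x"]] + z) / ctx$sad[["x"]]
      m_y <- (ctx$sad[["y"]] + z) / ctx$sad[["y"]]
      Gx <- lateral_matrix(xs, xs_all * m_x,
                           ctx$edges$x[["lo"]] * m_x, ctx$edges$x[["hi"]] * m_x,
                           ctx$sigma_up_iso[["x"]] * m_x, sd_x[k],
                           voxel_mm = grid$spacing_mm)
      Gy <- lateral_matrix(ys, ys_all * m_y,
                           ctx$edges$y[["lo"]] * m_y, ctx$edges$y[["hi"]] * m_y,
                           ctx$sigma_up_iso[["y"]] * m_y, sd_y[k],
                           voxel_mm = grid$spacing_mm)
      block <- DOSE_PER_PROTON_GY * idd[k] *
        (Gx[rep_x, sxi, drop = FALSE] * Gy[rep_y, syi, drop = FALSE])
      if (halo_on) {
        hz <- exp(-z / (model$halo_residual_range_cm * 10))
        scale <- DOSE_PER_PROTON_GY * model$trimmer_halo_weight * hz * idd_ent
        st_x <- sqrt((ctx$sigma_up_iso[["x"]] * m_x)^2 + sd_x[k]^2)
        st_y <- sqrt((ctx$sigma_up_iso[["y"]] * m_y)^2 + sd_y[k]^2)
        Hx <- matrix(0, nvx, length(xs_all))
        Hy <- matrix(0, nvy, length(ys_all))
        for (side in c("lo", "hi")) {
          ex <- ctx$edges$x[[side]]
          if (is.finite(ex)) {
            Hx <- Hx + outer(stats::dnorm(xs, ex * m_x, hs * st_x), fx[[side]])
          }
          ey <- ctx$edges$y[[side]]
          if (is.finite(ey)) {
            Hy <- Hy + outer(stats::dnorm(ys, ey * m_y, hs * st_y), fy[[side]])
          }
        }
        block <- block + scale *
          (Hx[rep_x, sxi, drop = FALSE] * Gy[rep_y, syi, drop = FALSE] +
             Gx[rep_x, sxi, drop = FALSE] * Hy[rep_y, syi, drop = FALSE])
      }
      rows <- (k - 1) * nvx * nvy + seq_len(nvx * nvy)
      A[rows, sel] <- A[rows, sel] + block
    }
  }
  list(A = A, voxels = voxels,
       row_weight = ifelse(voxels$zone == "target", 1,
                           ifelse(voxels$zone == "margin", 0, shell_weight)),
       plan = plan, grid = grid)
}

# Deterministic cyclic coordinate-descent NNLS on the normal equations.
# Each coordinate update is the exact clipped 1D minimizer, so the objective
# is nonincreasing from the uniform warm start; the compiled inner loop
# lives in src/nnls_cd.cpp.
nnls_solve <- function(AtA, Atb, max_sweeps = 2000, tol = 1e-10) {
  n <- length(Atb)
  s <- sum(Atb) / max(sum(AtA), .Machine$double.eps)
  w0 <- rep(max(s, 0), n)
  sol <- nnls_cd_cpp(AtA, Atb, w0, as.integer(max_sweeps), tol)
  w <- as.vector(sol$weights)
  list(weights = w,
       objective = 0.5 * sum(w * (AtA %*% w)) - sum(Atb * w),
       iterations = sol$sweeps, converged = sol$converged)
}

#' Optimize beamlet weights by nonnegative least squares
#'
#' Minimizes `sum_v r_v (A w - b)_v^2` subject to `w >= 0`, where `b` is the
#' prescription over PTV voxels and zero over the shell, and `r_v` are the
#' row weights. The solver is deterministic cyclic coordinate descent on
#' the normal equations with exact clipped single-coordinate minimizers, so
#' the residual never exceeds that of the best uniform-weight starting
#' point.
#'
#' @param influence The list returned by [build_influence_matrix()], or a
#'   plain influence matrix (rows voxels, columns beamlets).
#' @param prescription_gy Prescribed uniform PTV dose (Gy).
#' @param target Optional explicit per-voxel target vector overriding the
#'   prescription/shell construction.
#' @param row_weights Optional per-voxel least-squares weights.
#' @param max_sweeps,tol Solver controls (coordinate-descent sweeps;
#'   convergence when the projected-gradient norm falls below
#'   `tol * max|A'b|`).
#' @return An object of class `dcpt_opt`: `weights` (protons, `>= 0`),
#'   `objective`, `iterations`, `converged`, `n_voxels`, `n_beamlets`.
#' @export
optimize_weights <- function(influence, prescription_gy = 5, target = NULL,
                             row_weights = NULL, max_sweeps = 2000,
                             tol = 1e-10) {
  if (is.list(influence) && !is.null(influence$A)) {
    A <- influence$A
    if (is.null(target)) {
      target <- ifelse(influence$voxels$zone == "target", prescription_gy, 0)
    }
    if (is.null(row_weights)) row_weights <- influence$row_weight
  } else {
    A <- as.matrix(influence)
    if (is.null(target)) target <- rep(prescription_gy, nrow(A))
    if (is.null(row_weights)) row_weights <- rep(1, nrow(A))
  }
  if (nrow(A) == 0 || ncol(A) == 0 || all(A == 0)) {
    stop("influence matrix is empty or all-zero", call. = FALSE)
  }
  rw <- sqrt(row_weights)
  Aw <- A * rw
  bw <- target * rw
  AtA <- crossprod(Aw)
  Atb <- as.vector(crossprod(Aw, bw))
  sol <- nnls_solve(AtA, Atb, max_sweeps = max_sweeps, tol = tol)
  structure(
    list(weights = sol$weights,
         objective = sol$objective + 0.5 * sum(bw^2),
         iterations = sol$iterations, converged = sol$converged,
         n_voxels = nrow(A), n_beamlets = ncol(A)),
    class = "dcpt_opt"
  )
}

#' @export
print.dcpt_opt <- function(x, ...) {
  cat(sprintf(
    "<dcpt_opt> %d beamlets over %d voxels; %d nonzero weights; %d iterations%s\n",
    x$n_beamlets, x$n_voxels, sum(x$weights > 0), x$iterations,
    if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @rdname optimize_weights
#' @param x A `dcpt_opt`.
#' @param ... Unused.
#' @export
tidy.dcpt_opt <- function(x, ...) {
  tibble::tibble(beamlet = seq_along(x$weights), weight = x$weights)
}

#' @rdname optimize_weights
#' @export
glance.dcpt_opt <- function(x, ...) {
  tibble::tibble(objective = x$objective, iterations = x$iterations,
                 converged = x$converged, n_beamlets = x$n_beamlets,
                 n_nonzero = sum(x$weights > 0), n_voxels = x$n_voxels)
}

#' Coverage-normalization scale factor
#'
#' Returns the multiplicative dose scale after which the fraction of PTV
#' voxels at or above the prescription equals the requested coverage (to
#' within one voxel's quantile step): the threshold is the
#' `ceiling(coverage * N)`-th largest PTV dose.
#'
#' @param dose A [dose_grid()] of the composite plan dose (Gy).
#' @param ptv A [ptv_spec()].
#' @param prescription_gy Prescription (Gy).
#' @param coverage Target volume fraction at or above prescription.
#' @return Scalar scale factor.
#' @export
normalize_coverage <- function(dose, ptv, prescription_gy = 5,
                               coverage = 0.90) {
  d <- ptv_doses(dose, ptv)
  if (length(d) == 0) stop("no PTV voxels inside the grid", call. = FALSE)
  if (max(d) <= 0) stop("dose is zero everywhere in the PTV", call. = FALSE)
  m <- ceiling(coverage * length(d))
  thr <- sort(d, decreasing = TRUE)[m]
  prescription_gy / thr
}

ptv_doses <- function(dose, ptv) {
  co <- grid_coords(dose)
  half <- ptv$side_mm / 2
  zc <- ptv$center_depth_cm * 10
  ix <- abs(co$x) <= half + 1e-9
  iy <- abs(co$y) <= half + 1e-9
  iz <- abs(co$z - zc) <= half + 1e-9
  as.vector(dose$values[ix, iy, iz])
}

#' Reference-condition calibration for the protons/MU conversion
#'
#' The delivery system meters dose in monitor units (MU); optimized weights
#' are numbers of protons. The conversion is
#' `protons/MU = d_meas_ref (Gy/MU) / d_mc_ref (Gy/proton)`, both evaluated
#' under fixed reference conditions. Here `d_mc_ref` is computed by the
#' engine itself: the central-axis dose per proton of a single uncollimated,
#' non-range-shifted beamlet at 2 cm water depth. `d_meas_ref` is
#' configuration; its default puts mid-range catalog layer spots near 0.2 MU
#' so that the minimum-MU behaviour of the catalog is exercised.
#'
#' @param model A [beam_model()].
#' @param energy_mev Beam energies (MeV); the conversion is energy-dependent.
#' @param d_meas_ref_gy_per_mu Reference measured dose rate (Gy/MU).
#' @return Tibble with columns `energy_mev`, `d_meas_ref`, `d_mc_ref`,
#'   `protons_per_mu`.
#' @export
calibration_reference <- function(model, energy_mev,
                                  d_meas_ref_gy_per_mu = 0.1) {
  if (d_meas_ref_gy_per_mu <= 0) {
    stop("d_meas_ref must be positive", call. = FALSE)
  }
  d_mc <- vapply(energy_mev, function(E) {
    idd <- layer_idd(E, model, FALSE, 20.5, voxel_mm = 1)
    s <- beamlet_sigma_total(E, 2.05, model, tsd_cm = 5,
                             use_range_shifter = FALSE)
    sy <- beamlet_sigma_total(E, 2.05, model, tsd_cm = 5,
                              use_range_shifter = FALSE, axis = "y")
    DOSE_PER_PROTON_GY * idd * stats::dnorm(0, 0, s$sigma_total_mm) *
      stats::dnorm(0, 0, sy$sigma_total_mm)
  }, numeric(1))
  tibble::tibble(energy_mev = energy_mev,
                 d_meas_ref = d_meas_ref_gy_per_mu,
                 d_mc_ref = d_mc,
                 protons_per_mu = d_meas_ref_gy_per_mu / d_mc)
}

#' Convert proton numbers to monitor units
#'
#' `MU = protons / (d_meas_ref / d_mc_ref)`; linear in the weight.
#'
#' @param weight_protons Number of protons (vector allowed).
#' @param calib One row of [calibration_reference()] (or any list with
#'   positive `d_meas_ref` and `d_mc_ref`).
#' @return MU.
#' @export
protons_to_mu <- function(weight_protons, calib) {
  if (any(calib$d_meas_ref <= 0) || any(calib$d_mc_ref <= 0)) {
    stop("calibration reference doses must be positive", call. = FALSE)
  }
  weight_protons * calib$d_mc_ref / calib$d_meas_ref
}

#' Remove spots below the deliverable minimum MU
#'
#' Spots with `MU < min_mu` are removed; a layer whose spots are all removed
#' is deleted from the plan. Coverage re-normalization is the caller's
#' responsibility ([optimize_plan()] re-runs it automatically).
#'
#' @param plan A `dcpt_plan` with `mu` assigned on every spot.
#' @param min_mu Minimum deliverable MU per spot.
#' @return List with `plan` (filtered) and `report`: a tibble with one row
#'   per planned layer (`layer_index`, `energy_mev`, `n_spots`, `n_removed`,
#'   `layer_dropped`).
#' @export
apply_min_mu <- function(plan, min_mu = 0.05) {
  stopifnot(inherits(plan, "dcpt_plan"))
  keep <- plan$spots$mu >= min_mu
  if (!any(keep)) stop("minimum-MU filter removed every spot", call. = FALSE)
  report <- plan$spots |>
    dplyr::mutate(kept = keep) |>
    dplyr::group_by(.data$layer_index) |>
    dplyr::summarise(n_spots = dplyr::n(),
                     n_removed = sum(!.data$kept), .groups = "drop") |>
    dplyr::mutate(layer_dropped = .data$n_removed == .data$n_spots) |>
    dplyr::left_join(plan$layers[, c("layer_index", "energy_mev")],
                     by = "layer_index") |>
    dplyr::select("layer_index", "energy_mev", "n_spots", "n_removed",
                  "layer_dropped")
  plan$spots <- plan$spots[keep, ]
  kept_layers <- unique(plan$spots$layer_index)
  plan$layers <- plan$layers[plan$layers$layer_index %in% kept_layers, ]
  list(plan = plan, report = report)
}

#' Optimize a plan end to end
#'
#' Builds the influence matrix, solves the nonnegative least-squares
#' problem, normalizes to the requested PTV coverage, converts weights to MU
#' with the energy-dependent calibration, applies the minimum-MU filter
#' (re-normalizing after removals until the delivered spot set is stable),
#' and returns the final plan, weights and dose grid.
#'
#' @param plan A `dcpt_plan`.
#' @param model A [beam_model()].
#' @param grid Optional [dose_grid()].
#' @param stride_mm,shell_mm,shell_weight Passed to
#'   [build_influence_matrix()].
#' @param coverage Coverage fraction for normalization.
#' @param min_mu Minimum deliverable MU.
#' @param d_meas_ref_gy_per_mu Calibration constant (Gy/MU).
#' @param max_sweeps,tol Solver controls.
#' @return An object of class `dcpt_plan_result`: `plan` (delivered plan
#'   with weights and MU), `dose` (final [dose_grid()], Gy), `opt`
#'   (`dcpt_opt`), `filter_report`, `coverage_scale`, `calibration`.
#' @export
optimize_plan <- function(plan, model, grid = NULL, stride_mm = 2,
                          shell_mm = 5, shell_weight = 0.1, coverage = 0.90,
                          min_mu = 0.05, d_meas_ref_gy_per_mu = 0.1,
                          max_sweeps = 2000, tol = 1e-10) {
  if (is.null(grid)) grid <- default_grid(plan, model)
  infl <- build_influence_matrix(plan, model, grid, stride_mm = stride_mm,
                                 shell_mm = shell_mm,
                                 shell_weight = shell_weight)
  opt <- optimize_weights(infl, prescription_gy = plan$prescription_gy,
                          max_sweeps = max_sweeps, tol = tol)
  plan$spots$weight <- opt$weights
  calib <- calibration_reference(model, plan$layers$energy_mev,
                                 d_meas_ref_gy_per_mu)
  dose <- compute_dose(plan, model, grid)
  scale <- normalize_coverage(dose, plan$ptv, plan$prescription_gy, coverage)
  plan$spots$weight <- plan$spots$weight * scale
  dose$values <- dose$values * scale
  # map each spot to its layer's calibration row
  calib$layer_index <- plan$layers$layer_index
  plan$spots$mu <- protons_to_mu(
    plan$spots$weight,
    calib[match(plan$spots$layer_index, calib$layer_index), ])
  filter_report <- NULL
  for (pass in 1:5) {
    filt <- apply_min_mu(plan, min_mu)
    if (is.null(filter_report)) {
      filter_report <- filt$report
    }
    removed <- nrow(plan$spots) - nrow(filt$plan$spots)
    plan <- filt$plan
    if (removed > 0) {
      dose <- compute_dose(plan, model, grid)
      scale2 <- normalize_coverage(dose, plan$ptv, plan$prescription_gy,
                                   coverage)
      plan$spots$weight <- plan$spots$weight * scale2
      plan$spots$mu <- plan$spots$mu * scale2
      dose$values <- dose$values * scale2
      scale <- scale * scale2
    } else {
      break
    }
  }
  structure(
    list(plan = plan, dose = dose, opt = opt,
         filter_report = filter_report, coverage_scale = scale,
         calibration = calib),
    class = "dcpt_plan_result"
  )
}

#' @export
print.dcpt_plan_result <- function(x, ...) {
  cat(sprintf("<dcpt_plan_result> %s: %d delivered layers, %d spots\n",
              x$plan$name, nrow(x$plan$layers), nrow(x$plan$spots)))
  dropped <- sum(x$filter_report$layer_dropped)
  if (dropped > 0) {
    cat(sprintf("  %d layer(s) dropped by the minimum-MU filter\n", dropped))
  }
  invisible(x)
}

#' @rdname optimize_plan
#' @param x A `dcpt_plan_result`.
#' @param ... Unused.
#' @export
tidy.dcpt_plan_result <- function(x, ...) {
  tidy.dcpt_plan(x$plan)
}

#' @rdname optimize_plan
#' @export
glance.dcpt_plan_result <- function(x, ...) {
  d <- ptv_doses(x$dose, x$plan$ptv)
  rx <- x$plan$prescription_gy
  tibble::tibble(
    name = x$plan$name,
    collimated = x$plan$collimated,
    n_layers_delivered = nrow(x$plan$layers),
    n_spots_delivered = nrow(x$plan$spots),
    coverage = mean(d >= rx),
    d5_gy = stats::quantile(d, 0.95, names = FALSE),
    d95_gy = stats::quantile(d, 0.05, names = FALSE),
    homogeneity = (stats::quantile(d, 0.95, names = FALSE) -
                     stats::quantile(d, 0.05, names = FALSE)) / rx,
    total_mu = sum(x$plan$spots$mu)
  )
}
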