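# Composite dose accumulation: per-layer separable evaluation of
# D(x, y, z) = sum_i w_i * IDD_i(z) * LATx_i(x, z) * LATy_i(y, z)
# plus the shallow trimmer-scatter halo, on arbitrary voxel lattices.
# The same internals serve compute_dose() (full grid) and
# build_influence_matrix() (sampled voxels), which keeps the influence
# entries exactly consistent with the composite engine.

# Voxel-averaged integral depth dose (MeV/mm) for one layer on depth
# samples z_mm. Straggling-convolved power-law stopping power; with a range
# shifter the curve is the water curve shifted by the shifter WET.
layer_idd <- function(energy_mev, model, use_range_shifter, z_mm,
                      voxel_mm = 1, nsub = 4L) {
  offset_cm <- if (use_range_shifter) model$rs_wet_cm else 0
  offs <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * voxel_mm
  zf <- as.vector(outer(offs, z_mm, `+`))
  zf[zf < 0] <- 0
  d <- bragg_vectorized(energy_mev, zf / 10 + offset_cm, model)
  0.1 * colMeans(matrix(d, nrow = nsub))  # MeV/cm -> MeV/mm
}

# Vectorized Bragg curve: expectation of the pristine stopping power over a
# Gaussian residual-range kernel (quadrature over 81 kernel nodes).
bragg_vectorized <- function(energy_mev, depth_cm, model) {
  R <- range_from_energy(energy_mev, model)
  sig <- range_sigma_cm(energy_mev, model)
  p <- model$p
  nodes <- seq(-4, 4, length.out = 81L)
  wts <- stats::dnorm(nodes)
  wts <- wts / sum(wts)
  resid <- outer(depth_cm, sig * nodes, function(z, d) R + d - z)
  S <- ifelse(resid > 0, pmax(resid, 1e-12)^(1 / p - 1), 0) /
    (p * model$alpha^(1 / p))
  as.vector(S %*% wts)
}

# Voxel-averaged lateral profile matrix: |x_eval| x |centers|, each column
# the (possibly collimated) fluence density of a spot at that depth.
lateral_matrix <- function(x_eval, centers, edge_lo, edge_hi,
                           sigma_up, sigma_down, voxel_mm = 1, nsub = 4L) {
  offs <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * voxel_mm
  xf <- as.vector(outer(offs, x_eval, `+`))
  out <- matrix(0, length(x_eval), length(centers))
  for (j in seq_along(centers)) {
    v <- collimated_lateral_profile(xf, centers[j], edge_lo, edge_hi,
                                    sigma_up, sigma_down)
    out[, j] <- colMeans(matrix(v, nrow = nsub))
  }
  out
}

# Per-layer geometry/physics bundle reused across depth slices.
layer_context <- function(layer, plan, model) {
  E <- layer$energy_mev
  offset_cm <- if (plan$use_range_shifter) model$rs_wet_cm else 0
  e_surf <- surface_energy(E, model, plan$use_range_shifter)
  r_ent_mm <- (layer$range_cm - offset_cm) * 10
  s_air <- sigma_air(E, model)
  tsd_mm <- plan$tsd_cm * 10
  theta_rs <- 0
  sigma_up_extra <- 0
  if (plan$use_range_shifter) {
    theta_rs <- range_shifter_scatter(E, model)$theta_mrad / 1000
    sigma_up_extra <- theta_rs * model$rs_exit_to_trimmer_mm
  }
  list(
    energy_mev = E, e_surf = e_surf, r_ent_mm = r_ent_mm,
    sigma_straggle_mm = range_sigma_cm(E, model) * 10,
    tsd_mm = tsd_mm,
    sad = c(x = model$virtual_sad_x_mm, y = model$virtual_sad_y_mm),
    sigma_up_iso = c(
      x = sqrt((s_air * (model$virtual_sad_x_mm - tsd_mm) /
                  model$virtual_sad_x_mm)^2 + sigma_up_extra^2),
      y = sqrt((s_air * (model$virtual_sad_y_mm - tsd_mm) /
                  model$virtual_sad_y_mm)^2 + sigma_up_extra^2)
    ),
    theta = c(
      x = sqrt((s_air / model$virtual_sad_x_mm)^2 + theta_rs^2),
      y = sqrt((s_air / model$virtual_sad_y_mm)^2 + theta_rs^2)
    ),
    edges = list(
      x = c(lo = if (layer$retracted_x1) -Inf else layer$x1_mm,
            hi = if (layer$retracted_x2) Inf else layer$x2_mm),
      y = c(lo = if (layer$retracted_y1) -Inf else layer$y1_mm,
            hi = if (layer$retracted_y2) Inf else layer$y2_mm)
    )
  )
}

# sigma_down (mm) for one layer at depths z_mm (vector), one axis.
layer_sigma_down <- function(ctx, z_mm, axis, model) {
  z_cm <- pmin(z_mm, ctx$r_ent_mm - 1e-6) / 10
  z_cm <- pmax(z_cm, 0)
  mcs <- mcs_sigma(ctx$e_surf, z_cm, model)
  sqrt((ctx$theta[[axis]] * (ctx$tsd_mm + z_mm))^2 + mcs^2)
}

#' Composite plan dose on a 3D grid
#'
#' Accumulates every weighted beamlet of the plan onto the grid:
#' depth dose times the per-axis (collimated or uncollimated) lateral
#' profiles, plus the shallow trimmer-scatter halo for engaged blades.
#' Grid values are voxel averages (the lateral profiles and the depth dose
#' are averaged over each voxel with 4 sub-samples per axis), matching a
#' voxel-scoring transport engine. Dose is linear in the beamlet weights,
#' nonnegative, and zero wherever no beamlet contributes.
#'
#' @param plan A `dcpt_plan`.
#' @param model A [beam_model()].
#' @param grid A [dose_grid()]; defaults to [default_grid()].
#' @param weights Beamlet weights (protons), one per row of `plan$spots`;
#'   defaults to the weights stored in the plan.
#' @return The grid with `values` filled in Gy.
#' @export
compute_dose <- function(plan, model, grid = NULL, weights = NULL) {
  if (is.null(grid)) grid <- default_grid(plan, model)
  if (is.null(weights)) weights <- plan$spots$weight
  stopifnot(length(weights) == nrow(plan$spots))
  if (any(weights < 0)) stop("beamlet weights must be nonnegative", call. = FALSE)
  co <- grid_coords(grid)
  xs_all <- sort(unique(plan$spots$spot_x_mm))
  ys_all <- sort(unique(plan$spots$spot_y_mm))
  lat_half <- max(abs(c(co$x, co$y)))
  if (max(abs(c(xs_all, ys_all))) > lat_half) {
    warning("beamlet outside grid; contribution clipped", call. = FALSE)
  }
  vals <- array(0, dim = grid$shape)
  for (li in seq_len(nrow(plan$layers))) {
    layer <- plan$layers[li, ]
    ctx <- layer_context(layer, plan, model)
    sel <- plan$spots$layer_index == layer$layer_index
    w <- weights[sel]
    if (all(w == 0)) next
    sp <- plan$spots[sel, ]
    W <- matrix(0, length(xs_all), length(ys_all))
    W[cbind(match(sp$spot_x_mm, xs_all), match(sp$spot_y_mm, ys_all))] <- w
    idd <- layer_idd(ctx$energy_mev, model, plan$use_range_shifter, co$z,
                     voxel_mm = grid$spacing_mm)
    active <- which(idd > max(idd) * 1e-9 &
                      co$z < ctx$r_ent_mm + 4.5 * ctx$sigma_straggle_mm)
    if (length(active) == 0) next
    sd_x <- layer_sigma_down(ctx, co$z, "x", model)
    sd_y <- layer_sigma_down(ctx, co$z, "y", model)
    halo_on <- any(is.finite(unlist(ctx$edges))) &&
      model$trimmer_halo_weight > 0
    idd_ent <- idd[1]
    for (iz in active) {
      z <- co$z[iz]
      m_x <- (ctx$sad[["x"]] + z) / ctx$sad[["x"]]
      m_y <- (ctx$sad[["y"]] + z) / ctx$sad[["y"]]
      Gx <- lateral_matrix(co$x, xs_all * m_x,
                           ctx$edges$x[["lo"]] * m_x, ctx$edges$x[["hi"]] * m_x,
                           ctx$sigma_up_iso[["x"]] * m_x, sd_x[iz],
                           voxel_mm = grid$spacing_mm)
      Gy <- lateral_matrix(co$y, ys_all * m_y,
                           ctx$edges$y[["lo"]] * m_y, ctx$edges$y[["hi"]] * m_y,
                           ctx$sigma_up_iso[["y"]] * m_y, sd_y[iz],
                           voxel_mm = grid$spacing_mm)
      slice <- DOSE_PER_PROTON_GY * idd[iz] * (Gx %*% W %*% t(Gy))
      if (halo_on) {
        slice <- slice + halo_slice(ctx, model, co$x, co$y, z, iz,
                                    xs_all, ys_all, W, Gx, Gy,
                                    sd_x, sd_y, m_x, m_y, idd_ent,
                                    grid$spacing_mm)
      }
      vals[, , iz] <- vals[, , iz] + slice
    }
  }
  grid$values <- vals
  grid
}

# Trimmer-scatter halo for one depth slice: each engaged blade re-emits a
# fraction of the fluence it intercepts as a broad Gaussian centred on the
# edge, with an entrance-like depth dose that decays over an effective
# residual range (configuration on the beam model).
halo_slice <- function(ctx, model, x_co, y_co, z, iz, xs_all, ys_all, W,
                       Gx, Gy, sd_x, sd_y, m_x, m_y, idd_ent, voxel_mm) {
  hz <- exp(-z / (model$halo_residual_range_cm * 10))
  scale <- DOSE_PER_PROTON_GY * model$trimmer_halo_weight * hz * idd_ent
  st_x <- sqrt((ctx$sigma_up_iso[["x"]] * m_x)^2 + sd_x[iz]^2)
  st_y <- sqrt((ctx$sigma_up_iso[["y"]] * m_y)^2 + sd_y[iz]^2)
  out <- matrix(0, length(x_co), length(y_co))
  hs <- model$trimmer_halo_sigma_scale
  for (side in c("lo", "hi")) {
    ex <- ctx$edges$x[[side]]
    if (is.finite(ex)) {
      f <- intercepted_fraction(xs_all, ex, ctx$sigma_up_iso[["x"]], side)
      nx <- stats::dnorm(x_co, ex * m_x, hs * st_x)
      yprof <- Gy %*% (t(W) %*% f)
      out <- out + scale * (nx %o% as.vector(yprof))
    }
    ey <- ctx$edges$y[[side]]
    if (is.finite(ey)) {
      f <- intercepted_fraction(ys_all, ey, ctx$sigma_up_iso[["y"]], side)
      ny <- stats::dnorm(y_co, ey * m_y, hs * st_y)
      xprof <- Gx %*% (W %*% f)
      out <- out + scale * (as.vector(xprof) %o% ny)
    }
  }
  out
}

# Fraction of a spot's unit fluence stopped by a blade (at the trimmer
# plane, isocenter-plane coordinates).
intercepted_fraction <- function(centers, edge, sigma_up, side) {
  if (side == "hi") {
    1 - stats::pnorm((edge - centers) / sigma_up)
  } else {
    stats::pnorm((edge - centers) / sigma_up)
  }
}
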