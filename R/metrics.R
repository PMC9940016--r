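# Dosimetric metrics: profile extraction, 80-20 lateral penumbra, SOBP
# range/width/flatness, 2D gamma analysis, surface dose-horn enhancement,
# and rigid 2D registration of measured to simulated planes.

#' 1D dose profile
#'
#' @param position_mm Strictly increasing, uniformly spaced positions (mm).
#' @param value Nonnegative dose values (Gy or relative).
#' @param axis Axis label (`"x"`, `"y"` or `"z"`).
#' @return A tibble of class `dcpt_profile` with columns `position_mm`,
#'   `value`.
#' @export
dose_profile <- function(position_mm, value, axis = "x") {
  stopifnot(length(position_mm) == length(value), length(position_mm) >= 2)
  dp <- diff(position_mm)
  if (any(dp <= 0) || diff(range(dp)) > 1e-6 * mean(dp)) {
    stop("profile positions must be strictly increasing and uniform",
         call. = FALSE)
  }
  out <- tibble::tibble(position_mm = as.numeric(position_mm),
                        value = as.numeric(value))
  class(out) <- c("dcpt_profile", class(out))
  attr(out, "axis") <- axis
  out
}

# Bilinear interpolation on a dcpt_plane; NA outside the domain.
interp_plane <- function(plane, xq, yq) {
  x <- plane$x_mm; y <- plane$y_mm; v <- plane$values
  nx <- length(x); ny <- length(y)
  ix <- findInterval(xq, x)
  iy <- findInterval(yq, y)
  out <- rep(NA_real_, length(xq))
  ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
  # allow exact upper boundary
  at_xmax <- xq == x[nx] & iy >= 1 & iy < ny
  at_ymax <- yq == y[ny] & ix >= 1 & ix < nx
  ix2 <- pmin(pmax(ix, 1), nx - 1)
  iy2 <- pmin(pmax(iy, 1), ny - 1)
  okk <- ok | at_xmax | at_ymax | (xq == x[nx] & yq == y[ny])
  ixk <- ix2[okk]; iyk <- iy2[okk]
  tx <- (xq[okk] - x[ixk]) / (x[ixk + 1] - x[ixk])
  ty <- (yq[okk] - y[iyk]) / (y[iyk + 1] - y[iyk])
  v11 <- v[cbind(ixk, iyk)]
  v21 <- v[cbind(ixk + 1, iyk)]
  v12 <- v[cbind(ixk, iyk + 1)]
  v22 <- v[cbind(ixk + 1, iyk + 1)]
  out[okk] <- (1 - tx) * (1 - ty) * v11 + tx * (1 - ty) * v21 +
    (1 - tx) * ty * v12 + tx * ty * v22
  out
}

#' Extract a 1D profile from a dose grid or plane
#'
#' Lines are interpolated linearly between voxel centers. For a grid,
#' `axis = "x"`/`"y"` extracts a lateral profile at depth `depth_mm`
#' through `at_mm` on the other lateral axis; `axis = "z"` extracts the
#' depth dose at lateral position `at_mm` (length 2, x and y). For a plane,
#' `axis = "x"`/`"y"` with `at_mm` on the other axis.
#'
#' @param obj A [dose_grid()] or [dose_plane()].
#' @param axis `"x"`, `"y"` or `"z"` (grid only).
#' @param at_mm Fixed coordinate(s) of the line.
#' @param depth_mm Depth of a lateral profile (grid only).
#' @param step_mm Optional resampling step; default keeps the native
#'   spacing.
#' @return A [dose_profile()].
#' @export
extract_profile <- function(obj, axis = "x", at_mm = 0, depth_mm = NULL,
                            step_mm = NULL) {
  if (inherits(obj, "dcpt_dose_grid")) {
    co <- grid_coords(obj)
    if (axis %in% c("x", "y")) {
      if (is.null(depth_mm)) stop("depth_mm required for lateral profiles",
                                  call. = FALSE)
      plane <- extract_plane(obj, depth_mm)
      return(extract_profile(plane, axis = axis, at_mm = at_mm,
                             step_mm = step_mm))
    }
    if (axis != "z") stop("axis must be x, y or z", call. = FALSE)
    at_mm <- rep(at_mm, length.out = 2)
    pos <- co$z
    if (!is.null(step_mm)) pos <- seq(min(co$z), max(co$z), by = step_mm)
    vals <- vapply(pos, function(z) {
      pl <- extract_plane(obj, z)
      interp_plane(pl, at_mm[1], at_mm[2])
    }, numeric(1))
    return(dose_profile(pos, vals, axis = "z"))
  }
  stopifnot(inherits(obj, "dcpt_plane"))
  if (axis == "x") {
    pos <- obj$x_mm
    if (!is.null(step_mm)) pos <- seq(min(obj$x_mm), max(obj$x_mm), by = step_mm)
    vals <- interp_plane(obj, pos, rep(at_mm, length(pos)))
  } else if (axis == "y") {
    pos <- obj$y_mm
    if (!is.null(step_mm)) pos <- seq(min(obj$y_mm), max(obj$y_mm), by = step_mm)
    vals <- interp_plane(obj, rep(at_mm, length(pos)), pos)
  } else {
    stop("axis must be x or y for planes", call. = FALSE)
  }
  if (anyNA(vals)) stop("requested line lies outside the grid", call. = FALSE)
  dose_profile(pos, vals, axis = axis)
}

# First crossing of `level` moving outward from index `start` in direction
# `dir` (+1/-1); linear interpolation between samples.
crossing_position <- function(pos, val, level, start, dir) {
  i <- start
  n <- length(val)
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if ((val[i] - level) * (val[j] - level) <= 0 && val[i] != val[j]) {
      t <- (level - val[i]) / (val[j] - val[i])
      return(pos[i] + t * (pos[j] - pos[i]))
    }
    i <- j
  }
  NA_real_
}

# Plateau normalization value: mean over the central 50% of the region
# between the outermost half-maximum crossings.
plateau_norm <- function(pos, val) {
  vmax <- max(val)
  imax <- which.max(val)
  xl <- crossing_position(pos, val, vmax / 2, imax, -1L)
  xr <- crossing_position(pos, val, vmax / 2, imax, +1L)
  if (is.na(xl) || is.na(xr)) return(NA_real_)
  width <- xr - xl
  sel <- pos >= xl + width / 4 & pos <= xr - width / 4
  if (!any(sel)) return(vmax)
  mean(val[sel])
}

#' 80-20 lateral penumbra width
#'
#' Width between the 80% and 20% crossings of a field edge, relative to the
#' plateau normalization (mean of the central 50% of the region between the
#' half-maximum crossings; central-axis value and profile maximum are
#' selectable alternatives). Crossing positions are found by linear
#' interpolation between samples, scanning outward from the plateau center.
#'
#' @param profile A [dose_profile()].
#' @param side `"left"` or `"right"` field edge.
#' @param normalization `"plateau"` (default), `"center"` (value at the
#'   plateau midpoint) or `"max"`.
#' @return Penumbra width (mm).
#' @export
penumbra_80_20 <- function(profile, side = c("right", "left"),
                           normalization = c("plateau", "center", "max")) {
  side <- match.arg(side)
  normalization <- match.arg(normalization)
  pos <- profile$position_mm
  val <- profile$value
  vmax <- max(val)
  imax <- which.max(val)
  xl <- crossing_position(pos, val, vmax / 2, imax, -1L)
  xr <- crossing_position(pos, val, vmax / 2, imax, +1L)
  if ((is.na(xl) || is.na(xr)) && normalization != "max") {
    stop("profile has no identifiable plateau", call. = FALSE)
  }
  norm <- switch(normalization,
                 plateau = plateau_norm(pos, val),
                 center = stats::approx(pos, val, xout = (xl + xr) / 2)$y,
                 max = vmax)
  # edge-anchored search: scan inward from the profile tail so interior
  # ripple or edge horns cannot masquerade as the field edge
  n <- length(val)
  start <- if (side == "right") n else 1L
  dir <- if (side == "right") -1L else +1L
  x20 <- crossing_position(pos, val, 0.2 * norm, start, dir)
  if (is.na(x20)) {
    stop("profile does not cross the 20% level on the requested side",
         call. = FALSE)
  }
  # resume the 80% search from just outside the 20% crossing so that both
  # levels may be found on the same steep segment
  i20 <- if (side == "right") {
    min(which(pos >= x20))
  } else {
    max(which(pos <= x20))
  }
  x80 <- crossing_position(pos, val, 0.8 * norm, i20, dir)
  if (is.na(x80)) {
    stop("profile does not cross the 80% level on the requested side",
         call. = FALSE)
  }
  abs(x20 - x80)
}

#' Plan-level 80-20 penumbra at a depth
#'
#' Mean of the four field edges (left and right of the two central in-plane
#' profiles), the aggregation used for single-number plan penumbras.
#'
#' @param dose A [dose_grid()] (or a `dcpt_plan_result`).
#' @param depth_mm Evaluation depth (mm).
#' @param normalization Passed to [penumbra_80_20()].
#' @return Tibble with the four edge widths and their mean `penumbra_mm`.
#' @export
plan_penumbra <- function(dose, depth_mm, normalization = "plateau") {
  if (inherits(dose, "dcpt_plan_result")) dose <- dose$dose
  px <- extract_profile(dose, "x", at_mm = 0, depth_mm = depth_mm)
  py <- extract_profile(dose, "y", at_mm = 0, depth_mm = depth_mm)
  w <- c(x_left = penumbra_80_20(px, "left", normalization),
         x_right = penumbra_80_20(px, "right", normalization),
         y_left = penumbra_80_20(py, "left", normalization),
         y_right = penumbra_80_20(py, "right", normalization))
  tibble::tibble(depth_mm = depth_mm,
                 x_left_mm = w[["x_left"]], x_right_mm = w[["x_right"]],
                 y_left_mm = w[["y_left"]], y_right_mm = w[["y_right"]],
                 penumbra_mm = mean(w))
}

#' SOBP range, width and flatness from a depth-dose profile
#'
#' The plateau level is the mean of all samples at or above 90% of the
#' maximum. Range is the distal depth where the dose falls to 90% of that
#' level, width the distance between the proximal and distal 90% crossings
#' (searched outward from the maximum), and flatness
#' `(max - min) / (max + min)` over the plateau between those crossings.
#' Crossings use linear interpolation.
#'
#' @param depth_dose A [dose_profile()] along z.
#' @return Tibble with `range_cm`, `width_cm`, `flatness`.
#' @export
sobp_metrics <- function(depth_dose) {
  pos <- depth_dose$position_mm
  val <- depth_dose$value
  sel <- val >= 0.9 * max(val)
  if (sum(sel) < 2) stop("depth dose has no plateau", call. = FALSE)
  norm <- mean(val[sel])
  imax <- which.max(val)
  distal <- crossing_position(pos, val, 0.9 * norm, imax, +1L)
  proximal <- crossing_position(pos, val, 0.9 * norm, imax, -1L)
  if (is.na(distal) || is.na(proximal)) {
    stop("depth dose does not cross the 90% level on both sides",
         call. = FALSE)
  }
  sel <- pos >= proximal & pos <= distal
  fl <- (max(val[sel]) - min(val[sel])) / (max(val[sel]) + min(val[sel]))
  tibble::tibble(range_cm = distal / 10,
                 width_cm = (distal - proximal) / 10,
                 flatness = fl)
}

# ---- 2D gamma analysis ------------------------------------------------------

#' Gamma analysis criteria
#'
#' @param dose_difference_pct Dose-difference criterion (% of the
#'   normalization value).
#' @param distance_to_agreement_mm Distance-to-agreement criterion (mm).
#' @param low_dose_threshold_pct Points of the evaluated plane below this
#'   percentage of the normalization value are excluded.
#' @param normalization `"plateau"` (mean of evaluated-plane values at or
#'   above 90% of its maximum, the relative-dosimetry mode) or
#'   `"prescription"` (caller supplies `norm_value`).
#' @return A list of class `dcpt_gamma_criteria`.
#' @export
gamma_criteria <- function(dose_difference_pct = 2,
                           distance_to_agreement_mm = 2,
                           low_dose_threshold_pct = 5,
                           normalization = c("plateau", "prescription")) {
  stopifnot(dose_difference_pct > 0, distance_to_agreement_mm > 0,
            low_dose_threshold_pct > 0)
  structure(list(dose_difference_pct = dose_difference_pct,
                 distance_to_agreement_mm = distance_to_agreement_mm,
                 low_dose_threshold_pct = low_dose_threshold_pct,
                 normalization = match.arg(normalization)),
            class = "dcpt_gamma_criteria")
}

#' Relative 2D gamma pass rate
#'
#' Gamma is evaluated at every evaluated-plane point at or above the low
#' dose threshold; the reference plane is interpolated to a 0.2 mm search
#' lattice and searched within 3 times the DTA. Dose differences are global
#' (relative to the normalization value). Pass is `gamma <= 1`. Gamma is not
#' symmetric under swapping reference and evaluated planes (thresholding and
#' search direction both break the symmetry).
#'
#' @param reference,evaluated [dose_plane()] objects; lattices need not
#'   match.
#' @param criteria A [gamma_criteria()].
#' @param norm_value Normalization dose; required for
#'   `normalization = "prescription"`, otherwise computed from the
#'   evaluated plane.
#' @return A list of class `dcpt_gamma`: `pass_rate_pct`, `n_evaluable`,
#'   `n_pass`, `mean_gamma`, `criteria`, and `gamma` (matrix over the
#'   evaluated lattice, NA below threshold).
#' @export
gamma_2d <- function(reference, evaluated, criteria = gamma_criteria(),
                     norm_value = NULL) {
  stopifnot(inherits(reference, "dcpt_plane"), inherits(evaluated, "dcpt_plane"))
  if (is.null(norm_value)) {
    if (criteria$normalization == "prescription") {
      stop("norm_value required for prescription normalization", call. = FALSE)
    }
    ev <- evaluated$values
    norm_value <- mean(ev[ev >= 0.9 * max(ev)])
  }
  dd <- criteria$dose_difference_pct / 100 * norm_value
  dta <- criteria$distance_to_agreement_mm
  thr <- criteria$low_dose_threshold_pct / 100 * norm_value
  search_mm <- 3 * dta
  fine <- 0.2
  fx <- seq(min(reference$x_mm), max(reference$x_mm), by = fine)
  fy <- seq(min(reference$y_mm), max(reference$y_mm), by = fine)
  fref <- outer(fx, fy, function(x, y) interp_plane(reference, x, y))
  ex <- evaluated$x_mm; ey <- evaluated$y_mm
  gam <- matrix(NA_real_, length(ex), length(ey))
  win <- round(search_mm / fine)
  offs <- seq(-win, win)
  dist2 <- outer(offs, offs, function(a, b) (a * fine)^2 + (b * fine)^2)
  mask <- dist2 <= search_mm^2
  for (j in seq_along(ey)) {
    for (i in seq_along(ex)) {
      de <- evaluated$values[i, j]
      if (de < thr) next
      ci <- round((ex[i] - fx[1]) / fine) + 1
      cj <- round((ey[j] - fy[1]) / fine) + 1
      ii <- ci + offs
      jj <- cj + offs
      iok <- ii >= 1 & ii <= length(fx)
      jok <- jj >= 1 & jj <= length(fy)
      if (!any(iok) || !any(jok)) {
        gam[i, j] <- Inf
        next
      }
      sub <- fref[ii[iok], jj[jok], drop = FALSE]
      g2 <- (sub - de)^2 / dd^2 + dist2[iok, jok] / dta^2
      g2[!mask[iok, jok]] <- Inf
      gam[i, j] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  evaluable <- !is.na(gam)
  if (!any(evaluable)) stop("no evaluable points above the dose threshold",
                            call. = FALSE)
  structure(
    list(pass_rate_pct = 100 * mean(gam[evaluable] <= 1),
         n_evaluable = sum(evaluable), n_pass = sum(gam[evaluable] <= 1),
         mean_gamma = mean(gam[evaluable]), criteria = criteria,
         norm_value = norm_value, gamma = gam),
    class = "dcpt_gamma"
  )
}

#' @export
print.dcpt_gamma <- function(x, ...) {
  cat(sprintf(
    "<dcpt_gamma> %.1f%% pass (%d/%d points), criteria %g%%/%g mm/%g%% threshold\n",
    x$pass_rate_pct, x$n_pass, x$n_evaluable,
    x$criteria$dose_difference_pct, x$criteria$distance_to_agreement_mm,
    x$criteria$low_dose_threshold_pct))
  invisible(x)
}

# ---- surface dose-horn enhancement ------------------------------------------

#' Surface dose-horn enhancement at shallow depth
#'
#' At the requested depth plane, the maximum dose is located on each side of
#' the projected field edge for both central in-plane profiles (four
#' evaluated points per distribution), expressed as a percentage of the
#' prescription. The enhancement is the collimated minus the uncollimated
#' average; its standard deviation combines both in quadrature.
#'
#' @param uncollimated,collimated [dose_grid()]s of the two plan variants,
#'   both coverage-normalized.
#' @param ptv A [ptv_spec()] (defines the field edge).
#' @param prescription_gy Prescription (Gy).
#' @param depth_mm Evaluation depth (mm).
#' @param outside_mm,inside_mm Horn search window around the field edge (mm
#'   outside / inside the edge).
#' @return Tibble with `uncollimated_pct`, `uncollimated_sd`,
#'   `collimated_pct`, `collimated_sd`, `enhancement_pct`,
#'   `enhancement_sd`.
#' @export
surface_enhancement <- function(uncollimated, collimated, ptv,
                                prescription_gy = 5, depth_mm = 5,
                                outside_mm = 10, inside_mm = 5) {
  horn_points <- function(dose) {
    co <- grid_coords(dose)
    if (depth_mm < co$z[1] || depth_mm > max(co$z)) {
      stop("grid does not cover the evaluation depth", call. = FALSE)
    }
    half <- ptv$side_mm / 2
    px <- extract_profile(dose, "x", at_mm = 0, depth_mm = depth_mm)
    py <- extract_profile(dose, "y", at_mm = 0, depth_mm = depth_mm)
    vapply(list(list(p = px, s = -1), list(p = px, s = +1),
                list(p = py, s = -1), list(p = py, s = +1)),
           function(e) {
             lo <- e$s * half - inside_mm * e$s
             hi <- e$s * half + outside_mm * e$s
             sel <- e$p$position_mm >= min(lo, hi) &
               e$p$position_mm <= max(lo, hi)
             max(e$p$value[sel])
           }, numeric(1)) / prescription_gy * 100
  }
  u <- horn_points(uncollimated)
  c_ <- horn_points(collimated)
  tibble::tibble(
    uncollimated_pct = mean(u), uncollimated_sd = stats::sd(u),
    collimated_pct = mean(c_), collimated_sd = stats::sd(c_),
    enhancement_pct = mean(c_) - mean(u),
    enhancement_sd = sqrt(stats::var(u) + stats::var(c_))
  )
}

# ---- rigid 2D registration --------------------------------------------------

# Sample a plane at rotated+shifted coordinates: value at R(theta) x + t.
sample_transformed <- function(plane, xg, yg, rotation_deg, shift_mm) {
  th <- rotation_deg * pi / 180
  xq <- cos(th) * xg - sin(th) * yg + shift_mm[1]
  yq <- sin(th) * xg + cos(th) * yg + shift_mm[2]
  interp_plane(plane, xq, yq)
}

#' Rigid 2D registration of a measured to a simulated plane
#'
#' Finds the rotation and translation that minimize the mean squared
#' difference between the transformed measured plane and the simulated
#' plane, by coarse grid search (rotation within +/- 3 degrees, shifts
#' within +/- 10 mm) followed by Nelder-Mead refinement. Deterministic for
#' given inputs.
#'
#' @param measured,simulated [dose_plane()] objects with overlapping fields
#'   of view.
#' @param rotation_window_deg,shift_window_mm Search half-windows.
#' @return A list of class `dcpt_registration`: `rotation_deg`,
#'   `shift_x_mm`, `shift_y_mm`, `mse`, and `registered` (the measured
#'   plane resampled onto the simulated lattice).
#' @export
register_2d <- function(measured, simulated, rotation_window_deg = 3,
                        shift_window_mm = 10) {
  sx <- simulated$x_mm; sy <- simulated$y_mm
  xg <- matrix(sx, length(sx), length(sy))
  yg <- matrix(sy, length(sx), length(sy), byrow = TRUE)
  sv <- simulated$values
  sub <- seq(1, length(sx) * length(sy), by = 2L)
  objective <- function(par, subsample = TRUE) {
    v <- sample_transformed(measured, xg, yg, par[1], par[2:3])
    idx <- if (subsample) sub else seq_along(v)
    dv <- v[idx] - sv[idx]
    ok <- !is.na(dv)
    if (mean(ok) < 0.5) return(Inf)
    mean(dv[ok]^2)
  }
  rots <- seq(-rotation_window_deg, rotation_window_deg, by = 1)
  shifts <- seq(-shift_window_mm, shift_window_mm, by = 2)
  best <- NULL
  best_val <- Inf
  for (r in rots) for (dx in shifts) for (dy in shifts) {
    v <- objective(c(r, dx, dy))
    if (v < best_val) {
      best_val <- v
      best <- c(r, dx, dy)
    }
  }
  if (!is.finite(best_val)) {
    stop("measured and simulated planes do not overlap", call. = FALSE)
  }
  ref <- stats::optim(best, objective, subsample = FALSE,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 1000))
  reg_vals <- sample_transformed(measured, xg, yg, ref$par[1], ref$par[2:3])
  structure(
    list(rotation_deg = ref$par[1], shift_x_mm = ref$par[2],
         shift_y_mm = ref$par[3], mse = ref$value,
         registered = dose_plane(sx, sy, matrix(reg_vals, length(sx)))),
    class = "dcpt_registration"
  )
}

#' @export
print.dcpt_registration <- function(x, ...) {
  cat(sprintf(
    "<dcpt_registration> rotation %.3f deg, shift (%.3f, %.3f) mm, mse %.4g\n",
    x$rotation_deg, x$shift_x_mm, x$shift_y_mm, x$mse))
  invisible(x)
}
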