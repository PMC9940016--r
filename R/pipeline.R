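# End-to-end drivers: optimize the catalog, tabulate penumbra versus depth
# and versus trimmer-to-surface distance, and summarize surface enhancement
# -- the package's "reproduce the study conditions" entry point.

#' Optimize one catalog plan and report its mid-target penumbra
#'
#' Convenience wrapper: build, optimize and measure a single plan variant.
#'
#' @param name Catalog plan name.
#' @param model A [beam_model()].
#' @param collimated Logical.
#' @param tsd_cm Trimmer-to-surface distance (cm).
#' @param ... Passed to [optimize_plan()].
#' @return A `dcpt_plan_result` with an extra `penumbra` element (tibble
#'   from [plan_penumbra()] at the target center depth).
#' @export
run_catalog_plan <- function(name, model, collimated = TRUE, tsd_cm = 5,
                             ...) {
  plan <- build_plan(name, model, tsd_cm = tsd_cm, collimated = collimated)
  res <- optimize_plan(plan, model, ...)
  res$penumbra <- plan_penumbra(res$dose, plan$ptv$center_depth_cm * 10)
  res
}

#' Penumbra-versus-depth slope for the non-range-shifted plans
#'
#' Least-squares slope of the plan-level collimated 80-20 penumbra at
#' mid-target depth against target depth (cm of water).
#'
#' @param results Named list of `dcpt_plan_result`s (one per depth).
#' @return Tibble with `depth_cm`, `penumbra_mm` per plan plus the fitted
#'   `slope_mm_per_cm` and `intercept_mm` replicated on each row.
#' @export
penumbra_depth_trend <- function(results) {
  tab <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(name = r$plan$name,
                   depth_cm = r$plan$ptv$center_depth_cm,
                   penumbra_mm = r$penumbra$penumbra_mm)
  }))
  fit <- stats::lm(penumbra_mm ~ depth_cm, data = tab)
  tab$slope_mm_per_cm <- stats::coef(fit)[["depth_cm"]]
  tab$intercept_mm <- stats::coef(fit)[["(Intercept)"]]
  tab
}

#' Reproduce the catalog study conditions
#'
#' Optimizes the uncollimated and collimated variants of every catalog plan
#' at the reference trimmer-to-surface distance, evaluates the mid-target
#' penumbras and the shallow-depth surface enhancement, and (optionally)
#' sweeps the trimmer-to-surface distance for the range-shifted and one
#' non-range-shifted plan.
#'
#' @param model A [beam_model()].
#' @param tsd_cm Reference trimmer-to-surface distance (cm).
#' @param tsd_sweep_cm TSD values for the sweep (set `NULL` to skip).
#' @param names Catalog plan names to include.
#' @param ... Passed to [optimize_plan()].
#' @return A list of class `dcpt_reproduction`: `penumbra` (per plan and
#'   variant), `trend` (collimated NRS slope), `enhancement` (per plan),
#'   `tsd` (penumbra vs TSD), `results` (all `dcpt_plan_result`s).
#' @export
reproduce_catalog <- function(model = beam_model(), tsd_cm = 5,
                              tsd_sweep_cm = c(5, 10, 18.15),
                              names = plan_catalog()$name, ...) {
  cat_tab <- plan_catalog()
  cat_tab <- cat_tab[cat_tab$name %in% names, ]
  results <- list()
  pen_rows <- list()
  enh_rows <- list()
  for (i in seq_len(nrow(cat_tab))) {
    nm <- cat_tab$name[i]
    for (coll in c(FALSE, TRUE)) {
      key <- paste0(nm, if (coll) "/coll" else "/uncoll")
      results[[key]] <- run_catalog_plan(nm, model, collimated = coll,
                                         tsd_cm = tsd_cm, ...)
      pen_rows[[key]] <- tibble::tibble(
        name = nm, collimated = coll,
        depth_cm = cat_tab$center_depth_cm[i],
        n_layers_delivered = nrow(results[[key]]$plan$layers),
        n_candidate_beamlets = nrow(build_plan(nm, model)$spots),
        penumbra_mm = results[[key]]$penumbra$penumbra_mm)
    }
    ptv <- results[[paste0(nm, "/coll")]]$plan$ptv
    enh_rows[[nm]] <- dplyr::bind_cols(
      tibble::tibble(name = nm, depth_cm = cat_tab$center_depth_cm[i]),
      surface_enhancement(results[[paste0(nm, "/uncoll")]]$dose,
                          results[[paste0(nm, "/coll")]]$dose, ptv))
  }
  pen <- dplyr::bind_rows(pen_rows)
  nrs <- grep("/coll$", names(results), value = TRUE)
  nrs <- nrs[!vapply(results[nrs], function(r) r$plan$use_range_shifter,
                     logical(1))]
  trend <- if (length(nrs) >= 2) penumbra_depth_trend(results[nrs]) else NULL
  tsd_tab <- NULL
  if (!is.null(tsd_sweep_cm)) {
    sweep_names <- intersect(c("C3-D5-RS", "C3-D6-NRS"), cat_tab$name)
    rows <- list()
    for (nm in sweep_names) {
      for (tsd in tsd_sweep_cm) {
        key <- paste0(nm, "/coll")
        r <- if (tsd == tsd_cm && key %in% names(results)) {
          results[[key]]
        } else {
          run_catalog_plan(nm, model, collimated = TRUE, tsd_cm = tsd, ...)
        }
        rows[[paste(nm, tsd)]] <- tibble::tibble(
          name = nm, tsd_cm = tsd, penumbra_mm = r$penumbra$penumbra_mm)
      }
    }
    tsd_tab <- dplyr::bind_rows(rows)
  }
  structure(list(penumbra = pen, trend = trend,
                 enhancement = dplyr::bind_rows(enh_rows),
                 tsd = tsd_tab, results = results),
            class = "dcpt_reproduction")
}

#' @export
print.dcpt_reproduction <- function(x, ...) {
  cat("<dcpt_reproduction>\n\nPenumbra (80-20, mid-target):\n")
  print(as.data.frame(x$penumbra), row.names = FALSE)
  if (!is.null(x$trend)) {
    cat(sprintf("\nCollimated NRS penumbra-depth slope: %.3f mm/cm\n",
                x$trend$slope_mm_per_cm[1]))
  }
  cat("\nSurface enhancement at 5 mm depth (% of prescription):\n")
  print(as.data.frame(x$enhancement), row.names = FALSE)
  if (!is.null(x$tsd)) {
    cat("\nPenumbra vs trimmer-to-surface distance:\n")
    print(as.data.frame(x$tsd), row.names = FALSE)
  }
  invisible(x)
}

# ---- plotting ---------------------------------------------------------------

#' Plot a dose profile
#'
#' @param object A [dose_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcpt_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_mm,
                                       y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s position (mm)",
                              attr(object, "axis") %||% "x"),
                  y = "dose") +
    ggplot2::theme_minimal()
}

#' Plot a 2D dose plane
#'
#' @param object A [dose_plane()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcpt_plane <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "dose") +
    ggplot2::theme_minimal()
}

#' Plot penumbra versus depth and versus TSD for a reproduction run
#'
#' @param object A `dcpt_reproduction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dcpt_reproduction <- function(object, ...) {
  ggplot2::ggplot(object$penumbra,
                  ggplot2::aes(x = .data$depth_cm, y = .data$penumbra_mm,
                               colour = .data$collimated,
                               group = .data$collimated)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "target center depth (cm)",
                  y = "80-20 penumbra (mm)", colour = "collimated") +
    ggplot2::theme_minimal()
}
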