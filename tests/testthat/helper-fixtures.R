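# Shared fixtures: a default beam model, a small toy cube plan for fast
# engine/optimizer tests, and a lazy cache of full catalog optimizations so
# the acceptance tests share the expensive runs.

fixture_model <- function(...) beam_model(...)

# 6 mm cube at 5 cm depth: 3 x 3 spots, 4 energy layers, 36 beamlets
# (73.7-83.6 MeV, inside the default in-air sigma table domain).
toy_plan <- function(model = fixture_model(), collimated = TRUE,
                     tsd_cm = 5) {
  build_plan("toy", model, tsd_cm = tsd_cm, collimated = collimated,
             ptv = ptv_spec(side_mm = 6, center_depth_cm = 5))
}

toy_grid <- function(plan, model) {
  default_grid(plan, model, lateral_half_mm = 20)
}

.catalog_cache <- new.env(parent = emptyenv())

# Optimized catalog plan variant, memoised across test files.
catalog_result <- function(name, collimated = TRUE, tsd_cm = 5) {
  key <- paste(name, collimated, tsd_cm, sep = "/")
  if (is.null(.catalog_cache[[key]])) {
    .catalog_cache[[key]] <- run_catalog_plan(name, fixture_model(),
                                              collimated = collimated,
                                              tsd_cm = tsd_cm)
  }
  .catalog_cache[[key]]
}

catalog_depth_mm <- function(name) {
  cat_tab <- plan_catalog()
  cat_tab$center_depth_cm[cat_tab$name == name] * 10
}

# Symmetric field with error-function edges at +/- `edge_mm`, blurred with
# `sigma_mm`; the plateau sits well above half-maximum so the penumbra
# metric sees a proper field.
erf_edge_profile <- function(sigma_mm, edge_mm = 15, step_mm = 0.1,
                             half_mm = 40, plateau = 1) {
  x <- seq(-half_mm, half_mm, by = step_mm)
  v <- plateau * stats::pnorm((edge_mm - x) / sigma_mm) *
    stats::pnorm((x + edge_mm) / sigma_mm)
  dose_profile(x, v)
}
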