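# Spot lattice placement, energy layer selection, trimmer positioning and
# plan assembly.

test_that("the cover rule reproduces the catalog lattice combinatorics", {
  m <- fixture_model()
  ptv <- ptv_spec(side_mm = 30, center_depth_cm = 6)
  spots <- place_spots(ptv, 3)
  expect_equal(nrow(spots), 169)   # 13 x 13
  plan <- build_plan("C3-D6-NRS", m)
  expect_equal(nrow(plan$spots), 2028)
  expect_equal(nrow(plan$layers), 12)
  small <- ptv_spec(side_mm = 6, center_depth_cm = 3, lateral_margin_mm = 0)
  expect_equal(nrow(place_spots(small, 3)), 9)
  expect_equal(nrow(place_spots(small, 10)), 1)
  expect_equal(place_spots(small, 10)$spot_x_mm, 0)
  expect_error(place_spots(ptv, 0), "positive")
  expect_error(ptv_spec(side_mm = 30, center_depth_cm = 1.5), "submerged")
})

test_that("energy layer selection reproduces the catalog spans", {
  m <- fixture_model()
  d6 <- select_energy_layers(ptv_spec(30, 6), m)
  expect_equal(nrow(d6), 12)
  expect_equal(max(d6$energy_mev), 100.6, tolerance = 0.02 * 100.6)
  expect_equal(min(d6$energy_mev), 71.4, tolerance = 0.02 * 71.4)
  expect_equal(diff(range(d6$range_cm)), 3.5)
  d15 <- select_energy_layers(ptv_spec(30, 15), m)
  expect_equal(nrow(d15), 12)
  expect_equal(max(d15$energy_mev), 155.7, tolerance = 0.02 * 155.7)
  expect_equal(min(d15$energy_mev), 136.2, tolerance = 0.02 * 136.2)
  expect_true(all(diff(d6$energy_mev) < 0))  # distal to proximal
  # floor-rule tie-break: a span that divides exactly gives n = span/s + 1
  p30 <- ptv_spec(30, 6, depth_margin_mm = 0)  # span exactly 30 mm
  expect_equal(nrow(select_energy_layers(p30, m, 3)), 11)
  shallow <- ptv_spec(6, 3)
  shallow$center_depth_cm <- 0.2   # too shallow to reach without a shifter
  expect_error(select_energy_layers(shallow, m), "range shifter")
})

test_that("range-shifted selection adds the shifter WET to both range ends", {
  m <- fixture_model()
  rs <- select_energy_layers(ptv_spec(30, 5), m, use_range_shifter = TRUE)
  expect_equal(nrow(rs), 12)
  expect_equal(max(rs$range_cm), 5 + 1.5 + 0.25 + m$rs_wet_cm)
  expect_equal(min(rs$range_cm), 5 - 1.5 - 0.25 + m$rs_wet_cm)
})

test_that("trimmer edges follow the divergence projection", {
  m <- fixture_model()
  ptv <- ptv_spec(30, 6)
  # parallel-beam limit
  mp <- fixture_model(virtual_sad_x_mm = 1e9, virtual_sad_y_mm = 1e9)
  tp <- position_trimmers(6, ptv, mp)
  expect_equal(tp$x2_mm, 15, tolerance = 1e-6)
  # similar triangles at SAD 2000 mm, Bragg depth 60 mm
  tr <- position_trimmers(6, ptv, m)
  expect_equal(tr$x2_mm, 15 * 2000 / 2060, tolerance = 1e-9)
  expect_equal(tr$x1_mm, -tr$x2_mm)
  expect_equal(tr$y2_mm, 15 * 1900 / 1960, tolerance = 1e-9)
  expect_false(any(unlist(tr[, 5:8])))
  # retraction beyond travel
  big <- ptv_spec(side_mm = 200, center_depth_cm = 12, lateral_margin_mm = 0)
  expect_message(tb <- position_trimmers(12, big, m), "retracted")
  expect_true(tb$retracted_x2)
  # uncollimated plans retract every blade
  tu <- position_trimmers(6, ptv, m, engaged = FALSE)
  expect_true(all(unlist(tu[, 5:8])))
})

test_that("trimmer isocenter-plane edges shrink with layer depth", {
  m <- fixture_model()
  plan <- build_plan("C3-D6-NRS", m)
  # layer 1 is distal (deepest) so its projected edge is the smallest
  expect_true(all(diff(plan$layers$x2_mm) > 0))
  expect_true(all(diff(abs(plan$layers$x1_mm)) > 0))
})

test_that("plan assembly is consistent across layers and variants", {
  m <- fixture_model()
  pc <- build_plan("C3-D10-NRS", m, collimated = TRUE)
  pu <- build_plan("C3-D10-NRS", m, collimated = FALSE)
  # identical spot lattice in every layer
  lat <- split(pc$spots[, c("spot_x_mm", "spot_y_mm")], pc$spots$layer_index)
  for (l in lat[-1]) expect_equal(l, lat[[1]], ignore_attr = TRUE)
  # collimated and uncollimated variants share beamlets
  expect_equal(pc$spots, pu$spots)
  expect_equal(pc$layers$energy_mev, pu$layers$energy_mev)
  expect_true(all(unlist(pu$layers[, grep("retracted", names(pu$layers))])))
  expect_error(build_plan("C3-D42-NRS", m), "valid catalog names")
  expect_error(build_plan("C3-D6-NRS", m, tsd_cm = 30), "tsd_cm")
})

test_that("plans survive a serialization round trip", {
  m <- fixture_model()
  plan <- build_plan("C3-D5-RS", m, tsd_cm = 10)
  plan$spots$weight <- seq_len(nrow(plan$spots))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  plan2 <- read_plan(path)
  expect_equal(plan2$name, plan$name)
  expect_equal(plan2$tsd_cm, 10)
  expect_true(plan2$use_range_shifter)
  expect_equal(plan2$layers, plan$layers, tolerance = 1e-12)
  expect_equal(plan2$spots, plan$spots, tolerance = 1e-12)
  expect_equal(unclass(plan2$ptv), unclass(plan$ptv))
})

test_that("tidy() joins spots with their layer energies", {
  m <- fixture_model()
  plan <- toy_plan(m)
  td <- tidy(plan)
  expect_true(all(c("spot_x_mm", "energy_mev", "range_cm") %in% names(td)))
  expect_equal(nrow(td), nrow(plan$spots))
})
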