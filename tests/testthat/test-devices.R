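test_that("URS design maximizes pullback within the range budget", {
  b <- beam_model()
  # distal WET 79: budget 300 -> single 300 plate beats {100, 200}
  u <- design_urs(79, b)
  expect_equal(u$total_wet, 300)
  expect_equal(u$selected, 300)
  # distal 49: budget 330 -> best subset {10, 20, 300}
  u2 <- design_urs(49, b)
  expect_equal(u2$total_wet, 330)
  expect_setequal(u2$selected, c(10, 20, 300))
  # pullback never exceeds the budget over a scan of distal depths
  for (dw in seq(20, 370, by = 37)) {
    ui <- design_urs(dw, b)
    expect_lte(ui$total_wet, b$range_water - dw + 1e-9)
  }
  expect_error(design_urs(379, b), "infeasible")
  # physical thickness converts by the PMMA stopping power
  expect_equal(u$physical_thickness, 300 / 1.16)
})

test_that("RC design puts every ray's peak on the distal surface", {
  ph <- make_water_phantom(80, 200, spacing = 2)
  # box target spanning z 100..140 at the center
  tgt <- array(FALSE, dim(ph$rsp))
  cx <- voxel_centers(ph, 1)
  cz <- voxel_centers(ph, 3)
  tgt[abs(cx) < 20, abs(voxel_centers(ph, 2)) < 20, cz > 100 & cz < 140] <-
    TRUE
  ph$structures$target <- tgt
  geo <- beam_geometry(c(0, 0, 1), 100)
  urs <- urs_from_pullback(200)
  rc <- design_rc(ph, geo, "target", urs, lattice_pitch = 2)
  # in-field rays: rc + urs + distal = range
  iu <- which.min(abs(rc$u))
  expect_equal(rc$wet[iu, iu], 379 - 200 - 140, tolerance = 2)
  expect_true(all(rc$wet >= 0))
  # out-of-target rays carry the maximum in-field thickness
  expect_equal(max(rc$wet), rc$wet[1, 1])
  # URS too thick for the deepest ray is infeasible
  expect_error(design_rc(ph, geo, "target", urs_from_pullback(300)),
               "infeasible")
})

test_that("square aperture bypass has exact area and intervals", {
  geo <- beam_geometry(c(0, 0, 1), 100)
  ap <- design_aperture(geometry = geo, square_half_size = 15, margin = 5,
                        pitch = 0.5)
  expect_equal(aperture_opening_area(ap), 40^2, tolerance = 0.05 * 40^2)
  expect_equal(flashbp:::.aperture_interval(ap, "u", 0), c(-20, 20))
  expect_null(flashbp:::.aperture_interval(ap, "u", 25))
  expect_equal(ap$thickness, 50)
  expect_error(design_aperture(geometry = geo, square_half_size = 15,
                               margin = -1), "margin")
})

test_that("projected aperture dilates the target BEV by the margin", {
  ph <- make_head_phantom(37, 20260428)
  geo <- beam_geometry(c(1, 0, 0), 100)
  ap <- design_aperture(ph, geo, "GTV", margin = 5, pitch = 1)
  # opening area between projection area and dilated bound
  r <- 37 / 2
  area <- aperture_opening_area(ap)
  expect_gt(area, pi * r^2)
  expect_lt(area, pi * (r + 5 + 2)^2 * 1.1)
  # margin monotonicity
  ap0 <- design_aperture(ph, geo, "GTV", margin = 0, pitch = 1)
  expect_lt(aperture_opening_area(ap0), area)
  # central interval width ~ diameter + 2 margin
  iv <- flashbp:::.aperture_interval(ap, "u", at = 8)
  expect_equal(diff(iv), 37 + 10, tolerance = 4)
})

test_that("beam geometry requires axis-aligned directions", {
  expect_error(beam_geometry(c(1, 1, 0) / sqrt(2), 100), "axis-aligned")
  expect_error(beam_geometry(c(0, 0, 1), -1), "air_gap")
  fr <- flashbp:::.axis_frame(beam_geometry(c(0, -1, 0), 50))
  expect_equal(fr$travel, 2)
  expect_equal(fr$sign, -1)
  expect_equal(fr$lat, c(1, 3))
})
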