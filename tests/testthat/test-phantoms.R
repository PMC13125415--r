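test_that("voxel phantom constructor validates inputs", {
  expect_error(voxel_phantom(array(1, c(2, 2)), spacing = 2), "3-D")
  expect_error(voxel_phantom(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(voxel_phantom(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "> 0")
  bad <- list(s = array(TRUE, c(3, 2, 2)))
  expect_error(voxel_phantom(array(1, c(2, 2, 2)), structures = bad),
               "shape")
})

test_that("water phantom geometry follows the conventions", {
  ph <- make_water_phantom(100, 60, spacing = 2)
  expect_equal(dim(ph$rsp), c(50, 50, 30))
  # surface at z = 0, laterally centered
  expect_equal(ph$origin, c(-50, -50, 0))
  expect_equal(voxel_centers(ph, 3)[1], 1)
  expect_equal(mean(voxel_centers(ph, 1)), 0)
  expect_equal(structure_volume_cc(ph, "water"), 100 * 100 * 60 / 1000)
  expect_error(make_water_phantom(101, 60, spacing = 2), "multiples")
})

test_that("head phantom is deterministic with documented structures", {
  ph1 <- make_head_phantom(37, 20260428)
  ph2 <- make_head_phantom(37, 20260428)
  expect_identical(ph1$rsp, ph2$rsp)
  expect_identical(ph1$structures$GTV, ph2$structures$GTV)
  expect_setequal(names(ph1$structures),
                  c("brain", "skull", "GTV", "brainstem", "chiasm",
                    "optic_nerve_L", "optic_nerve_R"))
  # GTV volume close to the sphere volume of the requested diameter
  vol <- structure_volume_cc(ph1, "GTV")
  expect_equal(vol, 4 / 3 * pi * (37 / 2)^3 / 1000, tolerance = 0.05)
  # GTV inside brain; structures disjoint from air
  expect_true(all(ph1$structures$brain[ph1$structures$GTV]))
  expect_true(all(ph1$rsp[ph1$structures$GTV] == 1.0))
  expect_gt(structure_volume_cc(ph1, "brain"), 1000)
  # infeasible GTV size errors
  expect_error(make_head_phantom(200), "inside brain")
})

test_that("wet_along_ray matches analytic slab oracles", {
  ph <- make_water_phantom(100, 100, spacing = 2)
  # straight ray through water: WET = path length; stop_depth counts from
  # the grid entry, so a start outside the grid is equivalent to a surface
  # start
  expect_equal(wet_along_ray(ph, c(1, 1, -10), c(0, 0, 1), 50), 50,
               tolerance = 1e-9)
  expect_equal(wet_along_ray(ph, c(1, 1, 0), c(0, 0, 1), 50), 50,
               tolerance = 1e-9)
  # additive over sub-segments
  w1 <- wet_along_ray(ph, c(1, 1, 0), c(0, 0, 1), 30)
  w2 <- wet_along_ray(ph, c(1, 1, 30), c(0, 0, 1), 40)
  wtot <- wet_along_ray(ph, c(1, 1, 0), c(0, 0, 1), 70)
  expect_equal(w1 + w2, wtot, tolerance = 1e-9)
  # oblique ray: WET = path length in water
  d <- c(1, 0, 1) / sqrt(2)
  w <- wet_along_ray(ph, c(-20, 1, 0), d, 40)
  expect_equal(w, 40, tolerance = 1e-9)
  # non-unit rsp scales the integral
  ph2 <- ph
  ph2$rsp[] <- 1.16
  expect_equal(wet_along_ray(ph2, c(1, 1, 0), c(0, 0, 1), 50), 58,
               tolerance = 1e-9)
  # missing the grid: 0 with attribute and warning
  expect_warning(res <- wet_along_ray(ph, c(500, 500, -10), c(0, 0, 1), 50),
                 "misses")
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "missed"))
})
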