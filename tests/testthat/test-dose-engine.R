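small_field <- function(with_aperture = FALSE, axis = c(0, 0, 1)) {
  geo <- beam_geometry(axis, 50)
  ap <- if (with_aperture)
    design_aperture(geometry = geo, square_half_size = 10, margin = 5)
  else NULL
  sm <- generate_spot_map(10, 10, 5, beam_model())
  field_setup(geo, urs_from_pullback(300), sm, aperture = ap)
}

test_that("single-field water dose peaks at the pulled-back depth", {
  b <- beam_model()
  ph <- make_water_phantom(80, 100, spacing = 2)
  dg <- compute_field_dose(small_field(), ph, b)
  expect_s3_class(dg, "dose_grid")
  expect_true(all(dg$dose >= 0))
  cax <- dg$dose[which.min(abs(voxel_centers(ph, 1))),
                 which.min(abs(voxel_centers(ph, 2))), ]
  zpk <- voxel_centers(ph, 3)[which.max(cax)]
  expect_equal(zpk, bragg_peak_depth(b) - 300, tolerance = 3)
  # approximate energy bookkeeping: the in-phantom integral matches
  # n_protons x (depth-dose integral beyond the 300 mm pullback)
  e_total <- sum(dg$dose) * prod(ph$spacing)
  zz <- seq(300, 450, by = 0.25)
  e_expect <- sum(small_field()$spotmap$spots$mu) * b$protons_per_mu *
    sum(bragg_depth_dose(zz, b)) * 0.25
  expect_equal(e_total, e_expect, tolerance = 0.1)
})

test_that("dose is invariant under beam-frame permutation", {
  b <- beam_model()
  ph <- make_water_phantom(80, 80, spacing = 2)
  dz <- compute_field_dose(small_field(), ph, b)$dose
  # same cubic phantom irradiated along +x; rotate the grid to compare
  ph2 <- voxel_phantom(array(1, dim(ph$rsp)),
                       origin = c(0, -40, -40), spacing = 2)
  fx <- small_field(axis = c(1, 0, 0))
  dx <- compute_field_dose(fx, ph2, b)$dose
  expect_equal(aperm(dx, c(2, 3, 1)), dz, tolerance = 1e-9)
  # and along -z with the surface at the far face
  ph3 <- voxel_phantom(array(1, dim(ph$rsp)),
                       origin = c(-40, -40, -80), spacing = 2)
  fz <- small_field(axis = c(0, 0, -1))
  dzm <- compute_field_dose(fz, ph3, b)$dose
  expect_equal(dzm[, , rev(seq_len(dim(dzm)[3]))], dz, tolerance = 1e-9)
})

test_that("aperture trims the field edge but not the center", {
  b <- beam_model()
  ph <- make_water_phantom(100, 80, spacing = 2)
  d_off <- compute_field_dose(small_field(FALSE), ph, b)$dose
  d_on <- compute_field_dose(small_field(TRUE), ph, b)$dose
  # aperture never adds dose beyond angular-quadrature accuracy
  expect_true(all(d_on <= d_off * 1.02 + 1e-9))
  cx <- voxel_centers(ph, 1)
  mid <- which.min(abs(voxel_centers(ph, 3) - 40))
  icy <- which.min(abs(voxel_centers(ph, 2)))
  prof_off <- d_off[, icy, mid]
  prof_on <- d_on[, icy, mid]
  # center barely affected, far tail strongly suppressed
  expect_gt(prof_on[which.min(abs(cx))] / prof_off[which.min(abs(cx))], 0.95)
  far <- which.min(abs(cx - 35))
  expect_lt(prof_on[far] / prof_off[far], 0.5)
})

test_that("RBE scaling and influence rows are consistent", {
  b <- beam_model()
  ph <- make_water_phantom(60, 60, spacing = 2)
  f <- small_field()
  mask <- array(FALSE, dim(ph$rsp))
  mask[10:20, 12:18, 5:25] <- TRUE
  dg <- compute_field_dose(f, ph, b, influence_mask = mask)
  dg_rbe <- compute_field_dose(f, ph, b, rbe = TRUE)
  expect_equal(dg_rbe$dose, dg$dose * 1.1, tolerance = 1e-12)
  # influence rows reproduce the dose at the mask voxels
  expect_equal(rowSums(dg$per_spot), dg$dose[dg$mask_index],
               tolerance = 1e-9)
  expect_equal(dg$mask_index, which(mask))
  expect_equal(ncol(dg$per_spot), nrow(f$spotmap$spots))
})

test_that("spot fluence transmission follows the Gaussian mass", {
  geo <- beam_geometry(c(0, 0, 1), 100)
  ap <- design_aperture(geometry = geo, square_half_size = 15, margin = 5)
  b <- beam_model()
  urs <- urs_from_pullback(100)
  # centered spot: nearly full transmission
  t_c <- spot_fluence_at_aperture(list(x = 0, y = 0, mu = 400), ap, b, urs,
                                  geo)$transmission
  expect_gt(t_c, 0.99)
  # far-blocked spot
  t_b <- spot_fluence_at_aperture(list(x = 60, y = 0, mu = 400), ap, b, urs,
                                  geo)$transmission
  expect_lt(t_b, 1e-4)
  # monotone decreasing as the spot walks off the opening
  tt <- vapply(seq(0, 40, 5), function(xs)
    spot_fluence_at_aperture(list(x = xs, y = 0, mu = 400), ap, b, urs,
                             geo)$transmission, numeric(1))
  expect_true(all(diff(tt) < 0))
})
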