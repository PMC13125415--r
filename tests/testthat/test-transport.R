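test_that("lateral sigma grows with depth, pullback and air gap", {
  s_depth <- lateral_sigma(c(10, 100, 200, 300), 0, 0)
  expect_true(all(diff(s_depth) > 0))
  s_gap <- vapply(c(0, 50, 100, 150),
                  function(g) lateral_sigma(50, 100, g), numeric(1))
  expect_true(all(diff(s_gap) > 0))
  s_urs <- vapply(c(0, 100, 200, 300),
                  function(u) lateral_sigma(50, u, 100), numeric(1))
  expect_true(all(diff(s_urs) > 0))
})

test_that("scattering calibration reproduces the end-of-range benchmark", {
  b <- beam_model()
  # near the end of range the in-water MCS sigma is ~2.1% of the range
  tm <- transport_model(0, 0, depths = 378, beam = b)
  sig <- tm$core$layers[[1]]$sig_tot
  src <- 3.5 + 0.003 * 378
  mcs <- sqrt(sig^2 - src^2)
  expect_equal(mcs, 0.021 * 379, tolerance = 0.01)
})

test_that("gauss-hermite rule integrates exactly to its degree", {
  q <- flashbp:::.gauss_hermite(31)
  expect_equal(sum(q$w), 1, tolerance = 1e-12)
  expect_equal(sum(q$w * q$x^2), 1, tolerance = 1e-10)  # E[X^2], X~N(0,1)
  expect_equal(sum(q$w * q$x^4), 3, tolerance = 1e-9)
  expect_equal(sum(q$w * q$x^3), 0, tolerance = 1e-10)
})

test_that("no-aperture profiles are normalized densities", {
  tm <- transport_model(100, 50, depths = c(1, 150), beam = beam_model())
  x <- seq(-120, 120, by = 0.25)
  for (li in 1:2) {
    P <- spot_axis_profiles(tm, li, centers = c(-5, 0, 5), x)
    integ <- colSums(P) * 0.25
    expect_equal(unname(integ), rep(1, 3), tolerance = 1e-3)
  }
})

test_that("aperture transmission only removes fluence", {
  tm <- transport_model(200, 100, depths = c(1, 80), beam = beam_model())
  x <- seq(-80, 80, by = 0.5)
  for (li in 1:2) {
    off <- spot_axis_profiles(tm, li, centers = 0, x)
    on <- spot_axis_profiles(tm, li, centers = 0, x, aperture = 20)
    # 31-node Gauss-Hermite angular quadrature reproduces the closed-form
    # profile to well under 1% of the peak (error -> 0 with node count)
    expect_true(all(on <= off + 0.01 * max(off)))
    # a very wide opening is transparent (to quadrature accuracy)
    wide <- spot_axis_profiles(tm, li, centers = 0, x, aperture = 500)
    expect_lt(max(abs(as.vector(wide) - as.vector(off))), 0.01 * max(off))
  }
  # fully swallowed spot: centered far outside a small opening
  blocked <- spot_axis_profiles(tm, 1, centers = 60, x, aperture = 10)
  expect_lt(sum(blocked) * 0.5, 0.05)
})

test_that("aperture accepts off-center opening intervals", {
  tm <- transport_model(100, 100, depths = 1, beam = beam_model())
  x <- seq(-60, 60, by = 0.25)
  centered <- spot_axis_profiles(tm, 1, centers = 0, x, aperture = 15)
  shifted <- spot_axis_profiles(tm, 1, centers = 10, x,
                                aperture = c(-5, 25))
  # same spot/opening geometry translated by 10 mm
  i <- which(x >= -40 & x <= 40)
  j <- match(round(x[i] + 10, 4), round(x, 4))
  expect_equal(shifted[j], centered[i], tolerance = 1e-9)
})

test_that("transport_model validates inputs", {
  expect_error(transport_model(-1, 0, 10), "urs_wet")
  expect_error(transport_model(0, -5, 10), "air_gap")
})
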