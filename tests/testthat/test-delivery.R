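make_sm <- function(x, y, mu) {
  structure(list(spots = data.frame(x = x, y = y, mu = mu), spacing = 5),
            class = "spot_map")
}

test_that("timeline is serpentine with correct dwell and travel", {
  b <- beam_model()
  # 2 x 2 lattice: row y=0 left-to-right, row y=5 right-to-left
  sm <- make_sm(c(0, 5, 0, 5), c(0, 0, 5, 5), c(400, 800, 400, 1600))
  tl <- build_timeline(sm, b, scan_speed = 8000)
  expect_equal(tl$events$spot, c(1, 2, 4, 3))
  # dwell: max(MST, mu/rate); 400 MU at 8e5 MU/s exactly saturates the MST
  expect_equal(tl$events$dwell, c(5e-4, 1e-3, 2e-3, 5e-4))
  # travel: 5 mm hops at 8000 mm/s
  expect_equal(tl$events$travel, c(5, 5, 5, 0) / 8000)
  expect_equal(tl$total_time, sum(tl$events$dwell) + 3 * 5 / 8000)
  # chronology: starts strictly increasing, consistent with dwell + travel
  expect_true(all(diff(tl$events$start) > 0))
  # infinite scan speed removes travel
  tl2 <- build_timeline(sm, b, scan_speed = Inf)
  expect_equal(tl2$total_time, sum(tl2$events$dwell))
  expect_error(build_timeline(make_sm(0, 0, 100), b), "min_mu")
  expect_error(build_timeline(sm, b, scan_speed = 0), "scan_speed")
})

test_that("ADR matches hand-built cumulative-curve cases", {
  b <- beam_model()
  sm <- make_sm(c(0, 5), c(0, 0), c(800, 800))
  tl <- build_timeline(sm, b, scan_speed = 8000)
  # dwells 1 ms each, travel 0.625 ms between
  infl <- rbind(c(1, 1),     # voxel dosed by both spots
                c(2, 0),     # only the first spot
                c(0, 0))     # untouched
  adr <- compute_adr(infl, tl, window_dose = 0)
  span_both <- 2 * 1e-3 + 5 / 8000
  expect_equal(adr[1], 2 / span_both)
  expect_equal(adr[2], 2 / 1e-3)
  expect_true(is.na(adr[3]))
  # nonzero window: w = 0.5 inside a single 2 Gy spot of 1 ms
  adr_w <- compute_adr(infl, tl, window_dose = 0.5)
  # voxel 2: d(t) linear 0..2 over 1 ms; t0 at 0.25 ms, t1 at 0.75 ms
  expect_equal(adr_w[2], (2 - 1) / (0.5e-3))
  # voxel 1: t0 where cum = 0.5 (mid of spot 1), t1 where cum = 1.5
  t0 <- 0.5e-3
  t1 <- 1e-3 + 5 / 8000 + 0.5e-3
  expect_equal(adr_w[1], (2 - 1) / (t1 - t0))
  # window >= D/2 is undefined
  expect_true(is.na(compute_adr(infl, tl, window_dose = 1)[1]))
  expect_error(compute_adr(infl, tl, window_dose = -1), "window_dose")
})

test_that("ADR agrees with the independent oracle on random cases", {
  set.seed(7)
  b <- beam_model()
  sm <- make_sm(rep(seq(0, 15, 5), 3), rep(c(0, 5, 10), each = 4),
                sample(seq(400, 2000, 100), 12, replace = TRUE))
  tl <- build_timeline(sm, b, scan_speed = 8000)
  infl <- matrix(rexp(20 * 12, rate = 2), 20, 12)
  infl[sample(length(infl), 60)] <- 0
  for (w in c(0, 0.3)) {
    got <- compute_adr(infl, tl, window_dose = w)
    want <- adr_oracle(infl, tl, window_dose = w)
    ok <- !is.na(want)
    expect_equal(got[ok], want[ok], tolerance = 1e-6)
    expect_equal(is.na(got), is.na(want))
  }
})

test_that("V40 eligibility identities hold exactly", {
  adr <- list(c(50, 30, 45, NA), c(10, 80, 41, 39))
  dose <- list(c(5, 5, 0.5, 5), c(5, 5, 5, 0.05))
  # threshold 0: eligible = dose > 0 and ADR defined -> 7 obs, 4 at >= 40
  expect_equal(v40(adr, dose, dose_threshold = 0), 100 * 4 / 7)
  # threshold 1 drops the 0.5 and 0.05 Gy observations -> 5 obs, 3 pass
  expect_equal(v40(adr, dose, dose_threshold = 1), 100 * 3 / 5)
  # inclusive comparison at exactly 40
  expect_equal(v40(list(40), list(1)), 100)
  # nothing eligible -> NA
  expect_true(is.na(v40(list(c(50, 50)), list(c(0, 0)))))
  expect_error(v40(list(), list()), "empty ROI")
  # DRVH evaluated at 40 equals V40
  h <- drvh(adr, dose, dose_threshold = 0)
  expect_equal(h$volume_pct[h$rate == 40], v40(adr, dose, 0))
  expect_true(all(diff(h$volume_pct) <= 0))
})
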