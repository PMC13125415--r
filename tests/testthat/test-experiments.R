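test_that("sweep table has the full factorial shape", {
  sw <- get_sweep()
  expect_equal(nrow(sw), 108)
  expect_equal(sum(sw$aperture == "on"), 54)
  counts <- table(sw$field_size_mm, sw$pullback_mm, sw$air_gap_mm)
  expect_true(all(counts == 6))  # 3 depths x on/off per cell
  expect_true(all(sw$note == ""))
  expect_true(all(is.finite(sw$penumbra_mm)))
  expect_true(all(sw$penumbra_mm > 0))
})

test_that("every cell shows an aperture benefit", {
  sw <- get_sweep()
  expect_true(all(sw$reduction_mm > 0))
  # reduction is the pairwise off - on within each cell
  on <- sw[sw$aperture == "on", ]
  off <- sw[sw$aperture == "off", ]
  key <- function(d) paste(d$field_size_mm, d$pullback_mm, d$air_gap_mm,
                           d$depth_pos)
  m <- match(key(on), key(off))
  expect_equal(on$reduction_mm, off$penumbra_mm[m] - on$penumbra_mm,
               tolerance = 1e-9)
})

test_that("sweep targets report the documented sample sizes", {
  tg <- sweep_targets(get_sweep())
  expect_setequal(names(tg), paste0("t", 1:7))
  expect_equal(vapply(tg, `[[`, integer(1), "n"),
               c(t1 = 9L, t2 = 9L, t3 = 9L, t4 = 18L, t5 = 3L, t6 = 3L,
                 t7 = 18L))
  expect_true(all(vapply(tg, function(t) is.finite(t$value), logical(1))))
  # internal consistency with direct aggregation
  sw <- get_sweep()
  t2 <- mean(sw$penumbra_mm[sw$field_size_mm == 30 & sw$pullback_mm == 300 &
                              sw$aperture == "off"])
  expect_equal(tg$t2$value, t2)
})

test_that("single-cell penumbra responds to the air gap as documented", {
  # without aperture the penumbra grows mildly with air gap; with aperture
  # the entrance penumbra grows strongly with air gap (drift from the edge)
  sw <- get_sweep()
  s <- sw[sw$field_size_mm == 30 & sw$pullback_mm == 300 &
            sw$depth_pos == "entrance", ]
  on <- s$penumbra_mm[s$aperture == "on"][order(s$air_gap_mm[s$aperture == "on"])]
  expect_true(all(diff(on) > 0))
})

test_that("head case produces a coherent report", {
  hd <- get_head()
  for (arm in c("on", "off")) {
    r <- hd[[arm]]
    expect_equal(r$gtv_v95, 100)      # by normalization
    expect_gt(r$ci, 0.2)              # prescription isodose is nonempty
    expect_gt(r$gtv_dmean, 0.95 * 30)
    expect_true(all(r$v40$gtv_v40 >= 0 & r$v40$gtv_v40 <= 100))
    expect_equal(r$v40$dose_threshold, c(0, 2, 5))
    expect_true(all(c("brainstem", "chiasm") %in% r$oar$structure))
    expect_gt(r$total_time_s, 0)
    expect_gt(r$n_spots, 3)
    # composite equals the sum of per-field doses
    expect_equal(r$composite,
                 Reduce(`+`, lapply(r$field_dose, `[[`, "dose")),
                 tolerance = 1e-9)
  }
  expect_equal(hd$config$seed, 20260428)
  expect_gt(hd$phantom_volumes_cc[["brain"]], 1000)
})
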