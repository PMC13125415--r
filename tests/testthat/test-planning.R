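test_that("spot lattice counts match the documented examples", {
  b <- beam_model()
  expect_equal(nrow(generate_spot_map(15, 15, 5, b)$spots), 49)   # 3x3 cm
  expect_equal(nrow(generate_spot_map(25, 25, 5, b)$spots), 121)  # 5x5 cm
  expect_equal(nrow(generate_spot_map(2, 2, 5, b)$spots), 1)      # degenerate
  sm <- generate_spot_map(15, 10, 5, b)
  expect_true(all(sm$spots$mu == b$min_mu))
  expect_true(all(abs(sm$spots$x) <= 15) && all(abs(sm$spots$y) <= 10))
  expect_error(generate_spot_map(10, 10, 0), "spacing")
})

test_that("active-set NNLS solves unconstrained-feasible systems exactly", {
  set.seed(1)
  A <- matrix(runif(40 * 8), 40, 8)
  w_true <- runif(8, 1, 3)
  b <- as.vector(A %*% w_true)
  sol <- solve_nnls(A, b, method = "active-set")
  expect_equal(sol$w, w_true, tolerance = 1e-8)
  expect_true(all(diff(sol$objective) <= 1e-9))
})

test_that("FISTA matches active-set on constrained random systems", {
  set.seed(2)
  A <- matrix(abs(rnorm(60 * 12)), 60, 12)
  b <- rnorm(60, 5, 2)
  s1 <- solve_nnls(A, b, method = "active-set")
  s2 <- solve_nnls(A, b, method = "pgd")
  o1 <- sum((b - A %*% s1$w)^2)
  o2 <- sum((b - A %*% s2$w)^2)
  expect_equal(o2, o1, tolerance = 1e-6)
  expect_true(all(s2$w >= 0))
  expect_true(all(diff(s2$objective) <= 1e-9))
})

test_that("lower bounds are honored", {
  set.seed(3)
  A <- matrix(runif(30 * 6), 30, 6)
  b <- rnorm(30)
  for (m in c("active-set", "pgd")) {
    sol <- solve_nnls(A, b, lower = 400, method = m)
    expect_true(all(sol$w >= 400 - 1e-9))
  }
})

test_that("floor mode keeps every spot at or above the minimum MU", {
  set.seed(4)
  A <- matrix(runif(50 * 10, 0, 1e-3), 50, 10)
  opt <- optimize_spot_weights(A, 5, beam_model(), mode = "floor")
  expect_true(all(opt$mu >= 400 - 1e-9))
  expect_true(all(diff(opt$objective) <= 1e-9))
})

test_that("sparse mode finalizes with no spot in (0, min_mu)", {
  set.seed(5)
  # influence scaled so optimal weights straddle the minimum MU
  A <- matrix(abs(rnorm(80 * 25, 0, 2e-3)), 80, 25)
  opt <- optimize_spot_weights(A, 30, beam_model(), mode = "sparse")
  mu <- opt$mu
  expect_true(any(mu > 0))
  expect_false(any(mu > 0 & mu < 400))
  # empty plan raises
  expect_error(optimize_spot_weights(matrix(1, 4, 3) * 1e6, 1e-9,
                                     beam_model(), mode = "sparse"),
               "empty plan")
})

test_that("normalization pins the minimum target dose at 95% of rx", {
  d <- c(25, 28, 31)
  s <- normalize_plan(d, 30)
  expect_equal(min(d * s), 0.95 * 30)
  expect_error(normalize_plan(c(0, 1), 30), "cannot normalize")
})
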