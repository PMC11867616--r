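two_point_pattern <- function() {
  w <- volume_window(1e5, 1e5, 1e5)
  point_pattern3d(rbind(c(50000, 50000, 50000), c(50100, 50000, 50000)), w)
}

test_that("G of two points jumps at their separation", {
  pp <- two_point_pattern()
  g <- g_function(pp, r_grid = c(50, 99.9, 100, 200), correction = "none")
  expect_equal(g$observed, c(0, 0, 1, 1))
})

test_that("K of two points equals 1/lambda beyond their separation", {
  pp <- two_point_pattern()
  k <- k_function(pp, r_grid = c(50, 150), correction = "none")
  lambda_nm3 <- 2 / 1e15
  expect_equal(k$observed, c(0, 1 / lambda_nm3))
})

test_that("F jumps at zero when the query sits on the single point", {
  w <- volume_window(1e4, 1e4, 1e4)
  pp <- point_pattern3d(matrix(c(5000, 5000, 5000), 1), w)
  f <- f_function(pp, r_grid = c(0, 10), correction = "none",
                  query_points = matrix(c(5000, 5000, 5000), 1))
  expect_equal(f$observed, c(1, 1))
})

test_that("nearest-neighbour distances of two points are symmetric", {
  nn <- nearest_neighbor_distances(two_point_pattern())
  expect_equal(nn$distances_nm, c(100, 100))
  expect_equal(nn$mean_nm, 100)
})

test_that("uncorrected estimators match brute-force oracles", {
  w <- test_window()
  r_grid <- seq(0, 2500, length.out = 60)
  for (seed in c(21, 22)) {
    pts <- generate_centroids("poisson", n = 50, window = w, seed = seed)
    pp <- point_pattern3d(pts, w)
    expect_equal(g_function(pp, r_grid, "none")$observed,
                 oracle_g_none(pts, r_grid))
    expect_equal(k_function(pp, r_grid, "none")$observed,
                 oracle_k_none(pts, r_grid, w))
    queries <- generate_centroids("poisson", n = 120, window = w,
                                  seed = seed + 100)
    expect_equal(
      f_function(pp, r_grid, "none", query_points = queries)$observed,
      oracle_f_none(pts, queries, r_grid))
    expect_equal(nearest_neighbor_distances(pp)$distances_nm,
                 oracle_nn(pts))
  }
})

test_that("estimators are monotone and bounded", {
  w <- test_window()
  pts <- generate_centroids("poisson", n = 200, window = w, seed = 31)
  pp <- point_pattern3d(pts, w)
  # uncorrected estimators are exact CDFs / cumulative counts: monotone
  g <- g_function(pp, correction = "none")$observed
  f <- f_function(pp, correction = "none", seed = 1)$observed
  k <- k_function(pp, correction = "none")$observed
  for (v in list(g, f)) {
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(diff(k) >= -1e-9))
  expect_true(all(k >= 0))
  # reduced-sample (border) estimators change denominator with r, so they
  # are only bounded, not strictly monotone
  for (v in list(g_function(pp, correction = "border")$observed,
                 f_function(pp, correction = "border", seed = 1)$observed)) {
    v <- v[!is.na(v)]
    expect_true(all(v >= 0 & v <= 1))
  }
  kb <- k_function(pp, correction = "border")$observed
  expect_true(all(kb[!is.na(kb)] >= 0))
})

test_that("G approaches the analytic Poisson curve on a large CSR pattern", {
  w <- volume_window(2e4, 2e4, 1e4)
  n <- 4000
  pts <- generate_centroids("poisson", n = n, window = w, seed = 41)
  pp <- point_pattern3d(pts, w)
  r_grid <- seq(0, 1500, length.out = 50)
  g <- g_function(pp, r_grid, correction = "border")
  lambda_nm3 <- n / (2e4 * 2e4 * 1e4)
  theo <- 1 - exp(-lambda_nm3 * 4 / 3 * pi * r_grid^3)
  expect_lt(max(abs(g$observed - theo), na.rm = TRUE), 0.03)
})

test_that("border-corrected K approaches the ball volume under CSR", {
  w <- volume_window(2e4, 2e4, 1e4)
  pts <- generate_centroids("poisson", n = 3000, window = w, seed = 43)
  pp <- point_pattern3d(pts, w)
  r_grid <- seq(200, 2000, length.out = 25)
  k <- k_function(pp, r_grid, correction = "border")
  theo <- 4 / 3 * pi * r_grid^3
  expect_lt(max(abs(k$observed / theo - 1), na.rm = TRUE), 0.15)
})

test_that("corrected and uncorrected G converge as the window grows", {
  lam_nm3 <- 0.4 / 1e9
  r_grid <- seq(0, 1200, length.out = 30)
  gap <- vapply(c(1e4, 3e4), function(side) {
    w <- volume_window(side, side, side)
    n <- round(lam_nm3 * side^3)
    pp <- point_pattern3d(
      generate_centroids("poisson", n = n, window = w, seed = 51), w)
    a <- g_function(pp, r_grid, "border")$observed
    b <- g_function(pp, r_grid, "none")$observed
    max(abs(a - b), na.rm = TRUE)
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("estimators reject degenerate inputs", {
  w <- test_window()
  one <- point_pattern3d(matrix(c(1, 1, 1), 1), w)
  expect_error(g_function(one), "at least 2")
  expect_error(k_function(one), "at least 2")
  expect_error(nearest_neighbor_distances(one), "at least 2")
  zero <- point_pattern3d(matrix(numeric(0), 0, 3), w)
  expect_error(f_function(zero), "at least 1")
})

test_that("coincident points are flagged", {
  w <- test_window()
  pp <- point_pattern3d(rbind(c(100, 100, 100), c(100, 100, 100)), w)
  expect_warning(nn <- nearest_neighbor_distances(pp), "coincident")
  expect_equal(nn$distances_nm, c(0, 0))
})
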