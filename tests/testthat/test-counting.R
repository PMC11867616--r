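make_pop <- function(centers, radii) {
  data.frame(x_nm = centers[, 1], y_nm = centers[, 2], z_nm = centers[, 3],
             radius_nm = radii)
}

test_that("frame construction validates geometry", {
  expect_error(counting_frame(c(0, 0, 0), c(0, 10, 10)), "degenerate")
  cf <- counting_frame(c(0, 0, 0), c(1e4, 1e4, 5e3), artifact_fraction = 0.1)
  expect_equal(cf$raw_volume_um3, 500)
  expect_equal(cf$effective_volume_um3, 450)
})

test_that("interior and exclusion-crossing synapses classify as stated", {
  cf <- counting_frame(c(1000, 1000, 1000), c(9000, 7000, 4000))
  pop <- make_pop(rbind(c(5000, 4000, 2500),  # strictly interior
                        c(1000, 4000, 2500),  # centred on low-x exclusion
                        c(9000, 4000, 2500),  # touching high-x acceptance
                        c(20000, 4000, 2500)), # far outside
                  c(100, 100, 100, 100))
  expect_equal(classify_against_frame(pop, cf),
               c("counted", "excluded", "counted", "excluded"))
})

test_that("extension of exclusion planes dominates acceptance contact", {
  cf <- counting_frame(c(1000, 1000, 1000), c(9000, 7000, 4000))
  # sphere crossing the high-x acceptance face but also within reach of the
  # extended low-y exclusion plane
  pop <- make_pop(rbind(c(9000, 1005, 2500)), 50)
  expect_equal(classify_against_frame(pop, cf), "excluded")
})

test_that("sphere classification matches the exhaustive face-slab oracle", {
  set.seed(14)
  cf <- counting_frame(c(2000, 2000, 1000), c(8000, 6000, 4000),
                       exclusion_low = c(TRUE, FALSE, TRUE))
  n <- 200
  centers <- cbind(runif(n, 0, 10000), runif(n, 0, 8000), runif(n, 0, 5000))
  radii <- runif(n, 0, 800)
  got <- classify_against_frame(make_pop(centers, radii), cf)
  want <- vapply(seq_len(n), function(i) {
    oracle_classify(centers[i, ], radii[i], cf$lo, cf$hi,
                    c(TRUE, FALSE, TRUE))
  }, character(1))
  expect_identical(got, want)
})

test_that("centroid mode ignores the extent proxy", {
  cf <- counting_frame(c(1000, 1000, 1000), c(9000, 7000, 4000))
  pop <- make_pop(rbind(c(1100, 4000, 2500)), 500) # overlaps low-x exclusion
  expect_equal(classify_against_frame(pop, cf), "excluded")
  expect_equal(classify_against_frame(pop, cf, mode = "centroid"), "counted")
})

test_that("density is count over effective volume", {
  cf <- counting_frame(c(0, 0, 0), c(1e4, 1e4, 5e3))
  expect_equal(estimate_density(make_pop(matrix(numeric(0), 0, 3),
                                         numeric(0)), cf)$density_per_um3, 0)
  # forced arithmetic: 180 counted in 500 - 50 um^3 -> 0.40 /um^3
  cf2 <- counting_frame(c(0, 0, 0), c(1e4, 1e4, 5e3),
                        artifact_fraction = 0.1)
  set.seed(3)
  inner <- cbind(runif(180, 1500, 8500), runif(180, 1500, 8500),
                 runif(180, 1500, 3500))
  est <- estimate_density(make_pop(inner, rep(10, 180)), cf2)
  expect_equal(est$counted, 180)
  expect_equal(est$density_per_um3, 180 / 450)
})

test_that("counting is unbiased over random frame placements in CSR", {
  # one large CSR realisation, many frames: mean density near the truth
  w <- volume_window(3e4, 3e4, 1e4)
  lam <- 0.41
  pop <- simulate_stack(
    layer_profile("III", density = lam, as_fraction = 0.94,
                  mean_sas_as = 120000, mean_sas_ss = 70000),
    window = w, seed = 77)
  set.seed(78)
  dens <- vapply(1:40, function(i) {
    lo <- c(runif(1, 1000, 2e4), runif(1, 1000, 2e4), runif(1, 1000, 3000))
    cf <- counting_frame(lo, lo + c(8000, 8000, 5000))
    estimate_density(pop, cf)$density_per_um3
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - lam), 3.5 * se + 0.01)
})

test_that("shrinkage correction reproduces its defining identities", {
  f <- shrinkage_factors()
  # involution: corrected * factor returns the measured value exactly
  v <- c(0.123, 45.6, 1e5)
  expect_equal(apply_shrinkage(v, "area", f) * f$area, v)
  expect_equal(apply_shrinkage(v, "linear", f) * f$linear, v)
  expect_equal(apply_shrinkage(v, "volume", f) * f$volume, v)
  # density moves opposite to volume
  expect_equal(apply_shrinkage(0.42, "density", f), 0.42 * 0.9)
  # identity at factor 1
  f1 <- shrinkage_factors(1, 1, 1)
  expect_identical(apply_shrinkage(v, "area", f1), v)
  expect_error(shrinkage_factors(area = 1.2), "factors")
  expect_error(apply_shrinkage(-1, "area"), ">= 0")
})
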