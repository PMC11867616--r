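test_that("CSR generator handles the empty and fixed-n cases", {
  w <- test_window()
  expect_equal(nrow(generate_centroids("poisson", n = 0, window = w)), 0)
  pts <- generate_centroids("poisson", n = 1e4,
                            window = volume_window(1e4, 1e4, 5e3), seed = 1)
  # fixed-n construction: empirical intensity is exact
  expect_equal(nrow(pts) / 500, 20)
  expect_true(all(pts > 0))
  expect_true(all(pts[, 1] < 1e4 & pts[, 2] < 1e4 & pts[, 3] < 5e3))
})

test_that("generators are reproducible under a fixed seed and leave the RNG alone", {
  w <- test_window()
  set.seed(42); before <- runif(1)
  a <- generate_centroids("poisson", n = 50, window = w, seed = 7)
  b <- generate_centroids("poisson", n = 50, window = w, seed = 7)
  expect_identical(a, b)
  set.seed(42)
  expect_identical(runif(1), before)
})

test_that("Poisson-count mode draws N from the intensity", {
  w <- volume_window(1e4, 1e4, 1e4) # 1000 um^3
  ns <- vapply(1:50, function(i) {
    nrow(generate_centroids("poisson", intensity = 0.4, window = w,
                            seed = i))
  }, numeric(1))
  # N ~ Poisson(400): mean within 4 SE of 400
  expect_lt(abs(mean(ns) - 400), 4 * sqrt(400 / 50))
})

test_that("hardcore patterns respect the inhibition distance (brute force)", {
  w <- test_window()
  m <- spatial_model("hardcore", inhibition_nm = 500)
  pts <- generate_centroids(m, n = 50, window = w, seed = 3)
  expect_equal(nrow(pts), 50)
  expect_gte(min(pairwise_dists(pts)), 500)
})

test_that("infeasible hardcore packing fails with a clear error", {
  w <- volume_window(2000, 2000, 2000)
  m <- spatial_model("hardcore", inhibition_nm = 1900)
  expect_error(
    generate_centroids(m, n = 50, window = w, seed = 1, max_tries = 20),
    "infeasible")
})

test_that("Matern cluster generator returns the requested count inside the window", {
  w <- test_window()
  m <- spatial_model("matern_cluster", parent_intensity = 0.05,
                     cluster_radius = 300, offspring_mean = 10)
  pts <- generate_centroids(m, n = 120, window = w, seed = 11)
  expect_equal(nrow(pts), 120)
  expect_true(all(pts[, 1] > 0 & pts[, 1] < w$x_len))
  expect_true(all(pts[, 3] > 0 & pts[, 3] < w$z_len))
})

test_that("CSR mean nearest-neighbour distance matches the closed form", {
  # E d = 0.55396 lambda^(-1/3); Monte-Carlo check at lambda = 0.41/um^3
  w <- volume_window(2e4, 2e4, 1e4) # big box to dampen border effects
  lam <- 0.41
  n <- round(lam * window_volume_um3(w))
  means <- vapply(1:8, function(i) {
    pts <- generate_centroids("poisson", n = n, window = w, seed = 100 + i)
    nn <- nearest_neighbor_distances(point_pattern3d(pts, w))
    # restrict to interior points: the closed form is border-free, and
    # points near the faces have inflated nearest-neighbour distances
    b <- pmin(pts[, 1], 2e4 - pts[, 1], pts[, 2], 2e4 - pts[, 2],
              pts[, 3], 1e4 - pts[, 3])
    mean(nn$distances_nm[b >= 1500])
  }, numeric(1))
  expected <- csr_mean_nn_nm(lam)
  expect_equal(expected, 0.55396 * (lam / 1e9)^(-1 / 3), tolerance = 1e-4)
  expect_lt(abs(mean(means) - expected) / expected, 0.02)
})

test_that("attribute draws follow the configured probabilities", {
  w <- test_window()
  prof <- layer_profile("III", density = 0.4, as_fraction = 0.941,
                        mean_sas_as = 130268, mean_sas_ss = 74248)
  pts <- generate_centroids("poisson", n = 1e5,
                            window = volume_window(5e4, 5e4, 5e4), seed = 5)
  pop <- assign_attributes(pts, prof, seed = 6)
  # AS fraction within 3 binomial SDs
  p_hat <- mean(pop$type == "AS")
  expect_lt(abs(p_hat - 0.941), 3 * sqrt(0.941 * 0.059 / 1e5))
  # log-normal mean: exp(mu + sigma^2/2)
  as_areas <- pop$sas_area_nm2[pop$type == "AS"]
  se <- sd(as_areas) / sqrt(length(as_areas))
  expect_lt(abs(mean(as_areas) - 130268), 3 * se)
  # shape and target marginals within 3 binomial SDs
  p_mac <- mean(pop$shape[pop$type == "AS"] == "macular")
  expect_lt(abs(p_mac - 0.84), 3 * sqrt(0.84 * 0.16 / length(as_areas)))
  p_head <- mean(pop$target[pop$type == "AS"] == "spine_head")
  expect_lt(abs(p_head - 59.3 / 94.1),
            3 * sqrt(0.63 * 0.37 / length(as_areas)))
  # spine linkage only on spine-targeted synapses
  on_spine <- pop$target %in% c("spine_head", "spine_neck")
  expect_true(all(!is.na(pop$spine_id[on_spine])))
  expect_true(all(is.na(pop$spine_id[!on_spine])))
})

test_that("degenerate profiles produce degenerate draws", {
  pts <- generate_centroids("poisson", n = 200, window = test_window(),
                            seed = 1)
  prof <- layer_profile("I", density = 0.4, as_fraction = 1,
                        mu_as = log(1e5), sigma_as = 0,
                        mean_sas_ss = 5e4)
  pop <- assign_attributes(pts, prof, seed = 2)
  expect_true(all(pop$type == "AS"))
  expect_equal(pop$sas_area_nm2, rep(1e5, 200))
})

test_that("invalid probability vectors are rejected by field name", {
  expect_error(
    layer_profile("I", density = 0.4, as_fraction = 0.9,
                  mean_sas_as = 1e5, mean_sas_ss = 5e4,
                  shape_probs_as = c(macular = 0.5, perforated = 0.2,
                                     horseshoe = 0.2, fragmented = 0.2)),
    "shape_probs_as")
  expect_error(
    layer_profile("I", density = -1, as_fraction = 0.9,
                  mean_sas_as = 1e5, mean_sas_ss = 5e4),
    "density")
})

test_that("composition grids reproduce requested fractions", {
  g <- generate_composition_grid(c(neuropil = 1), nrow = 100, ncol = 100)
  expect_true(all(attr(g, "legend")[as.vector(g)] == "neuropil"))
  g2 <- generate_composition_grid(c(neuropil = 0.9, vessel = 0.1),
                                  nrow = 1000, ncol = 1000, seed = 9)
  frac_vessel <- mean(attr(g2, "legend")[as.vector(g2)] == "vessel")
  expect_lt(abs(frac_vessel - 0.1), 3 * sqrt(0.1 * 0.9 / 1e6))
  expect_error(generate_composition_grid(c(neuropil = 0.5, vessel = 0.3)),
               "sum to 1")
  expect_error(generate_composition_grid(c(neuropil = 1.2, vessel = -0.2)),
               "nonnegative")
})

test_that("default layer profiles encode the calibration table", {
  profs <- mec_layer_profiles()
  expect_setequal(names(profs),
                  c("I", "II-is", "II-ni", "III", "Va/b", "Vc", "VI"))
  expect_equal(profile_mean_sas(profs[["VI"]], "AS"), 99489)
  expect_equal(profile_mean_sas(profs[["I"]], "SS"), 53367)
  expect_equal(profs[["III"]]$as_fraction, 0.941)
  expect_equal(profs[["I"]]$density, 0.47)
})
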