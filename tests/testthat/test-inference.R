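test_that("category proportions and ratio strings follow the conventions", {
  p <- category_proportions(c(AS = 8605, SS = 541))
  expect_equal(round(p$percent[["AS"]], 1), 94.1)
  p2 <- category_proportions(c(AS = 1265, SS = 80))
  expect_equal(p2$ratio, "94:6")
  p3 <- category_proportions(c(AS = 10, SS = 0))
  expect_equal(p3$ratio, "100:0")
  expect_error(category_proportions(c(AS = 0, SS = 0)), "positive")
})

test_that("pairwise chi-square matches the closed-form Pearson statistic", {
  # proportional rows -> exactly zero
  m0 <- rbind(a = c(94, 6), b = c(940, 60))
  expect_equal(chi_square_pairwise(m0)$statistic, 0)
  # hand-computed {10,20;20,10}: sum (O-E)^2/E = 6.667, no continuity corr.
  m <- rbind(a = c(10, 20), b = c(20, 10))
  res <- chi_square_pairwise(m)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  # Bonferroni is a plain multiply-and-cap
  m3 <- rbind(a = c(30, 20), b = c(20, 30), c = c(25, 25))
  r3 <- chi_square_pairwise(m3)
  expect_equal(nrow(r3), 3)
  expect_equal(r3$p_adjusted, pmin(1, r3$p * 3))
  # all-zero row flagged untestable
  mz <- rbind(a = c(0, 0), b = c(5, 5))
  expect_false(chi_square_pairwise(mz)$testable)
})

test_that("Mann-Whitney agrees with exhaustive permutation on tiny samples", {
  res <- rank_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$test, "mann_whitney")
  expect_equal(res$statistic, 0) # first group wholly below the second
  p_exact <- oracle_mw_p(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_exact, 0.1) # 2/20 assignments as extreme
  # asymptotic p close to the enumeration for such tiny n, same side of .05
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8) + 0.5
  p_asym <- rank_tests(list(a = a, b = b))$p
  expect_lt(abs(p_asym - oracle_mw_p(a, b)), 0.06)
})

test_that("Kruskal-Wallis omnibus gates Dunn post hocs", {
  const <- list(a = rep(2, 5), b = rep(2, 5), c = rep(2, 5))
  res <- rank_tests(const)
  expect_true(is.na(res$statistic) || res$statistic == 0)
  expect_null(res$posthoc)
  set.seed(6)
  sep <- list(a = rnorm(20), b = rnorm(20) + 3, c = rnorm(20) + 6)
  res2 <- rank_tests(sep)
  expect_true(res2$significant)
  expect_s3_class(res2$posthoc, "data.frame")
  expect_equal(nrow(res2$posthoc), 3)
  expect_equal(res2$posthoc$p_adjusted, pmin(1, res2$posthoc$p * 3))
  expect_true(all(res2$posthoc$significant))
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  set.seed(7)
  rejections <- vapply(1:1000, function(i) {
    s <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    rank_tests(s)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("dual significance thresholds follow the sampling unit", {
  expect_equal(significance_threshold("stack"), 0.05)
  expect_equal(significance_threshold("subject"), 0.05)
  expect_equal(significance_threshold("synapse"), 1e-4)
})

test_that("coefficient of variation is exact and scale-invariant", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(rep(4, 6)), 0)
  x <- c(2, 3, 7, 11)
  expect_equal(coefficient_of_variation(x * 37),
               coefficient_of_variation(x))
  expect_warning(cv <- coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_true(is.na(cv))
  expect_warning(coefficient_of_variation(5), "n < 2")
})

test_that("spine occupancy classifies multisets of synapses", {
  pop <- data.frame(
    type = c("AS", "AS", "SS", "AS", "SS", "AS", "AS"),
    target = c("spine_head", "spine_head", "spine_head", "spine_head",
               "spine_head", "spine_neck", "aspiny_shaft"),
    spine_id = c("s1", "s2", "s2", "s3", "s4", "s3", NA)
  )
  tab <- tabulate_spine_occupancy(pop)
  expect_equal(tab$n_spines[tab$class == "single_AS"], 1)
  expect_equal(tab$n_spines[tab$class == "AS_SS"], 1)
  expect_equal(tab$n_spines[tab$class == "single_SS"], 1)
  expect_equal(tab$n_spines[tab$class == "other"], 1) # s3: two AS
  expect_equal(sum(tab$percent), 100)
  bad <- pop; bad$spine_id[7] <- "s9"
  expect_error(tabulate_spine_occupancy(bad), "non-spine")
})

test_that("generated spine composition tracks the configured probabilities", {
  w <- volume_window(5e4, 5e4, 2e4)
  prof <- mec_layer_profiles()[["III"]]
  pop <- simulate_stack(prof, w, n = 60000, seed = 71)
  tab <- tabulate_spine_occupancy(pop)
  n_sp <- sum(tab$n_spines)
  p_single <- tab$percent[tab$class == "single_AS"] / 100
  expect_lt(abs(p_single - 0.96), 3 * sqrt(0.96 * 0.04 / n_sp) + 0.01)
  # rare classes present in the configured order of magnitude
  expect_gt(tab$n_spines[tab$class == "AS_SS"], 0)
})
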