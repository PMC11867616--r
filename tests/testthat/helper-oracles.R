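# Independent brute-force oracles used to validate the package estimators.
# These deliberately use naive O(n^2) / exhaustive logic and no package
# internals.

# printed-table convention: integers rounded half up
round_printed <- function(x) as.integer(floor(x + 0.5))

test_window <- function(x = 10000, y = 8000, z = 5000, ...) {
  volume_window(x, y, z, ...)
}

pairwise_dists <- function(pts) {
  n <- nrow(pts)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    }
  }
  d
}

oracle_nn <- function(pts) apply(pairwise_dists(pts), 1, min)

oracle_g_none <- function(pts, r_grid) {
  d <- oracle_nn(pts)
  sapply(r_grid, function(r) mean(d <= r))
}

oracle_f_none <- function(pts, queries, r_grid) {
  d <- apply(queries, 1, function(q) {
    min(sqrt(colSums((t(pts) - q)^2)))
  })
  sapply(r_grid, function(r) mean(d <= r))
}

oracle_k_none <- function(pts, r_grid, window) {
  n <- nrow(pts)
  vol_nm3 <- window$x_len * window$y_len * window$z_len
  lambda <- n / vol_nm3
  d <- pairwise_dists(pts)
  sapply(r_grid, function(r) mean(rowSums(d <= r)) / lambda)
}

# exhaustive sphere-vs-frame classification testing every face slab
oracle_classify <- function(center, radius, lo, hi, exclusion_low) {
  closest <- pmin(pmax(center, lo), hi)
  intersects <- sum((center - closest)^2) <= radius^2
  touches_excl <- FALSE
  for (ax in 1:3) {
    plane <- if (exclusion_low[ax]) lo[ax] else hi[ax]
    if (abs(center[ax] - plane) <= radius) touches_excl <- TRUE
  }
  if (intersects && !touches_excl) "counted" else "excluded"
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group
# assignments (small n only)
oracle_mw_p <- function(a, b) {
  x <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    aa <- x[idx]; bb <- x[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  obs <- u_stat(seq_len(n_a))
  all_idx <- combn(length(x), n_a, simplify = FALSE)
  us <- vapply(all_idx, u_stat, numeric(1))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

oracle_ks_two <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
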