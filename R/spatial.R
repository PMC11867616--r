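#' 3D point pattern in a box window
#'
#' Container for synapse centroids analysed as a spatial point pattern. The
#' intensity is derived as `n / volume`.
#'
#' @param points n x 3 matrix of coordinates (nm), or a
#'   `synapse_population` (its centroids are taken).
#' @param window a [volume_window()]; defaults to the population's attached
#'   window when available.
#' @return object of class `point_pattern3d` with fields `points`, `window`,
#'   `n`, `intensity_per_um3`.
#' @export
point_pattern3d <- function(points, window = NULL) {
  if (inherits(points, "synapse_population")) {
    window <- window %||% attr(points, "window")
    points <- cbind(points$x_nm, points$y_nm, points$z_nm)
  }
  window <- window %||% volume_window()
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3", call. = FALSE)
  if (nrow(points) > 0 && !all(points_in_window(points, window) |
                               on_window_boundary(points, window))) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  colnames(points) <- c("x", "y", "z")
  structure(
    list(points = points, window = window, n = nrow(points),
         intensity_per_um3 = nrow(points) / window_volume_um3(window)),
    class = "point_pattern3d"
  )
}

on_window_boundary <- function(points, window) {
  points[, 1] >= 0 & points[, 1] <= window$x_len &
    points[, 2] >= 0 & points[, 2] <= window$y_len &
    points[, 3] >= 0 & points[, 3] <= window$z_len
}

#' @export
print.point_pattern3d <- function(x, ...) {
  cat(sprintf("3D point pattern: %d points, %.3f per um^3\n", x$n,
              x$intensity_per_um3))
  invisible(x)
}

# distance from each point to the nearest window face
boundary_distance <- function(points, window) {
  pmin(points[, 1], window$x_len - points[, 1],
       points[, 2], window$y_len - points[, 2],
       points[, 3], window$z_len - points[, 3])
}

# nearest-neighbour distance of rows of `a` to rows of `b`; `self = TRUE`
# when a and b are the same set (excludes the zero self-distance). Chunked
# so memory stays bounded for large patterns.
cross_nn_dist <- function(a, b, self = FALSE, chunk = 512L) {
  n <- nrow(a)
  out <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 +
      outer(a[idx, 2], b[, 2], "-")^2 +
      outer(a[idx, 3], b[, 3], "-")^2
    if (self) d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# per-point neighbour counts within each r of r_grid (pairs, no self)
pair_counts <- function(points, r_grid, chunk = 512L) {
  n <- nrow(points)
  counts <- matrix(0L, n, length(r_grid))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(points[idx, 1], points[, 1], "-")^2 +
      outer(points[idx, 2], points[, 2], "-")^2 +
      outer(points[idx, 3], points[, 3], "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf
    d <- sqrt(d2)
    for (k in seq_along(r_grid)) {
      counts[idx, k] <- rowSums(d <= r_grid[k])
    }
  }
  counts
}

default_r_grid <- function(window, n_r = 100L) {
  rmax <- min(window$x_len, window$y_len, window$z_len) / 4
  seq(0, rmax, length.out = n_r)
}

#' Nearest-neighbour distance function G
#'
#' Empirical cumulative distribution of the distance from each point to its
#' nearest neighbour. With the border (reduced-sample) correction, at each
#' distance `d` only points at least `d` from every window face enter both
#' numerator and denominator; `"none"` uses all points (the form checked
#' against brute force).
#'
#' @param pattern a [point_pattern3d()]; needs at least 2 points.
#' @param r_grid distances in nm (default 100 values up to a quarter of the
#'   shortest window side).
#' @param correction `"border"` or `"none"`.
#' @return object of class `curve_estimate` with `r_nm`, `observed`,
#'   `theoretical` (CSR: `1 - exp(-lambda * 4/3 * pi * r^3)`), `fun`,
#'   `correction`.
#' @export
g_function <- function(pattern, r_grid = NULL,
                       correction = c("border", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern3d"))
  if (pattern$n < 2) stop("G function needs at least 2 points", call. = FALSE)
  r_grid <- r_grid %||% default_r_grid(pattern$window)
  d <- cross_nn_dist(pattern$points, pattern$points, self = TRUE)
  obs <- if (correction == "none") {
    vapply(r_grid, function(r) mean(d <= r), numeric(1))
  } else {
    b <- boundary_distance(pattern$points, pattern$window)
    vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(d[keep] <= r)
    }, numeric(1))
  }
  curve_estimate(r_grid, obs, csr_theory("G", r_grid, pattern), "G",
                 correction)
}

#' Empty-space function F
#'
#' Cumulative distribution, over reference locations, of the distance to
#' the nearest data point. Reference locations are a regular lattice of
#' about `n_query` points, jittered once under `seed` (or pass
#' `query_points` explicitly). Border correction is minus-sampling: at each
#' `d` only query locations at least `d` from every face are used.
#'
#' @inheritParams g_function
#' @param n_query target number of query locations (default `10 * n`,
#'   at least 1000).
#' @param query_points optional explicit m x 3 matrix of query locations.
#' @param seed seed for the lattice jitter.
#' @return a `curve_estimate` (theoretical CSR curve as for G).
#' @export
f_function <- function(pattern, r_grid = NULL,
                       correction = c("border", "none"),
                       n_query = NULL, query_points = NULL, seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern3d"))
  if (pattern$n < 1) stop("F function needs at least 1 point", call. = FALSE)
  r_grid <- r_grid %||% default_r_grid(pattern$window)
  if (is.null(query_points)) {
    n_query <- n_query %||% max(1000L, 10L * pattern$n)
    query_points <- query_lattice(pattern$window, n_query, seed)
  }
  query_points <- as.matrix(query_points)
  d <- cross_nn_dist(query_points, pattern$points)
  obs <- if (correction == "none") {
    vapply(r_grid, function(r) mean(d <= r), numeric(1))
  } else {
    b <- boundary_distance(query_points, pattern$window)
    vapply(r_grid, function(r) {
      keep <- b >= r
      if (!any(keep)) return(NA_real_)
      mean(d[keep] <= r)
    }, numeric(1))
  }
  curve_estimate(r_grid, obs, csr_theory("F", r_grid, pattern), "F",
                 correction)
}

# regular lattice of ~n points in the window, one shared jitter per call
query_lattice <- function(window, n, seed = NULL) {
  lens <- c(window$x_len, window$y_len, window$z_len)
  s <- (prod(lens) / n)^(1 / 3)
  counts <- pmax(1L, round(lens / s))
  with_seed(seed, {
    jit <- stats::runif(3, -0.5, 0.5)
    grids <- lapply(1:3, function(ax) {
      step <- lens[ax] / counts[ax]
      (seq_len(counts[ax]) - 0.5 + jit[ax] * 0.999) * step
    })
    as.matrix(expand.grid(x = grids[[1]], y = grids[[2]], z = grids[[3]]))
  })
}

#' Ripley's K function in 3D
#'
#' Mean number of further points within distance `d` of a typical point,
#' divided by the intensity. With the border correction, at each `d` only
#' centres at least `d` from every face contribute; distances where no
#' centre is eligible are returned as `NA`.
#'
#' @inheritParams g_function
#' @return a `curve_estimate`; theoretical CSR curve `4/3 * pi * r^3`
#'   (nm^3).
#' @export
k_function <- function(pattern, r_grid = NULL,
                       correction = c("border", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern3d"))
  if (pattern$n < 2) stop("K function needs at least 2 points", call. = FALSE)
  r_grid <- r_grid %||% default_r_grid(pattern$window)
  lambda_nm3 <- pattern$n / (pattern$window$x_len * pattern$window$y_len *
                               pattern$window$z_len)
  counts <- pair_counts(pattern$points, r_grid)
  obs <- if (correction == "none") {
    colMeans(counts) / lambda_nm3
  } else {
    b <- boundary_distance(pattern$points, pattern$window)
    vapply(seq_along(r_grid), function(k) {
      keep <- b >= r_grid[k]
      if (!any(keep)) return(NA_real_)
      mean(counts[keep, k]) / lambda_nm3
    }, numeric(1))
  }
  curve_estimate(r_grid, obs, csr_theory("K", r_grid, pattern), "K",
                 correction)
}

csr_theory <- function(fun, r_grid, pattern) {
  vol_ball <- 4 / 3 * pi * r_grid^3
  if (fun == "K") return(vol_ball)
  lambda_nm3 <- pattern$n / (pattern$window$x_len * pattern$window$y_len *
                               pattern$window$z_len)
  1 - exp(-lambda_nm3 * vol_ball)
}

curve_estimate <- function(r_nm, observed, theoretical, fun, correction) {
  structure(
    data.frame(r_nm = r_nm, observed = observed, theoretical = theoretical),
    fun = fun, correction = correction,
    class = c("curve_estimate", "data.frame")
  )
}

#' Intersynaptic (nearest-neighbour) distances
#'
#' Distance from each synapse centroid to its nearest neighbouring
#' centroid; all points retained (no border deletion), matching how mean
#' intersynaptic distance is reported. Coincident points yield distance 0
#' and a warning.
#'
#' @param pattern a [point_pattern3d()] or `synapse_population`.
#' @return object of class `nn_distance_set`: `distances_nm`, `mean_nm`,
#'   `sd_nm`, `n`.
#' @examples
#' pp <- point_pattern3d(generate_centroids("poisson", n = 200, seed = 1))
#' nearest_neighbor_distances(pp)$mean_nm
#' @export
nearest_neighbor_distances <- function(pattern) {
  if (!inherits(pattern, "point_pattern3d")) {
    pattern <- point_pattern3d(pattern)
  }
  if (pattern$n < 2) stop("need at least 2 points", call. = FALSE)
  d <- cross_nn_dist(pattern$points, pattern$points, self = TRUE)
  if (any(d == 0)) warning("coincident points: zero nearest-neighbour distance")
  structure(list(distances_nm = d, mean_nm = mean(d), sd_nm = stats::sd(d),
                 n = pattern$n),
            class = "nn_distance_set")
}

#' @export
print.nn_distance_set <- function(x, ...) {
  cat(sprintf("nearest-neighbour distances: mean %.0f +/- %.0f nm (n = %d)\n",
              x$mean_nm, x$sd_nm, x$n))
  invisible(x)
}

#' Expected CSR nearest-neighbour distance
#'
#' Closed form for the homogeneous Poisson process in 3D:
#' `E d = Gamma(4/3) * (4/3 * pi * lambda)^(-1/3) = 0.55396 * lambda^(-1/3)`.
#'
#' @param intensity_per_um3 points per um^3.
#' @return expected nearest-neighbour distance in nm.
#' @export
csr_mean_nn_nm <- function(intensity_per_um3) {
  lambda_nm3 <- intensity_per_um3 / 1e9
  gamma(4 / 3) * (4 / 3 * pi * lambda_nm3)^(-1 / 3)
}
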