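#' Spatial point-process models for synapse centroids
#'
#' Three generative models cover the spatial hypotheses the analysis
#' distinguishes: complete spatial randomness (homogeneous Poisson),
#' clustering (Matern cluster process: Poisson parents, offspring uniform in
#' a sphere), and regularity (hardcore inhibition by sequential rejection).
#'
#' @param kind one of `"poisson"`, `"matern_cluster"`, `"hardcore"`.
#' @param parent_intensity Matern: parent intensity, parents per um^3.
#' @param cluster_radius Matern: offspring sphere radius in nm; must be > 0.
#' @param offspring_mean Matern: mean offspring per parent (Poisson).
#' @param inhibition_nm hardcore: minimum allowed pairwise distance in nm.
#'
#' @return An object of class `spatial_model`.
#' @export
spatial_model <- function(kind = c("poisson", "matern_cluster", "hardcore"),
                          parent_intensity = NULL, cluster_radius = NULL,
                          offspring_mean = NULL, inhibition_nm = NULL) {
  kind <- match.arg(kind)
  if (kind == "matern_cluster") {
    if (is.null(cluster_radius) || cluster_radius <= 0) {
      stop("matern_cluster requires cluster_radius > 0 (nm)", call. = FALSE)
    }
    if (is.null(parent_intensity) || parent_intensity <= 0) {
      stop("matern_cluster requires parent_intensity > 0 (per um^3)",
           call. = FALSE)
    }
    offspring_mean <- offspring_mean %||% 10
  }
  if (kind == "hardcore") {
    if (is.null(inhibition_nm) || inhibition_nm < 0) {
      stop("hardcore requires inhibition_nm >= 0", call. = FALSE)
    }
  }
  structure(list(kind = kind, parent_intensity = parent_intensity,
                 cluster_radius = cluster_radius,
                 offspring_mean = offspring_mean,
                 inhibition_nm = inhibition_nm),
            class = "spatial_model")
}

#' Generate synapse centroids in a 3D window
#'
#' Places points in a [volume_window()] under a [spatial_model()]. The
#' default CSR generator is conditional on the point count (a binomial
#' process: `n` i.i.d. uniform points), which is the form used when
#' simulation envelopes are built "with the same number of centroids" as an
#' observed pattern. Passing `intensity` instead of `n` draws
#' `N ~ Poisson(lambda * V)` first (the unconditional process).
#'
#' @param model a [spatial_model()]; plain strings are promoted, so
#'   `generate_centroids("poisson", ...)` works for CSR.
#' @param n exact number of points, or `NULL` to use `intensity`.
#' @param intensity points per um^3 (used when `n` is `NULL`).
#' @param window a [volume_window()].
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param max_tries hardcore only: rejection proposals allowed per point
#'   before the packing is declared infeasible.
#'
#' @return numeric matrix with `n` rows and columns `x`, `y`, `z` (nm); all
#'   points strictly inside the window.
#' @examples
#' pts <- generate_centroids("poisson", n = 100, seed = 1)
#' nrow(pts)
#' @export
generate_centroids <- function(model = spatial_model("poisson"), n = NULL,
                               intensity = NULL,
                               window = volume_window(), seed = NULL,
                               max_tries = 200L) {
  if (is.character(model)) model <- spatial_model(model)
  stopifnot(inherits(model, "spatial_model"),
            inherits(window, "volume_window"))
  if (is.null(n)) {
    if (is.null(intensity) || intensity < 0) {
      stop("supply n >= 0 or intensity >= 0", call. = FALSE)
    }
  } else if (n < 0) {
    stop("n must be >= 0", call. = FALSE)
  }

  with_seed(seed, {
    if (is.null(n)) n <- stats::rpois(1, intensity * window_volume_um3(window))
    pts <- switch(model$kind,
      poisson = runif_box(n, window),
      matern_cluster = matern_points(n, model, window),
      hardcore = hardcore_points(n, model, window, max_tries)
    )
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

runif_box <- function(n, window) {
  cbind(stats::runif(n, 0, window$x_len),
        stats::runif(n, 0, window$y_len),
        stats::runif(n, 0, window$z_len))
}

# Matern cluster: parents in the window dilated by the cluster radius so
# clusters straddling the boundary keep their in-window offspring; the
# requested n is then taken as a random subset of the accumulated offspring.
matern_points <- function(n, model, window) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  r <- model$cluster_radius
  dil <- c(window$x_len, window$y_len, window$z_len) + 2 * r
  vol_dil <- nm3_to_um3(prod(dil))
  acc <- matrix(numeric(0), 0, 3)
  for (round in 1:50) {
    n_par <- max(1L, stats::rpois(1, model$parent_intensity * vol_dil))
    parents <- cbind(stats::runif(n_par, -r, window$x_len + r),
                     stats::runif(n_par, -r, window$y_len + r),
                     stats::runif(n_par, -r, window$z_len + r))
    n_off <- stats::rpois(n_par, model$offspring_mean)
    idx <- rep.int(seq_len(n_par), n_off)
    m <- length(idx)
    if (m > 0) {
      # uniform in a sphere of radius r around each parent
      u <- matrix(stats::rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- r * stats::runif(m)^(1 / 3)
      off <- parents[idx, , drop = FALSE] + u * rad
      off <- off[points_in_window(off, window), , drop = FALSE]
      acc <- rbind(acc, off)
    }
    if (nrow(acc) >= n) break
  }
  if (nrow(acc) < n) {
    stop("matern_cluster could not accumulate the requested point count; ",
         "increase parent_intensity or offspring_mean", call. = FALSE)
  }
  acc[sample.int(nrow(acc), n), , drop = FALSE]
}

# Sequential hardcore packing (random sequential adsorption): propose
# uniform points, reject any within the inhibition distance of an accepted
# one. Fails loudly when the packing is infeasible at the attempt budget.
hardcore_points <- function(n, model, window, max_tries) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  d2min <- model$inhibition_nm^2
  pts <- matrix(NA_real_, n, 3)
  accepted <- 0L
  tries <- 0L
  budget <- max_tries * n
  while (accepted < n) {
    if (tries >= budget) {
      stop(sprintf(
        "hardcore packing infeasible: placed %d of %d points after %d proposals",
        accepted, n, tries), call. = FALSE)
    }
    p <- c(stats::runif(1, 0, window$x_len),
           stats::runif(1, 0, window$y_len),
           stats::runif(1, 0, window$z_len))
    tries <- tries + 1L
    if (accepted > 0L) {
      d2 <- (pts[1:accepted, 1] - p[1])^2 + (pts[1:accepted, 2] - p[2])^2 +
        (pts[1:accepted, 3] - p[3])^2
      if (min(d2) < d2min) next
    }
    accepted <- accepted + 1L
    pts[accepted, ] <- p
  }
  pts
}
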