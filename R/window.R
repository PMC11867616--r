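#' Define a 3D tissue window
#'
#' A `volume_window` is the axis-aligned box in which synapse centroids live:
#' the imaged FIB/SEM stack. Default dimensions follow a typical acquisition
#' geometry of 2048 x 1536 pixels at 5 nm/pixel in-plane and ~274 serial
#' sections at 20 nm, i.e. roughly 10.2 x 7.7 x 5.5 um.
#'
#' @param x_len,y_len,z_len box edge lengths in nm; all must be positive.
#' @param voxel_xy in-plane sampling in nm/pixel (metadata only).
#' @param voxel_z section thickness in nm (metadata only).
#' @param artifact_fraction fraction of the box volume occupied by
#'   acquisition artifacts and therefore unusable for counting; in `[0, 1)`.
#'
#' @return An object of class `volume_window`.
#' @examples
#' w <- volume_window()
#' window_volume_um3(w)
#' @export
volume_window <- function(x_len = 2048 * 5, y_len = 1536 * 5,
                          z_len = 274 * 20,
                          voxel_xy = 5, voxel_z = 20,
                          artifact_fraction = 0) {
  x_len <- as.numeric(x_len); y_len <- as.numeric(y_len)
  z_len <- as.numeric(z_len) # doubles: nm^3 products overflow integers
  lens <- c(x_len = x_len, y_len = y_len, z_len = z_len)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("window edge lengths must be positive and finite", call. = FALSE)
  }
  if (!is.finite(artifact_fraction) || artifact_fraction < 0 ||
      artifact_fraction >= 1) {
    stop("artifact_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(x_len = x_len, y_len = y_len, z_len = z_len,
         voxel_xy = voxel_xy, voxel_z = voxel_z,
         artifact_fraction = artifact_fraction),
    class = "volume_window"
  )
}

#' @rdname volume_window
#' @param window a `volume_window`.
#' @export
window_volume_um3 <- function(window) {
  stopifnot(inherits(window, "volume_window"))
  nm3_to_um3(window$x_len * window$y_len * window$z_len)
}

#' @rdname volume_window
#' @export
window_effective_volume_um3 <- function(window) {
  window_volume_um3(window) * (1 - window$artifact_fraction)
}

#' @export
print.volume_window <- function(x, ...) {
  cat(sprintf("3D window: %.0f x %.0f x %.0f nm (%.1f um^3", x$x_len,
              x$y_len, x$z_len, window_volume_um3(x)))
  if (x$artifact_fraction > 0) {
    cat(sprintf(", %.1f%% artifact", 100 * x$artifact_fraction))
  }
  cat(")\n")
  invisible(x)
}

# points matrix (n x 3, nm) strictly inside the window?
points_in_window <- function(points, window) {
  if (nrow(points) == 0) return(logical(0))
  points[, 1] > 0 & points[, 1] < window$x_len &
    points[, 2] > 0 & points[, 2] < window$y_len &
    points[, 3] > 0 & points[, 3] < window$z_len
}
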