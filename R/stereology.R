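#' Cavalieri point counting on a composition grid
#'
#' Overlays one or more regular point grids (spacing `spacing_um`, each
#' covering `extent_um x extent_um`, default 50 x 50 um = 2500 um^2 of
#' points at 5 um spacing) at uniformly random positions on a tissue label
#' grid, and counts the points hitting each tissue class. Points falling
#' outside the label field are skipped and tallied in `skipped`.
#'
#' @param grid a `composition_grid` (see [generate_composition_grid()]).
#' @param n_placements number of random grid placements (the study used
#'   10-15 sites per section).
#' @param spacing_um distance between grid points in um.
#' @param extent_um side of the square covered by one placement, um.
#' @param seed integer seed for the random offsets.
#' @return object of class `element_counts`: named integer vector `Q` over
#'   tissue classes, plus `skipped` and `n_placements`.
#' @examples
#' g <- generate_composition_grid(c(neuropil = 0.9, vessel = 0.1), seed = 1)
#' count_hits(g, n_placements = 10, seed = 2)
#' @export
count_hits <- function(grid, n_placements = 10L, spacing_um = 5,
                       extent_um = 50, seed = NULL) {
  stopifnot(inherits(grid, "composition_grid"))
  if (spacing_um <= 0) stop("spacing_um must be > 0", call. = FALSE)
  legend <- attr(grid, "legend")
  cell <- attr(grid, "cell_um")
  field_x <- ncol(grid) * cell
  field_y <- nrow(grid) * cell
  offs <- seq(spacing_um / 2, extent_um, by = spacing_um)
  Q <- stats::setNames(integer(length(legend)), legend)
  skipped <- 0L
  with_seed(seed, {
    for (p in seq_len(n_placements)) {
      # random lower-left corner; the quadrat may overhang a small field
      ox <- stats::runif(1, 0, max(field_x - extent_um, 0)) +
        stats::runif(1, -spacing_um / 2, spacing_um / 2)
      oy <- stats::runif(1, 0, max(field_y - extent_um, 0)) +
        stats::runif(1, -spacing_um / 2, spacing_um / 2)
      pts <- expand.grid(x = ox + offs, y = oy + offs)
      col <- floor(pts$x / cell) + 1
      row <- floor(pts$y / cell) + 1
      inside <- col >= 1 & col <= ncol(grid) & row >= 1 & row <= nrow(grid)
      skipped <- skipped + sum(!inside)
      hits <- grid[cbind(row[inside], col[inside])]
      tab <- tabulate(hits, nbins = length(legend))
      Q <- Q + tab
    }
  })
  if (skipped > 0) {
    warning(sprintf("%d grid points fell outside the label field", skipped))
  }
  structure(list(Q = Q, skipped = skipped, n_placements = n_placements),
            class = "element_counts")
}

#' @export
print.element_counts <- function(x, ...) {
  cat("Cavalieri point counts (Q):\n")
  print(x$Q)
  invisible(x)
}

#' Volume fraction from point counts
#'
#' `Vv(element) = Q(element) * 100 / sum(Q)` over all tissue classes;
#' fractions across elements sum to exactly 100.
#'
#' @param counts an `element_counts` (or a named nonnegative vector).
#' @param element class name, or `NULL` for all classes.
#' @return percent, named numeric.
#' @examples
#' volume_fraction(c(neuropil = 86, neuron = 9, vessel = 5), "neuropil")
#' @export
volume_fraction <- function(counts, element = NULL) {
  Q <- if (inherits(counts, "element_counts")) counts$Q else counts
  if (any(Q < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(Q)
  if (total <= 0) stop("total point count must be positive", call. = FALSE)
  vv <- Q * 100 / total
  if (is.null(element)) return(vv)
  if (!element %in% names(vv)) {
    stop(sprintf("unknown element '%s'", element), call. = FALSE)
  }
  vv[[element]]
}
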