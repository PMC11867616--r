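#' Generate a 2D tissue-composition label grid
#'
#' Simulates the semithin-section view used for Cavalieri point counting:
#' each cell of the grid is one tissue class (neuropil, neuronal soma, glia,
#' undetermined soma, blood vessel) drawn i.i.d. from the requested area
#' fractions. Cells are square with side `cell_um`.
#'
#' @param fractions named numeric over (a subset of)
#'   neuropil/neuron/glia/undetermined/vessel; must be nonnegative and sum
#'   to 1.
#' @param nrow,ncol grid dimensions in cells.
#' @param cell_um cell side length in micrometres.
#' @param seed integer seed.
#' @return integer matrix of class `composition_grid` with attributes
#'   `legend` (integer -> class name) and `cell_um`.
#' @examples
#' g <- generate_composition_grid(c(neuropil = 0.9, vessel = 0.1),
#'                                nrow = 50, ncol = 50, seed = 1)
#' table(attr(g, "legend")[g])
#' @export
generate_composition_grid <- function(fractions, nrow = 200, ncol = 200,
                                      cell_um = 0.5, seed = NULL) {
  full <- stats::setNames(numeric(length(COMPOSITION_LEVELS)),
                          COMPOSITION_LEVELS)
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% COMPOSITION_LEVELS)) {
    stop("fractions must be named with classes among {",
         paste(COMPOSITION_LEVELS, collapse = ", "), "}", call. = FALSE)
  }
  full[names(fractions)] <- fractions
  if (any(full < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (abs(sum(full) - 1) > 1e-9) {
    stop(sprintf("fractions must sum to 1 (got %.6f)", sum(full)),
         call. = FALSE)
  }
  with_seed(seed, {
    labels <- sample.int(length(full), nrow * ncol, replace = TRUE,
                         prob = full)
    g <- matrix(as.integer(labels), nrow = nrow, ncol = ncol)
    structure(g, legend = COMPOSITION_LEVELS, cell_um = cell_um,
              class = c("composition_grid", "matrix", "array"))
  })
}

#' Read and write composition grids as CSV with a JSON legend sidecar
#'
#' The grid is stored as a plain integer CSV (no header) and the legend and
#' cell size as `<path>.json`.
#'
#' @param grid a `composition_grid`.
#' @param path CSV file path.
#' @return `read_composition_grid` returns a `composition_grid`.
#' @export
write_composition_grid <- function(grid, path) {
  utils::write.table(unclass(grid), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(legend = as.list(stats::setNames(
    seq_along(attr(grid, "legend")), attr(grid, "legend"))),
    cell_um = attr(grid, "cell_um"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_composition_grid
#' @export
read_composition_grid <- function(path) {
  g <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(g) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  legend <- character(length(meta$legend))
  for (nm in names(meta$legend)) legend[meta$legend[[nm]]] <- nm
  structure(matrix(as.integer(g), nrow(g), ncol(g)), legend = legend,
            cell_um = meta$cell_um,
            class = c("composition_grid", "matrix", "array"))
}
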