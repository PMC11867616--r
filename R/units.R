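#' Unit conversions between nanometres and micrometres
#'
#' All geometry inside the package is carried in nanometres (coordinates,
#' distances, radii) and square nanometres (areas); densities are reported
#' per cubic micrometre. These helpers centralise the conversions so no
#' magic powers of ten appear elsewhere.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
nm_to_um <- function(x) x / 1e3

#' @rdname units
#' @export
um_to_nm <- function(x) x * 1e3

#' @rdname units
#' @export
nm3_to_um3 <- function(x) x / 1e9

#' @rdname units
#' @export
um3_to_nm3 <- function(x) x * 1e9

# Run a block with a locally-set RNG state, restoring the caller's stream.
# `seed = NULL` leaves the global stream untouched (draws advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-stage substream seeds derived from one run seed.
# Keeps every derived seed a valid 32-bit integer.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(as.character(stage))) * 7919
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
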