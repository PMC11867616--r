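#' Dress centroids into a synapse population
#'
#' Turns bare centroids into one record per synapse: AS/SS type drawn
#' Bernoulli from the layer's AS fraction, SAS area drawn log-normal with
#' the type's `(mu, sigma)`, junction shape and postsynaptic target drawn
#' from the type's categoricals, and spine-targeted synapses grouped into
#' dendritic spines following the spine occupancy composition. A spatial
#' extent proxy `radius_nm = sqrt(sas_area / (4 * pi))` accompanies every
#' record so counting-frame rules can act on whole objects, not centroids.
#'
#' Spine grouping draws occupancy classes (single AS, AS+SS spine, single
#' SS, other multisynaptic) and consumes synapses from the AS and SS
#' spine-targeted pools; classes that the remaining pools cannot supply are
#' dropped from the draw, so extreme configurations degrade gracefully.
#' Each spine is then flagged complete or incomplete (truncated by the
#' stack border) with the profile's incomplete-spine probability.
#'
#' @param centroids n x 3 matrix from [generate_centroids()] (nm).
#' @param profile a [layer_profile()].
#' @param seed integer seed for reproducible draws.
#' @param case,stack identifiers stamped on every record.
#' @return a `data.frame` of class `synapse_population` with columns
#'   `id, x_nm, y_nm, z_nm, radius_nm, type, sas_area_nm2, shape, target,
#'   spine_id, spine_complete, layer, case, stack`.
#' @examples
#' pts <- generate_centroids("poisson", n = 50, seed = 1)
#' pop <- assign_attributes(pts, mec_layer_profiles()[["I"]], seed = 2)
#' table(pop$type)
#' @export
assign_attributes <- function(centroids, profile, seed = NULL,
                              case = "sim", stack = "stack1") {
  stopifnot(inherits(profile, "layer_profile"))
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n == 0) return(empty_population())

  with_seed(seed, {
    type <- ifelse(stats::runif(n) < profile$as_fraction, "AS", "SS")
    is_as <- type == "AS"
    sas <- numeric(n)
    sas[is_as] <- stats::rlnorm(sum(is_as), profile$mu_as, profile$sigma_as)
    sas[!is_as] <- stats::rlnorm(sum(!is_as), profile$mu_ss, profile$sigma_ss)
    shape <- character(n)
    shape[is_as] <- draw_cat(sum(is_as), profile$shape_probs_as)
    shape[!is_as] <- draw_cat(sum(!is_as), profile$shape_probs_ss)
    target <- character(n)
    target[is_as] <- draw_cat(sum(is_as), profile$target_probs_as)
    target[!is_as] <- draw_cat(sum(!is_as), profile$target_probs_ss)

    pop <- data.frame(
      id = seq_len(n),
      x_nm = centroids[, 1], y_nm = centroids[, 2], z_nm = centroids[, 3],
      radius_nm = sqrt(sas / (4 * pi)),
      type = type, sas_area_nm2 = sas, shape = shape, target = target,
      spine_id = NA_character_, spine_complete = NA,
      layer = profile$layer_id, case = case, stack = stack,
      stringsAsFactors = FALSE
    )
    pop <- group_spines(pop, profile)
    class(pop) <- c("synapse_population", "data.frame")
    pop
  })
}

draw_cat <- function(n, probs) {
  if (n == 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

empty_population <- function() {
  pop <- data.frame(
    id = integer(0), x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
    radius_nm = numeric(0), type = character(0), sas_area_nm2 = numeric(0),
    shape = character(0), target = character(0), spine_id = character(0),
    spine_complete = logical(0), layer = character(0), case = character(0),
    stack = character(0), stringsAsFactors = FALSE
  )
  class(pop) <- c("synapse_population", "data.frame")
  pop
}

# Consume spine-targeted synapses into spines according to the occupancy
# composition. single_AS: one AS; AS_SS: one AS and one SS; single_SS: one
# SS; other: two AS (the commonest multi-AS configuration).
group_spines <- function(pop, profile) {
  on_spine <- pop$target %in% c("spine_head", "spine_neck")
  shuffle <- function(x) if (length(x) > 1) sample(x) else x
  as_pool <- shuffle(which(on_spine & pop$type == "AS"))
  ss_pool <- shuffle(which(on_spine & pop$type == "SS"))
  probs <- profile$spine_composition_probs
  need_as <- c(single_AS = 1, AS_SS = 1, single_SS = 0, other = 2)
  need_ss <- c(single_AS = 0, AS_SS = 1, single_SS = 1, other = 0)
  spine_counter <- 0L
  while (length(as_pool) + length(ss_pool) > 0) {
    feasible <- need_as <= length(as_pool) & need_ss <= length(ss_pool)
    p <- probs * feasible
    if (sum(p) == 0) { # leftovers become single-synapse spines
      cls <- if (length(as_pool) > 0) "single_AS" else "single_SS"
    } else {
      cls <- sample(names(probs), 1, prob = p)
    }
    spine_counter <- spine_counter + 1L
    sid <- sprintf("sp%05d", spine_counter)
    take_as <- min(need_as[[cls]], length(as_pool))
    take_ss <- min(need_ss[[cls]], length(ss_pool))
    members <- c(utils::head(as_pool, take_as), utils::head(ss_pool, take_ss))
    as_pool <- utils::tail(as_pool, length(as_pool) - take_as)
    ss_pool <- utils::tail(ss_pool, length(ss_pool) - take_ss)
    pop$spine_id[members] <- sid
    pop$spine_complete[members] <-
      stats::runif(1) >= profile$incomplete_spine_prob
  }
  pop
}

#' Simulate one stack of synthetic neuropil
#'
#' Convenience wrapper: centroids from the spatial model at the profile's
#' density (conditional on the rounded expected count), then attributes via
#' [assign_attributes()].
#'
#' @param profile a [layer_profile()].
#' @param window a [volume_window()].
#' @param model a [spatial_model()] (default CSR).
#' @param n point count; default `round(density * effective volume)`. The
#'   profile density is a count per artifact-free um^3 (the convention of
#'   counting-frame reports), so the artifact fraction of the window scales
#'   the expected count down while the points still spread over the whole
#'   box (artifacts are metadata, not holes).
#' @param seed integer seed (substreams are derived for the two stages).
#' @param case,stack identifiers.
#' @return a `synapse_population` with the window attached as attribute
#'   `window`.
#' @export
simulate_stack <- function(profile, window = volume_window(),
                           model = spatial_model("poisson"), n = NULL,
                           seed = NULL, case = "sim", stack = "stack1") {
  n <- n %||% round(profile$density * window_effective_volume_um3(window))
  pts <- generate_centroids(model, n = n, window = window,
                            seed = stage_seed(seed, "centroids"))
  pop <- assign_attributes(pts, profile, seed = stage_seed(seed, "attributes"),
                           case = case, stack = stack)
  attr(pop, "window") <- window
  pop
}

#' @export
print.synapse_population <- function(x, ...) {
  cat(sprintf("synapse population: %d synapses (%d AS, %d SS)\n",
              nrow(x), sum(x$type == "AS"), sum(x$type == "SS")))
  if (nrow(x) > 0) {
    cat(sprintf("  layers: %s\n", paste(unique(x$layer), collapse = ", ")))
  }
  invisible(x)
}
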