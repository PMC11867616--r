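SHAPE_LEVELS <- c("macular", "perforated", "horseshoe", "fragmented")
TARGET_LEVELS <- c("spine_head", "spine_neck", "spiny_shaft", "aspiny_shaft")
SPINE_CLASSES <- c("single_AS", "AS_SS", "single_SS", "other")
COMPOSITION_LEVELS <- c("neuropil", "neuron", "glia", "undetermined", "vessel")
LAYER_LEVELS <- c("I", "II-is", "II-ni", "III", "Va/b", "Vc", "VI")

check_probs <- function(p, levels, field) {
  if (is.null(names(p))) names(p) <- levels[seq_along(p)]
  if (!setequal(names(p), levels)) {
    stop(sprintf("%s must have probabilities for {%s}", field,
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  p <- p[levels]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must be nonnegative and sum to 1 (got %.12f)",
                 field, sum(p)), call. = FALSE)
  }
  p
}

#' Per-layer generative parameters for synthetic neuropil
#'
#' A `layer_profile` bundles everything needed to simulate the synapse
#' population of one cortical layer: overall synapse density, the AS/SS
#' split, log-normal synaptic apposition surface (SAS) area parameters per
#' type, shape and postsynaptic-target categoricals per type, the spine
#' occupancy composition, and the incomplete-spine rate.
#'
#' SAS areas are log-normal; instead of `mu` you may give `mean_sas`, and
#' `mu` is solved from `mean = exp(mu + sigma^2/2)`.
#'
#' @param layer_id layer label, one of `r paste(LAYER_LEVELS, collapse=", ")`.
#' @param density synapses per um^3 (> 0).
#' @param as_fraction fraction of synapses that are asymmetric (AS), `[0,1]`.
#' @param mean_sas_as,mean_sas_ss mean SAS area in nm^2 per type (used to
#'   solve `mu` when it is not given directly).
#' @param sigma_as,sigma_ss SD of log SAS area (log-units).
#' @param mu_as,mu_ss mean of log SAS area (log-nm^2); overrides the mean.
#' @param shape_probs_as,shape_probs_ss named categoricals over
#'   macular/perforated/horseshoe/fragmented.
#' @param target_probs_as,target_probs_ss named categoricals over
#'   spine_head/spine_neck/spiny_shaft/aspiny_shaft.
#' @param spine_composition_probs named categorical over spine occupancy
#'   classes single_AS/AS_SS/single_SS/other.
#' @param incomplete_spine_prob probability a spine is truncated by the
#'   stack boundary and flagged incomplete.
#'
#' @return An object of class `layer_profile`.
#' @seealso [mec_layer_profiles()] for the calibrated defaults.
#' @export
layer_profile <- function(layer_id, density, as_fraction,
                          mean_sas_as = NULL, mean_sas_ss = NULL,
                          sigma_as = 0.8, sigma_ss = 0.8,
                          mu_as = NULL, mu_ss = NULL,
                          shape_probs_as = NULL, shape_probs_ss = NULL,
                          target_probs_as = NULL, target_probs_ss = NULL,
                          spine_composition_probs = NULL,
                          incomplete_spine_prob = 0.15) {
  if (!is.finite(density) || density <= 0) {
    stop("density must be > 0 (synapses per um^3)", call. = FALSE)
  }
  if (as_fraction < 0 || as_fraction > 1) {
    stop("as_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (sigma_as < 0 || sigma_ss < 0) stop("sigma must be >= 0", call. = FALSE)
  solve_mu <- function(mu, mean, sigma, which) {
    if (!is.null(mu)) return(mu)
    if (is.null(mean) || mean <= 0) {
      stop(sprintf("give mu_%s or a positive mean_sas_%s", which, which),
           call. = FALSE)
    }
    log(mean) - sigma^2 / 2
  }
  mu_as <- solve_mu(mu_as, mean_sas_as, sigma_as, "as")
  mu_ss <- solve_mu(mu_ss, mean_sas_ss, sigma_ss, "ss")

  # Aggregate defaults: 84% of AS and 76% of SS are macular, the complex
  # remainder split evenly over perforated/horseshoe/fragmented.
  complex_split <- function(mac) c(macular = mac, perforated = (1 - mac) / 3,
                                   horseshoe = (1 - mac) / 3,
                                   fragmented = (1 - mac) / 3)
  shape_probs_as <- check_probs(shape_probs_as %||% complex_split(0.84),
                                SHAPE_LEVELS, "shape_probs_as")
  shape_probs_ss <- check_probs(shape_probs_ss %||% complex_split(0.76),
                                SHAPE_LEVELS, "shape_probs_ss")
  # Whole-cortex target mix: shares of all synapses 59.3 / 0.5 / 34.3 (AS
  # head / neck / shaft of 94.1% AS) and 0.7 / 0.1 / 5.1 (of 5.9% SS),
  # renormalised within type; shaft share split evenly spiny/aspiny.
  target_probs_as <- check_probs(
    target_probs_as %||% c(spine_head = 59.3 / 94.1, spine_neck = 0.5 / 94.1,
                           spiny_shaft = 17.15 / 94.1,
                           aspiny_shaft = 17.15 / 94.1),
    TARGET_LEVELS, "target_probs_as")
  target_probs_ss <- check_probs(
    target_probs_ss %||% c(spine_head = 0.7 / 5.9, spine_neck = 0.1 / 5.9,
                           spiny_shaft = 2.55 / 5.9, aspiny_shaft = 2.55 / 5.9),
    TARGET_LEVELS, "target_probs_ss")
  spine_composition_probs <- check_probs(
    spine_composition_probs %||% c(single_AS = 0.96, AS_SS = 0.0073,
                                   single_SS = 0.0050, other = 0.0277),
    SPINE_CLASSES, "spine_composition_probs")
  if (incomplete_spine_prob < 0 || incomplete_spine_prob > 1) {
    stop("incomplete_spine_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(layer_id = layer_id, density = density, as_fraction = as_fraction,
         mu_as = mu_as, sigma_as = sigma_as, mu_ss = mu_ss,
         sigma_ss = sigma_ss, shape_probs_as = shape_probs_as,
         shape_probs_ss = shape_probs_ss, target_probs_as = target_probs_as,
         target_probs_ss = target_probs_ss,
         spine_composition_probs = spine_composition_probs,
         incomplete_spine_prob = incomplete_spine_prob),
    class = "layer_profile"
  )
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf(
    "layer %s: %.2f syn/um^3, %.1f%% AS, mean SAS AS %.0f / SS %.0f nm^2\n",
    x$layer_id, x$density, 100 * x$as_fraction,
    exp(x$mu_as + x$sigma_as^2 / 2), exp(x$mu_ss + x$sigma_ss^2 / 2)))
  invisible(x)
}

#' Implied mean SAS area of a layer profile
#'
#' @param profile a [layer_profile()].
#' @param type `"AS"` or `"SS"`.
#' @return mean of the configured log-normal, `exp(mu + sigma^2/2)`, nm^2.
#' @export
profile_mean_sas <- function(profile, type = c("AS", "SS")) {
  type <- match.arg(type)
  if (type == "AS") exp(profile$mu_as + profile$sigma_as^2 / 2)
  else exp(profile$mu_ss + profile$sigma_ss^2 / 2)
}

#' Calibrated per-layer profiles for the human medial entorhinal cortex
#'
#' Default generative parameters for layers I, II (island and inter-island),
#' III, Va/b, Vc and VI: shrinkage-corrected overall synapse density, AS
#' percentage, and mean SAS area per type, as tabulated for the human MEC.
#' Shape, target and spine-composition categoricals use the whole-cortex
#' aggregate defaults of [layer_profile()].
#'
#' @return named list of [layer_profile()] objects, one per layer.
#' @examples
#' profs <- mec_layer_profiles()
#' profs[["III"]]
#' @export
mec_layer_profiles <- function() {
  tab <- data.frame(
    layer = LAYER_LEVELS,
    density = c(0.47, 0.42, 0.44, 0.40, 0.35, 0.41, 0.36),
    as_pct = c(94.0, 92.6, 93.1, 94.1, 95.8, 93.5, 95.6),
    mean_as = c(105906, 118070, 118550, 130268, 136111, 126298, 99489),
    mean_ss = c(53367, 67492, 73141, 74248, 74698, 87377, 69365)
  )
  profs <- lapply(seq_len(nrow(tab)), function(i) {
    layer_profile(tab$layer[i], density = tab$density[i],
                  as_fraction = tab$as_pct[i] / 100,
                  mean_sas_as = tab$mean_as[i], mean_sas_ss = tab$mean_ss[i])
  })
  names(profs) <- tab$layer
  profs
}
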