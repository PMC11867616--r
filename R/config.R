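#' Load a pipeline run configuration
#'
#' Reads a YAML configuration (per-layer generative parameters, window and
#' counting-frame geometry, spatial-analysis settings, composition-grid
#' settings) and validates it. The packaged default encodes the published
#' per-layer calibration for the human medial entorhinal cortex.
#'
#' @param path YAML file; default the packaged
#'   `extdata/mec_default_config.yaml`.
#' @return object of class `run_config`: validated list with an added
#'   `profiles` element (named list of [layer_profile()]s) and
#'   `composition_fractions` per layer.
#' @examples
#' cfg <- load_run_config()
#' names(cfg$profiles)
#' @export
load_run_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mec_default_config.yaml",
                                package = "synstereo")
  cfg <- yaml::read_yaml(path)
  required <- c("window", "layers", "spatial", "shrinkage")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("config missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  w <- cfg$window
  if (any(unlist(w[c("x_len_nm", "y_len_nm", "z_len_nm")]) <= 0)) {
    stop("window lengths must be positive", call. = FALSE)
  }
  cfg$frame_margin_nm <- cfg$frame_margin_nm %||% 400
  cfg$n_stacks_per_layer <- cfg$n_stacks_per_layer %||% 9
  cfg$artifact_fraction <- cfg$artifact_fraction %||% 0.10
  cfg$sas_sigma <- cfg$sas_sigma %||% 0.8
  cfg$incomplete_spine_prob <- cfg$incomplete_spine_prob %||% 0.15
  cfg$spatial$n_sim <- cfg$spatial$n_sim %||% 99
  cfg$spatial$min_run <- cfg$spatial$min_run %||% 3
  cfg$spatial$correction <- cfg$spatial$correction %||% "border"
  sf <- cfg$shrinkage
  cfg$factors <- shrinkage_factors(sf$volume %||% 0.90, sf$area %||% 0.93,
                                   sf$linear %||% 0.97)

  comp_probs <- if (!is.null(cfg$spine_composition)) {
    unlist(cfg$spine_composition)
  } else NULL
  cfg$profiles <- lapply(names(cfg$layers), function(ly) {
    l <- cfg$layers[[ly]]
    layer_profile(
      ly, density = l$density, as_fraction = l$as_pct / 100,
      mean_sas_as = l$mean_sas_as, mean_sas_ss = l$mean_sas_ss,
      sigma_as = l$sigma %||% cfg$sas_sigma,
      sigma_ss = l$sigma %||% cfg$sas_sigma,
      spine_composition_probs = comp_probs,
      incomplete_spine_prob = cfg$incomplete_spine_prob
    )
  })
  names(cfg$profiles) <- names(cfg$layers)
  cfg$composition_fractions <- lapply(cfg$layers, function(l) {
    fr <- unlist(l[intersect(COMPOSITION_LEVELS, names(l))])
    if (length(fr) > 0 && abs(sum(fr) - 1) > 1e-9) {
      stop("layer composition fractions must sum to 1", call. = FALSE)
    }
    fr
  })
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run config: %d layers x %d stacks, window %.0f x %.0f x %.0f nm\n",
    length(x$profiles), x$n_stacks_per_layer, x$window$x_len_nm,
    x$window$y_len_nm, x$window$z_len_nm))
  invisible(x)
}
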