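#' Filter a population for size analyses
#'
#' For target-stratified size analyses, synapses established on incomplete
#' dendritic spines (spines truncated by the stack border, whose head may
#' carry unseen synapses) are removed; shaft synapses and synapses on
#' complete spines are kept. Type- and layer-level analyses use the full
#' population and should not apply this filter.
#'
#' @param population a `synapse_population`.
#' @param drop_incomplete_spines apply the exclusion (default `TRUE`).
#' @return filtered `synapse_population`.
#' @export
filter_for_size_analysis <- function(population,
                                     drop_incomplete_spines = TRUE) {
  if (!drop_incomplete_spines) return(population)
  on_spine <- population$target %in% c("spine_head", "spine_neck")
  keep <- !on_spine | (!is.na(population$spine_complete) &
                         population$spine_complete)
  population[keep, , drop = FALSE]
}

#' Group summaries of SAS area
#'
#' Mean, standard error (sample SD over sqrt(n)) and n of the synaptic
#' apposition surface area per group. Optionally adds shrinkage-corrected
#' columns (areas divided by the area factor).
#'
#' @param population a `synapse_population` (or data frame with
#'   `sas_area_nm2`).
#' @param group_by character vector of grouping columns (e.g. `"type"`,
#'   `c("layer", "type")`); `NULL` summarises the whole sample.
#' @param corrected also report shrinkage-corrected mean/SE.
#' @param factors a [shrinkage_factors()].
#' @return data frame with the group columns plus `n`, `mean_nm2`, `se_nm2`
#'   (and `mean_corrected_nm2`, `se_corrected_nm2`). `se_nm2` is `NA` for
#'   singleton groups.
#' @export
summarize_sizes <- function(population, group_by = "type", corrected = TRUE,
                            factors = shrinkage_factors()) {
  if (nrow(population) == 0) {
    stop("no synapses to summarise", call. = FALSE)
  }
  x <- population$sas_area_nm2
  if (any(x <= 0)) stop("sas_area_nm2 must be positive", call. = FALSE)
  key <- if (is.null(group_by)) rep("all", length(x)) else {
    interaction(population[group_by], drop = TRUE, sep = "|")
  }
  groups <- split(x, key)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean_nm2 = mean(v),
               se_nm2 = if (length(v) > 1) {
                 stats::sd(v) / sqrt(length(v))
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(group_by)) {
    labs <- do.call(rbind, strsplit(out$group, "|", fixed = TRUE))
    colnames(labs) <- group_by
    out <- cbind(as.data.frame(labs, stringsAsFactors = FALSE),
                 out[c("n", "mean_nm2", "se_nm2")])
  } else {
    out$group <- NULL
  }
  if (corrected) {
    out$mean_corrected_nm2 <- apply_shrinkage(out$mean_nm2, "area", factors)
    out$se_corrected_nm2 <- out$se_nm2 / factors$area
  }
  rownames(out) <- NULL
  out
}

#' Log-normal maximum-likelihood fit of SAS areas
#'
#' `mu` and `sigma` are the MLEs on the log scale (mean of logs; SD of logs
#' with the `n` denominator). Goodness of fit is a one-sample
#' Kolmogorov-Smirnov distance against the fitted log-normal; because the
#' parameters are estimated from the same data, the p-value is approximate
#' (anti-conservative) and labelled as such.
#'
#' @param x positive numeric vector, `n >= 3` (SAS areas in nm^2).
#' @return object of class `lognormal_fit`: `mu`, `sigma`, `n`, `mean_nm2`
#'   (implied `exp(mu + sigma^2/2)`), `gof_statistic`, `gof_p_approx`.
#' @examples
#' fit <- fit_lognormal(rlnorm(500, 11.6, 0.8))
#' c(fit$mu, fit$sigma)
#' @export
fit_lognormal <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2)) # MLE (population) form
  gof <- if (sigma > 0) {
    suppressWarnings(stats::ks.test(x, stats::plnorm, meanlog = mu,
                                    sdlog = sigma))
  } else NULL
  structure(
    list(mu = mu, sigma = sigma, n = length(x),
         mean_nm2 = exp(mu + sigma^2 / 2),
         gof_statistic = if (is.null(gof)) NA_real_ else unname(gof$statistic),
         gof_p_approx = if (is.null(gof)) NA_real_ else gof$p.value),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "log-normal fit: mu = %.3f, sigma = %.3f (implied mean %.0f nm^2, n = %d)\n",
    x$mu, x$sigma, x$mean_nm2, x$n))
  cat(sprintf("  KS distance to fit: %.4f (approximate p = %.3g)\n",
              x$gof_statistic, x$gof_p_approx))
  invisible(x)
}

#' Two-sample comparison of SAS size distributions
#'
#' Two-sample Kolmogorov-Smirnov test (sup distance between empirical
#' CDFs) with asymptotic p-value; per the synapse-level reporting
#' convention, significance is declared at p < 1e-4.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param alpha significance threshold (default `1e-4`, the synapse-level
#'   convention).
#' @return list: `statistic`, `p_value`, `significant`, `n_a`, `n_b`.
#' @export
compare_size_distributions <- function(a, b, alpha = 1e-4) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha, n_a = length(a), n_b = length(b))
}

#' Equal-count bins for frequency-distribution plots
#'
#' Splits a sample into `n_bins` quantile bins (default 20) and returns the
#' bin centres and relative frequencies, the form used for size
#' frequency-distribution figures.
#'
#' @param x numeric sample.
#' @param n_bins number of equal-count bins.
#' @return data frame `bin_center`, `frequency`.
#' @export
size_frequency_bins <- function(x, n_bins = 20L) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  qs[1] <- qs[1] - 1e-9
  cuts <- cut(x, breaks = unique(qs), include.lowest = TRUE)
  centers <- tapply(x, cuts, stats::median)
  data.frame(bin_center = as.numeric(centers),
             frequency = as.numeric(table(cuts)) / length(x))
}
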