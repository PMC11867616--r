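#' Significance threshold by sampling unit
#'
#' The reporting convention uses two thresholds: p < 0.05 when the
#' statistical unit is subjects or image stacks, p < 1e-4 when the unit is
#' individual synapses (where the enormous n makes tiny effects
#' "significant" at conventional levels).
#'
#' @param unit `"stack"`, `"subject"` or `"synapse"`.
#' @return numeric threshold.
#' @export
significance_threshold <- function(unit = c("stack", "subject", "synapse")) {
  unit <- match.arg(unit)
  if (unit == "synapse") 1e-4 else 0.05
}

#' Category proportions and ratio strings
#'
#' Percentages per category (full precision; round only when formatting)
#' and, for two categories, the integer ratio string used in prose (e.g.
#' "94:6").
#'
#' @param counts named nonnegative counts.
#' @return object of class `proportion_result`: `percent` (named), `n`,
#'   `ratio` (two categories only, integers summing to 100).
#' @examples
#' category_proportions(c(AS = 8605, SS = 541))$percent[["AS"]]
#' @export
category_proportions <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  pct <- counts * 100 / total
  ratio <- if (length(counts) == 2) {
    a <- round_half_up(pct[[1]], 0)
    paste0(a, ":", 100 - a)
  } else NA_character_
  structure(list(percent = pct, n = total, ratio = ratio),
            class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(paste(sprintf("%s %.1f%%", names(x$percent), x$percent),
            collapse = ", "), sprintf("(n = %d)\n", x$n))
  invisible(x)
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pairwise chi-square tests on a contingency table
#'
#' Pearson chi-square (no continuity correction) on the 2 x C slice of each
#' requested pair of rows, Bonferroni-adjusted over the pairs actually run.
#'
#' @param table matrix of counts, rows = groups, columns = categories.
#' @param pairs list of length-2 vectors of row names/indices; default all
#'   row pairs.
#' @param unit sampling unit for the significance call (see
#'   [significance_threshold()]); synapse counts by default.
#' @return data frame: `group1, group2, statistic, df, p, p_adjusted,
#'   significant, testable`.
#' @examples
#' m <- rbind(I = c(AS = 1265, SS = 80), VI = c(AS = 1177, SS = 53))
#' chi_square_pairwise(m)
#' @export
chi_square_pairwise <- function(table, pairs = NULL, unit = "synapse") {
  table <- as.matrix(table)
  if (is.null(rownames(table))) {
    rownames(table) <- paste0("g", seq_len(nrow(table)))
  }
  if (is.null(pairs)) {
    pairs <- utils::combn(rownames(table), 2, simplify = FALSE)
  }
  alpha <- significance_threshold(unit)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    slice <- table[pr, , drop = FALSE]
    ok <- all(rowSums(slice) > 0) && all(colSums(slice) > 0)
    if (ok) {
      ct <- suppressWarnings(stats::chisq.test(slice, correct = FALSE))
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, testable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group1 = pr[1], group2 = pr[2], statistic = NA_real_,
                 df = NA_real_, p = NA_real_, testable = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  res$p_adjusted <- pmin(1, res$p * sum(res$testable))
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}

#' Nonparametric group comparisons (Mann-Whitney, Kruskal-Wallis, Dunn)
#'
#' Two groups: Mann-Whitney U (Wilcoxon rank-sum, tie-corrected normal
#' approximation). Three or more: Kruskal-Wallis H with tie correction,
#' followed by Dunn's pairwise z tests (Bonferroni-adjusted over all pairs)
#' only when the omnibus test is significant at the unit's threshold.
#'
#' @param samples named list of numeric vectors, each nonempty.
#' @param unit sampling unit for thresholds (default `"stack"`).
#' @return list: `test` ("mann_whitney" or "kruskal_wallis"), `statistic`,
#'   `p`, `significant`, and for k groups a `posthoc` data frame
#'   (`group1, group2, z, p, p_adjusted, significant`), `NULL` when the
#'   omnibus is not significant.
#' @examples
#' rank_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
rank_tests <- function(samples, unit = "stack") {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(vapply(samples, length, integer(1)) == 0)) {
    stop("all samples must be nonempty", call. = FALSE)
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0("g", seq_along(samples))
  }
  alpha <- significance_threshold(unit)
  if (length(samples) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(samples[[1]], samples[[2]],
                                              exact = FALSE, correct = FALSE))
    return(list(test = "mann_whitney", statistic = unname(wt$statistic),
                p = wt$p.value, significant = wt$p.value < alpha,
                posthoc = NULL))
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), vapply(samples, length, integer(1))),
              levels = names(samples))
  kw <- stats::kruskal.test(x, g)
  sig <- isTRUE(kw$p.value < alpha) # all-ties data give NaN: not significant
  posthoc <- if (sig) dunn_test(x, g) else NULL
  list(test = "kruskal_wallis", statistic = unname(kw$statistic),
       p = kw$p.value, significant = sig, posthoc = posthoc)
}

# Dunn's pairwise z statistics on joint ranks with tie correction,
# Bonferroni over all pairs.
dunn_test <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    z <- (mean_r[[pr[1]]] - mean_r[[pr[2]]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- pmin(1, res$p * nrow(res))
  res$significant <- res$p_adjusted < 0.05
  res
}

#' Coefficient of variation
#'
#' `CV% = 100 * SD / mean` per group (SD with the n-1 denominator), the
#' between-case and between-stack variability measure.
#'
#' @param values numeric vector (one value per case or stack).
#' @return percent; `NA` with a warning when the mean is zero or `n < 2`.
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) {
    warning("CV undefined for n < 2")
    return(NA_real_)
  }
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined for zero mean")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Spine occupancy classes
#'
#' Classifies each dendritic spine by the multiset of synapses it carries:
#' `single_AS`, `single_SS`, `AS_SS` (exactly one of each), or `other`
#' (any other multisynaptic combination).
#'
#' @param population a `synapse_population` with `spine_id` set on
#'   spine-targeted synapses.
#' @return data frame: `class`, `n_spines`, `percent`.
#' @export
tabulate_spine_occupancy <- function(population) {
  on_spine <- !is.na(population$spine_id)
  if (any(on_spine &
          !population$target %in% c("spine_head", "spine_neck"))) {
    stop("spine_id set on a non-spine-targeted synapse", call. = FALSE)
  }
  spines <- split(population$type[on_spine], population$spine_id[on_spine])
  if (length(spines) == 0) {
    return(data.frame(class = SPINE_CLASSES, n_spines = 0L,
                      percent = NA_real_))
  }
  cls <- vapply(spines, function(tps) {
    n_as <- sum(tps == "AS"); n_ss <- sum(tps == "SS")
    if (n_as == 1 && n_ss == 0) "single_AS"
    else if (n_as == 0 && n_ss == 1) "single_SS"
    else if (n_as == 1 && n_ss == 1) "AS_SS"
    else "other"
  }, character(1))
  tab <- table(factor(cls, levels = SPINE_CLASSES))
  data.frame(class = names(tab), n_spines = as.integer(tab),
             percent = as.numeric(tab) * 100 / length(cls),
             stringsAsFactors = FALSE)
}
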