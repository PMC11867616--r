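#' Run the full synthetic-neuropil analysis pipeline
#'
#' End-to-end orchestration: for every layer in the configuration, simulate
#' `n_stacks_per_layer` FIB/SEM-sized stacks (or analyse supplied
#' populations), count synapses with the unbiased 3D counting frame,
#' estimate densities against the artifact-corrected frame volume, measure
#' intersynaptic distances, classify the spatial pattern against CSR
#' envelopes, summarise and fit SAS sizes, estimate tissue volume fractions
#' by Cavalieri point counting, and assemble the per-layer report with
#' corrected and uncorrected columns linked by the shrinkage identities.
#'
#' All randomness is driven by `seed` through per-stage substreams, so a
#' fixed `(config, seed)` pair reproduces the report exactly.
#'
#' @param config a `run_config` from [load_run_config()].
#' @param seed integer run seed.
#' @param populations optional named list (by layer) of lists of
#'   `synapse_population`s to analyse instead of simulating.
#' @param run_spatial run the CSR-envelope classification per stack (the
#'   most expensive stage); `FALSE` leaves verdicts `NA`.
#' @param n_stacks,n_sim optional overrides of the config values.
#' @return object of class `analysis_report`; see Details.
#' @details The report contains `layer_table` (per-layer and pooled rows:
#'   counts, percentages, densities as mean over stacks with SD, SAS means
#'   with SE, intersynaptic distances — measured values plus
#'   shrinkage-corrected twins), `cv_table` (between-stack coefficients of
#'   variation), `spatial_table` (per-stack verdicts), `vv_table`
#'   (Cavalieri volume fractions), `occupancy` (spine occupancy classes),
#'   `tests` (tidy cross-layer comparisons: Kruskal-Wallis on densities and
#'   AS SAS areas, pairwise chi-square on AS:SS splits, each with its
#'   sampling unit and threshold),
#'   `fits` (per-layer/type log-normal parameters) and `seed`.
#' @examples
#' \donttest{
#' cfg <- load_run_config()
#' rep <- run_pipeline(cfg, seed = 1, run_spatial = FALSE, n_stacks = 2)
#' rep$layer_table[, c("layer", "n_all", "pct_as")]
#' }
#' @export
run_pipeline <- function(config = load_run_config(), seed = 1,
                         populations = NULL, run_spatial = TRUE,
                         n_stacks = NULL, n_sim = NULL) {
  stopifnot(inherits(config, "run_config"))
  n_stacks <- n_stacks %||% config$n_stacks_per_layer
  n_sim <- n_sim %||% config$spatial$n_sim
  window <- volume_window(config$window$x_len_nm, config$window$y_len_nm,
                          config$window$z_len_nm,
                          artifact_fraction = config$artifact_fraction)
  margin <- config$frame_margin_nm
  frame <- counting_frame(
    lo = rep(margin, 3),
    hi = c(window$x_len, window$y_len, window$z_len) - margin,
    artifact_fraction = config$artifact_fraction
  )
  factors <- config$factors

  layer_rows <- list()
  cv_rows <- list()
  spatial_rows <- list()
  vv_rows <- list()
  occ_all <- list()
  fits <- list()
  pooled <- list(pop = list(), nn = list(), dens = list())

  for (ly in names(config$profiles)) {
    profile <- config$profiles[[ly]]
    stacks <- lapply(seq_len(n_stacks), function(s) {
      if (!is.null(populations)) return(populations[[ly]][[s]])
      simulate_stack(profile, window,
                     seed = stage_seed(seed, paste0(ly, "_", s)),
                     case = "sim", stack = sprintf("%s_s%02d", ly, s))
    })

    per_stack <- lapply(seq_along(stacks), function(s) {
      pop <- stacks[[s]]
      dens <- estimate_density(pop, frame)
      counted <- pop[classify_against_frame(pop, frame) == "counted", ,
                     drop = FALSE]
      nn <- if (nrow(pop) >= 2) {
        nearest_neighbor_distances(point_pattern3d(pop, window))
      } else NULL
      verdict <- NA_character_
      if (run_spatial && nrow(pop) >= 10) {
        cls <- classify_spatial_pattern(
          point_pattern3d(pop, window), n_sim = n_sim,
          correction = config$spatial$correction,
          min_run = config$spatial$min_run,
          seed = stage_seed(seed, paste0("spatial_", ly, "_", s)))
        verdict <- cls$verdict
      }
      list(pop = pop, counted = counted, dens = dens, nn = nn,
           verdict = verdict,
           stack = if (nrow(pop) > 0) pop$stack[1] else "empty")
    })

    counted_all <- do.call(rbind, lapply(per_stack, `[[`, "counted"))
    if (is.null(counted_all)) counted_all <- empty_population()
    nn_pool <- unlist(lapply(per_stack, function(x) {
      if (is.null(x$nn)) numeric(0) else x$nn$distances_nm
    }))
    dens_all <- vapply(per_stack, function(x) x$dens$density_per_um3,
                       numeric(1))
    dens_as <- vapply(per_stack, function(x) {
      sum(x$counted$type == "AS") / x$dens$effective_volume_um3
    }, numeric(1))
    dens_ss <- vapply(per_stack, function(x) {
      sum(x$counted$type == "SS") / x$dens$effective_volume_um3
    }, numeric(1))

    layer_rows[[ly]] <- layer_summary_row(
      ly, counted_all, dens_as, dens_ss, dens_all,
      frame$effective_volume_um3 * n_stacks, nn_pool, factors)

    # between-stack variability of the headline parameters
    sas_as_stack <- vapply(per_stack, function(x) {
      v <- x$counted$sas_area_nm2[x$counted$type == "AS"]
      if (length(v) > 0) mean(v) else NA_real_
    }, numeric(1))
    pct_as_stack <- vapply(per_stack, function(x) {
      if (nrow(x$counted) > 0) 100 * mean(x$counted$type == "AS")
      else NA_real_
    }, numeric(1))
    cv_rows[[ly]] <- data.frame(
      layer = ly,
      cv_density = safe_cv(dens_all),
      cv_pct_as = safe_cv(pct_as_stack),
      cv_sas_as = safe_cv(sas_as_stack),
      stringsAsFactors = FALSE
    )

    spatial_rows[[ly]] <- data.frame(
      layer = ly,
      stack = vapply(per_stack, `[[`, character(1), "stack"),
      n = vapply(per_stack, function(x) nrow(x$pop), numeric(1)),
      verdict = vapply(per_stack, `[[`, character(1), "verdict"),
      stringsAsFactors = FALSE
    )

    fr <- config$composition_fractions[[ly]]
    if (length(fr) > 0) {
      cg <- config$composition_grid %||% list()
      grid <- generate_composition_grid(
        fr, nrow = cg$nrow %||% 200, ncol = cg$ncol %||% 200,
        cell_um = cg$cell_um %||% 0.5,
        seed = stage_seed(seed, paste0("grid_", ly)))
      counts <- count_hits(grid, n_placements = cg$n_placements %||% 10,
                           spacing_um = cg$spacing_um %||% 5,
                           extent_um = cg$extent_um %||% 50,
                           seed = stage_seed(seed, paste0("cavalieri_", ly)))
      vv <- volume_fraction(counts)
      vv_rows[[ly]] <- data.frame(layer = ly, element = names(vv),
                                  vv_percent = as.numeric(vv),
                                  stringsAsFactors = FALSE)
    }

    if (nrow(counted_all) > 0) {
      occ <- tabulate_spine_occupancy(counted_all)
      occ$layer <- ly
      occ_all[[ly]] <- occ
      for (tp in c("AS", "SS")) {
        v <- counted_all$sas_area_nm2[counted_all$type == tp]
        if (length(v) >= 3) {
          f <- fit_lognormal(v)
          fits[[paste(ly, tp, sep = "_")]] <- list(
            layer = ly, type = tp, mu = f$mu, sigma = f$sigma, n = f$n,
            mean_nm2 = f$mean_nm2, gof_statistic = f$gof_statistic)
        }
      }
    }
    pooled$pop[[ly]] <- counted_all
    pooled$nn[[ly]] <- nn_pool
    pooled$dens[[ly]] <- list(as = dens_as, ss = dens_ss, all = dens_all)
  }

  all_pop <- do.call(rbind, pooled$pop)
  if (is.null(all_pop)) all_pop <- empty_population()
  total_row <- layer_summary_row(
    "all", all_pop,
    unlist(lapply(pooled$dens, `[[`, "as")),
    unlist(lapply(pooled$dens, `[[`, "ss")),
    unlist(lapply(pooled$dens, `[[`, "all")),
    frame$effective_volume_um3 * n_stacks * length(config$profiles),
    unlist(pooled$nn), factors)

  structure(
    list(layer_table = rbind(do.call(rbind, layer_rows), total_row),
         cv_table = do.call(rbind, cv_rows),
         spatial_table = do.call(rbind, spatial_rows),
         vv_table = do.call(rbind, vv_rows),
         occupancy = do.call(rbind, occ_all),
         tests = layer_comparison_tests(pooled, all_pop),
         fits = fits, seed = seed, n_stacks = n_stacks),
    class = "analysis_report"
  )
}

# cross-layer comparisons in the tidy form
# (test, groups, unit, statistic, p, p_adjusted, significant)
layer_comparison_tests <- function(pooled, all_pop) {
  rows <- list()
  tidy_row <- function(test, groups, unit, statistic, p,
                       p_adjusted = NA_real_) {
    data.frame(test = test, groups = groups, unit = unit,
               statistic = statistic, p = p, p_adjusted = p_adjusted,
               significant = !is.na(p) &
                 (if (is.na(p_adjusted)) p else p_adjusted) <
                 significance_threshold(unit),
               stringsAsFactors = FALSE)
  }
  dens <- lapply(pooled$dens, `[[`, "all")
  dens <- dens[vapply(dens, length, integer(1)) > 0]
  if (length(dens) >= 2) {
    kw <- rank_tests(dens, unit = "stack")
    rows$dens <- tidy_row("kruskal_wallis", "density ~ layer", "stack",
                          kw$statistic, kw$p)
  }
  sas <- lapply(pooled$pop, function(p) p$sas_area_nm2[p$type == "AS"])
  sas <- sas[vapply(sas, length, integer(1)) > 1]
  if (length(sas) >= 2) {
    kw <- rank_tests(sas, unit = "synapse")
    rows$sas <- tidy_row("kruskal_wallis", "AS SAS area ~ layer", "synapse",
                         kw$statistic, kw$p)
  }
  counts <- t(vapply(pooled$pop, function(p) {
    c(AS = sum(p$type == "AS"), SS = sum(p$type == "SS"))
  }, numeric(2)))
  keep <- rowSums(counts) > 0
  if (sum(keep) >= 2) {
    cs <- chi_square_pairwise(counts[keep, , drop = FALSE],
                              unit = "synapse")
    rows$chisq <- do.call(rbind, lapply(seq_len(nrow(cs)), function(i) {
      tidy_row("chi_square", paste0("AS:SS ", cs$group1[i], " vs ",
                                    cs$group2[i]),
               "synapse", cs$statistic[i], cs$p[i], cs$p_adjusted[i])
    }))
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

safe_cv <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2 || mean(v) == 0) return(NA_real_)
  coefficient_of_variation(v)
}

# one Table-1-style row; measured values plus shrinkage-corrected twins
layer_summary_row <- function(layer, counted, dens_as, dens_ss, dens_all,
                              cf_volume_um3, nn_pool, factors) {
  n_as <- sum(counted$type == "AS")
  n_ss <- sum(counted$type == "SS")
  n_all <- n_as + n_ss
  sas_stats <- function(tp) {
    v <- counted$sas_area_nm2[counted$type == tp]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }
  sas_as <- sas_stats("AS")
  sas_ss <- sas_stats("SS")
  msd <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  d_as <- msd(dens_as); d_ss <- msd(dens_ss); d_all <- msd(dens_all)
  nn <- msd(nn_pool)
  data.frame(
    layer = layer, n_as = n_as, n_ss = n_ss, n_all = n_all,
    pct_as = if (n_all > 0) 100 * n_as / n_all else NA_real_,
    pct_ss = if (n_all > 0) 100 * n_ss / n_all else NA_real_,
    cf_volume_um3 = cf_volume_um3,
    density_as = d_as[1], density_as_sd = d_as[2],
    density_ss = d_ss[1], density_ss_sd = d_ss[2],
    density_all = d_all[1], density_all_sd = d_all[2],
    density_all_corrected = apply_shrinkage(d_all[1], "density", factors),
    sas_as_mean = sas_as[1], sas_as_se = sas_as[2],
    sas_as_mean_corrected = apply_shrinkage(sas_as[1], "area", factors),
    sas_ss_mean = sas_ss[1], sas_ss_se = sas_ss[2],
    sas_ss_mean_corrected = apply_shrinkage(sas_ss[1], "area", factors),
    nn_mean_nm = nn[1], nn_sd_nm = nn[2],
    nn_mean_corrected_nm = apply_shrinkage(nn[1], "linear", factors),
    stringsAsFactors = FALSE
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis report: %d layers x %d stacks (seed %s)\n",
              nrow(x$layer_table) - 1, x$n_stacks, x$seed))
  tot <- x$layer_table[x$layer_table$layer == "all", ]
  if (nrow(tot) == 1 && tot$n_all > 0) {
    cat(sprintf("  %d synapses, %.1f%% AS, density %.2f/um^3, mean NN %.0f nm\n",
                tot$n_all, tot$pct_as, tot$density_all, tot$nn_mean_nm))
  }
  invisible(x)
}

#' Format a report at the printed precision
#'
#' Rounds only for presentation (half-up): percentages to 1 decimal, SAS
#' areas to integer nm^2, densities to 2 decimals, distances to integer nm.
#' Intermediate report values stay at full precision.
#'
#' @param report an `analysis_report`.
#' @return data frame, formatted copy of `report$layer_table`.
#' @export
format_layer_table <- function(report) {
  t1 <- report$layer_table
  pct <- grep("^pct_", names(t1))
  dens <- grep("^density", names(t1))
  area <- grep("^sas_", names(t1))
  dist <- grep("^nn_", names(t1))
  t1[pct] <- lapply(t1[pct], round_half_up, 1)
  t1[dens] <- lapply(t1[dens], round_half_up, 2)
  t1[area] <- lapply(t1[area], round_half_up, 0)
  t1[dist] <- lapply(t1[dist], round_half_up, 0)
  t1$cf_volume_um3 <- round_half_up(t1$cf_volume_um3, 0)
  t1
}

#' Write report artifacts to a directory
#'
#' Emits `layer_table.tsv` (formatted per [format_layer_table()]), `cv.tsv`,
#' `spatial.tsv`, `vv.tsv`, `occupancy.tsv` and `fits.json`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wr(format_layer_table(report), "layer_table.tsv")
  wr(report$cv_table, "cv.tsv")
  wr(report$spatial_table, "spatial.tsv")
  wr(report$vv_table, "vv.tsv")
  wr(report$occupancy, "occupancy.tsv")
  wr(report$tests, "tests.tsv")
  jsonlite::write_json(report$fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
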