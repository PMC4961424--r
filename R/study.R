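# Orchestration of the full scaled-down in-silico study: synthetic
# geometries -> CV calibration -> AF induction -> DF windows -> virtual
# ablation trials -> statistics. Every stochastic element is keyed off the
# config seeds, so a (config, seed) pair determines every output.

#' Study configuration
#'
#' Desk-scale defaults run three ~2,650-node synthetic atria, three 2-s DF
#' windows and three ablation fractions in minutes on one CPU. The
#' `paper_scale` switch restores the full protocol (nine 6-s windows every
#' 30 s, 30-s ablation follow-up), which is orders of magnitude heavier.
#'
#' @param n_geometries number of synthetic "patients".
#' @param geometry_seeds seeds, one per geometry.
#' @param subdivisions,jitter forwarded to [synthetic_la_params()].
#' @param cv_target conduction-velocity calibration target (m/s).
#' @param beats_per_cl beats per pacing cycle length.
#' @param n_windows,window_length_ms,window_every_ms DF window schedule.
#' @param first_window_offset_ms gap between end of pacing and T1 (ms).
#' @param df_band DF search band (Hz).
#' @param fractions ablation area fractions.
#' @param follow_ms post-ablation observation (ms).
#' @param out_dir output directory (NULL: in-memory only).
#' @param seed global seed (probe selection etc.).
#' @param paper_scale if TRUE, use the full-study schedule.
#' @return a `study_config`.
#' @export
study_config <- function(n_geometries = 3,
                         geometry_seeds = c(1, 5, 13)[seq_len(n_geometries)],
                         subdivisions = 4, jitter = 1.0, cv_target = 0.4,
                         beats_per_cl = 8,
                         pacing_cycle_lengths = c(300, 285, 270),
                         n_windows = 3,
                         window_length_ms = 2000, window_every_ms = 4000,
                         first_window_offset_ms = 1000,
                         df_band = c(1, 20), fractions = c(0.10, 0.15, 0.20),
                         follow_ms = 4000, out_dir = NULL, seed = 1,
                         paper_scale = FALSE) {
  if (paper_scale) {
    n_windows <- 9; window_length_ms <- 6000; window_every_ms <- 30000
    follow_ms <- 30000; pacing_cycle_lengths <- c(200, 190, 180)
    warning("paper-scale study requested: expect a very long run",
            call. = FALSE)
  }
  structure(list(
    n_geometries = n_geometries, geometry_seeds = geometry_seeds,
    subdivisions = subdivisions, jitter = jitter, cv_target = cv_target,
    beats_per_cl = beats_per_cl,
    pacing_cycle_lengths = pacing_cycle_lengths, n_windows = n_windows,
    window_length_ms = window_length_ms, window_every_ms = window_every_ms,
    first_window_offset_ms = first_window_offset_ms, df_band = df_band,
    fractions = fractions, follow_ms = follow_ms, out_dir = out_dir,
    seed = seed), class = "study_config")
}

#' Save / load a study configuration (JSON)
#' @param config a `study_config`.
#' @param path JSON file path.
#' @export
save_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_study_config
#' @export
load_study_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$out_dir <- x$out_dir %||% NULL
  do.call(study_config, x[setdiff(names(x), character(0))])
}

#' Mean edge length of a mesh (mm)
#' @param mesh a `surface_mesh`.
#' @export
mean_edge_length <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  mean(sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2)))
}

# run one geometry end-to-end; returns list(region_table, trials, episode
# metadata); NULL on induction failure
.run_geometry <- function(config, gs) {
  params <- synthetic_la_params(subdivisions = config$subdivisions,
                                jitter = config$jitter, seed = gs)
  mesh <- partition_regions(make_synthetic_la(params))
  res <- round(mean_edge_length(mesh), 1)
  cal <- calibrate_diffusion(config$cv_target, res)
  op <- build_diffusion_operator(mesh, diffusion_field(cal$D))
  protocol <- straight_pacing(mesh, beats_per_cl = config$beats_per_cl,
                              cycle_lengths = config$pacing_cycle_lengths)
  t1 <- protocol$total_ms + config$first_window_offset_ms
  windows <- analysis_windows(config$n_windows, config$window_length_ms,
                              config$window_every_ms, t0 = t1)
  follow <- max(windows) - protocol$total_ms
  episode <- induce_af(op, remodeling_preset("af_remodeled"), protocol,
                       follow_ms = follow, windows = windows)
  out <- list(mesh = mesh, op = op, windows = windows, episode = episode,
              D = cal$D, resolution = res, seed = gs)
  if (!episode$induced || !is.na(episode$self_termination_ms)) {
    out$complete <- FALSE
    return(out)
  }
  nT <- nrow(windows)
  region_table <- matrix(NA_real_, nT, 10,
                         dimnames = list(rownames(windows), .region_names))
  df_maps <- vector("list", nT)
  trials <- list()
  for (k in seq_len(nT)) {
    dm <- compute_df_map(episode$recording, windows[k, ], config$df_band)
    df_maps[[k]] <- dm
    mask <- high_df_mask(dm, mesh$area, 0.10)
    region_table[k, ] <- regional_proportions(mask, mesh)
    for (fr in config$fractions) {
      tr <- run_ablation_trial(op, episode$checkpoints[[k]], dm, fr,
                               follow_ms = config$follow_ms,
                               seed = config$seed)
      trials[[length(trials) + 1]] <-
        data.frame(geometry_seed = gs, window = rownames(windows)[k],
                   fraction = fr, outcome = tr$outcome$label,
                   event_time_s = tr$outcome$event_time_s,
                   n_ablated = tr$n_ablated)
    }
  }
  out$complete <- TRUE
  out$region_table <- region_table
  out$df_maps <- df_maps
  out$trials <- do.call(rbind, trials)
  out
}

#' Run the full scaled-down study
#'
#' For each geometry seed: generate and partition the synthetic LA,
#' calibrate the diffusion coefficient to the CV target, induce AF by
#' straight pacing, map DF in each analysis window, ablate the high-DF
#' area at each fraction from the window-end checkpoint, and classify the
#' outcomes. Incomplete geometries (induction failure or early
#' self-termination) are flagged and skipped in the statistics.
#'
#' @param config a [study_config()].
#' @param keep_geometries if TRUE, keep full per-geometry objects (meshes,
#'   DF maps, episodes) in the report; otherwise only tables.
#' @return a `study_report`.
#' @export
run_study <- function(config = study_config(), keep_geometries = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  geoms <- vector("list", config$n_geometries)
  for (i in seq_len(config$n_geometries)) {
    gs <- config$geometry_seeds[i]
    cache_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("geometry_%03d.rds", gs)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      geoms[[i]] <- readRDS(cache_file)
      next
    }
    g <- .run_geometry(config, gs)
    g$mesh_summary <- list(nodes = nrow(g$mesh$vertices),
                           area_mm2 = sum(g$mesh$area))
    if (!is.null(out_dir)) {
      if (g$complete) {
        utils::write.csv(
          data.frame(window = rownames(g$region_table), g$region_table,
                     check.names = FALSE),
          file.path(out_dir, sprintf("highdf_regions_%03d.csv", gs)),
          row.names = FALSE)
        fields <- setNames(lapply(g$df_maps, function(d)
          ifelse(is.na(d$df), -1, d$df)),
          paste0("DF_Hz_", rownames(g$windows)))
        fields$highDF <- as.numeric(high_df_mask(
          g$df_maps[[length(g$df_maps)]], g$mesh$area, 0.10))
        write_mesh(g$mesh, file.path(out_dir, sprintf("dfmap_%03d.vtk", gs)),
                   fields = fields)
      }
      slim <- g[setdiff(names(g), c("mesh", "op", "episode", "df_maps"))]
      saveRDS(slim, cache_file)
    }
    geoms[[i]] <- if (keep_geometries) g else
      g[setdiff(names(g), c("mesh", "op", "episode", "df_maps"))]
  }
  complete <- vapply(geoms, function(g) isTRUE(g$complete), TRUE)
  trials <- do.call(rbind, lapply(geoms[complete], `[[`, "trials"))
  report <- list(config = config, geometries = geoms,
                 complete = complete, trials = trials)
  if (!is.null(trials) && nrow(trials)) {
    report$outcome_table <- tabulate_outcomes(split_trials(trials))
    report$chi_square <- tryCatch(chi_square_outcomes(report$outcome_table),
                                  error = function(e) NULL)
  }
  tabs <- lapply(geoms[complete], `[[`, "region_table")
  if (length(tabs)) {
    report$friedman <- lapply(tabs, friedman_consistency)
    report$friedman_p <- vapply(report$friedman, `[[`, 0, "p")
    report$consistent_fraction <- mean(report$friedman_p < 0.05)
    covs <- t(vapply(tabs, function(tb) apply(tb, 2, temporal_cov),
                     numeric(10)))
    colnames(covs) <- .region_names
    report$cov_matrix <- covs
    report$mean_cov <- mean(covs, na.rm = TRUE)
    cov_long <- data.frame(value = as.numeric(covs),
                           group = rep(.region_names, each = nrow(covs)))
    cov_long <- cov_long[!is.na(cov_long$value), ]
    report$kruskal <- tryCatch(kruskal_regions(cov_long),
                               error = function(e) NULL)
    report$group_ttest <- tryCatch(grouped_cov_ttest(covs),
                                   error = function(e) NULL)
  }
  report <- structure(report, class = "study_report")
  if (!is.null(out_dir)) {
    if (!is.null(trials))
      utils::write.csv(trials, file.path(out_dir, "ablation_trials.csv"),
                       row.names = FALSE)
    if (!is.null(report$outcome_table))
      utils::write.csv(report$outcome_table,
                       file.path(out_dir, "outcome_table.csv"),
                       row.names = FALSE)
    save_study_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}

# trials data frame -> list of pseudo-trials for tabulate_outcomes
split_trials <- function(trials) {
  lapply(seq_len(nrow(trials)), function(i)
    structure(list(fraction = trials$fraction[i],
                   outcome = list(label = trials$outcome[i],
                                  event_time_s = trials$event_time_s[i])),
              class = "ablation_trial"))
}

#' Plain-list summary of a study report (JSON-friendly)
#' @param report a `study_report`.
#' @export
report_summary <- function(report) {
  list(
    n_geometries = length(report$geometries),
    complete = report$complete,
    friedman_p = report$friedman_p,
    consistent_fraction = report$consistent_fraction,
    mean_temporal_cov = report$mean_cov,
    kruskal_p = report$kruskal$p,
    group_ttest = report$group_ttest,
    outcome_table = report$outcome_table,
    chi_square_p = report$chi_square$p)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(x$geometries), "geometries (",
      sum(x$complete), "complete )\n")
  if (!is.null(x$friedman_p))
    cat("  Friedman p:", paste(signif(x$friedman_p, 3), collapse = ", "),
        "| consistent fraction:", x$consistent_fraction, "\n")
  if (!is.null(x$mean_cov))
    cat("  mean temporal CoV:", round(x$mean_cov, 1), "%\n")
  if (!is.null(x$group_ttest))
    cat(sprintf("  group CoV: %.1f +/- %.1f%% vs %.1f +/- %.1f%% (p = %.3g)\n",
                x$group_ttest$mean_a, x$group_ttest$sd_a,
                x$group_ttest$mean_b, x$group_ttest$sd_b, x$group_ttest$p))
  if (!is.null(x$outcome_table)) {
    cat("  defrag-or-termination rates:",
        paste(sprintf("%s: %.1f%%", x$outcome_table$fraction,
                      x$outcome_table$defrag_or_term_rate), collapse = ", "),
        "\n")
  }
  invisible(x)
}
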