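#' Configuration of a full analysis run
#'
#' Bundles every tunable of the preprocessing, background, overlap,
#' tracking and variance-partitioning stages. Defaults follow the
#' conventional protocol: 100 locations/day, 1-km thinning, 100% MCP with
#' a 300-km buffer, 10 000 background points, 200 randomizations at
#' alpha = 0.05.
#'
#' @param n_per_day daily subsampling cap.
#' @param thin_cell_km spatial thinning cell, km.
#' @param buffer_km MCP buffer, km.
#' @param n_background background points per flyway.
#' @param grid_R_1d,grid_R_3d bins per axis for 1-D / 3-D niches.
#' @param n_perm randomizations per similarity test.
#' @param alpha significance level.
#' @param pairing season pairing (`"consecutive"` or `"all"`).
#' @param levels,modes,variable_sets strata analysed.
#' @param min_points minimum occurrences per unit-season.
#' @param mcmc an [mcmc_control()].
#' @param method similarity-test null mechanism.
#' @param seed global seed for the analysis stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_per_day = 100, thin_cell_km = 1, buffer_km = 300,
                       n_background = 10000, grid_R_1d = 100,
                       grid_R_3d = 50, n_perm = 200, alpha = 0.05,
                       pairing = c("consecutive", "all"),
                       levels = c("individual", "population"),
                       modes = c("climate", "weather"),
                       variable_sets = c("all", "temperature",
                                         "precipitation", "ndvi"),
                       min_points = 5, mcmc = mcmc_control(),
                       method = "resample", seed = 1L) {
  structure(list(n_per_day = n_per_day, thin_cell_km = thin_cell_km,
                 buffer_km = buffer_km, n_background = n_background,
                 grid_R_1d = grid_R_1d, grid_R_3d = grid_R_3d,
                 n_perm = n_perm, alpha = alpha,
                 pairing = match.arg(pairing),
                 levels = levels, modes = modes,
                 variable_sets = variable_sets,
                 min_points = min_points, mcmc = mcmc, method = method,
                 seed = as.integer(seed)),
            class = "run_config")
}

thin_by_unit <- function(points, by, cell_km, seed, origin) {
  points |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~ spatial_thin(.x, cell_km, seed = seed,
                                       origin = origin)) |>
    dplyr::ungroup()
}

#' Run the full seasonal niche analysis on simulated data
#'
#' Executes simulate -> preprocess -> background -> overlap -> tracking ->
#' variance partitioning for every combination of level, mode and variable
#' set in the run configuration, writing all intermediate tables, a
#' summary and a manifest to `dir`. Fully deterministic given the two
#' configurations.
#'
#' @param sim_cfg a [sim_config()] (simulation stage).
#' @param cfg a [run_config()] (analysis stages).
#' @param dir output directory (created if missing); NULL skips writing.
#' @return (invisibly) a list: `tracks`, `points` (preprocessed),
#'   `backgrounds`, `overlaps` (per-unit results), `tracking_rates`,
#'   `overlap_summary`, `welch`, `varcomp` (glance table), `dir`.
#' @export
run_niche_analysis <- function(sim_cfg, cfg = run_config(), dir = NULL) {
  env <- generate_environment(sim_cfg)
  tracks <- generate_tracks(sim_cfg, env)

  tracks_kept <- filter_full_year(tracks)
  if (nrow(tracks_kept) == 0) stop_cfg("no individual passed the full-year filter")
  sub <- subsample_daily(tracks_kept, cfg$n_per_day, seed = cfg$seed)
  seas <- assign_seasons(sub)

  backgrounds <- lapply(split(tracks_kept, tracks_kept$flyway), function(tf)
    build_background(tf, buffer_km = cfg$buffer_km, n = cfg$n_background,
                     seed = cfg$seed, flyway = as.character(tf$flyway[1]),
                     clip_rect = env_rect(env)))

  pts <- list(
    individual = thin_by_unit(seas, c("individual_id", "cycle_year", "season"),
                              cfg$thin_cell_km, cfg$seed, env$origin),
    population = thin_by_unit(seas, c("flyway", "cycle_year", "season"),
                              cfg$thin_cell_km, cfg$seed, env$origin))

  overlaps <- list()
  for (level in cfg$levels) for (mode in cfg$modes)
    for (vs in cfg$variable_sets) {
      R <- if (identical(vs, "all")) cfg$grid_R_3d else cfg$grid_R_1d
      overlaps[[paste(level, mode, vs, sep = "_")]] <- seasonal_overlaps(
        pts[[level]], env, backgrounds, level = level, mode = mode,
        variable_set = vs, pairing = cfg$pairing, R = R,
        n_perm = cfg$n_perm, alpha = cfg$alpha,
        min_points = cfg$min_points, method = cfg$method,
        seed = substream_seed(cfg$seed, "ovl", level, mode, vs))
    }
  overlaps <- dplyr::bind_rows(overlaps)

  overlap_summary <- overlaps |>
    dplyr::group_by(.data$level, .data$mode, .data$variable_set) |>
    dplyr::summarise(n = dplyr::n(), mean_D = mean(.data$D),
                     min_D = min(.data$D), max_D = max(.data$D),
                     .groups = "drop")
  tracking_rates <- if (cfg$n_perm > 0)
    tracking_proportion(overlaps, .data$level, .data$mode,
                        .data$variable_set)
    else tibble::tibble()

  # climate vs weather contrast on the 3-D overlap, per level
  welch <- overlaps |>
    dplyr::filter(.data$variable_set == "all") |>
    (\(d) purrr::map(intersect(cfg$levels, unique(d$level)), function(lv) {
      dd <- d[d$level == lv, ]
      if (length(unique(dd$mode)) < 2 ||
          min(table(dd$mode)) < 2 ||
          any(tapply(dd$D, dd$mode, sd) == 0)) return(NULL)
      cbind(tibble::tibble(level = lv),
            welch_t(dd$D[dd$mode == "climate"], dd$D[dd$mode == "weather"]))
    }))() |>
    dplyr::bind_rows()

  varcomp <- fit_varcomp_models(overlaps, cfg)

  out <- list(tracks = tracks, points = pts, backgrounds = backgrounds,
              overlaps = overlaps, overlap_summary = overlap_summary,
              tracking_rates = tracking_rates, welch = welch,
              varcomp = varcomp, env = env, dir = dir)
  if (!is.null(dir)) write_run(out, sim_cfg, cfg, dir)
  invisible(out)
}

# variance-partitioning models on the 3-D overlap/tracking results:
# Gaussian on standardized D and, where both classes occur, binary on the
# tracking flag; individual-level models take flyway as fixed effect
fit_varcomp_models <- function(overlaps, cfg) {
  rows <- list()
  d3 <- overlaps[overlaps$variable_set == "all", , drop = FALSE]
  for (lv in unique(d3$level)) for (md in unique(d3$mode)) {
    dd <- d3[d3$level == lv & d3$mode == md, , drop = FALSE]
    if (dplyr::n_distinct(dd$id) < 2 || nrow(dd) < 4 || sd(dd$D) == 0) next
    fw <- if (lv == "individual") dd$flyway else NULL
    fit_g <- tryCatch(suppressWarnings(fit_gaussian_varcomp(
      standardize(dd$D), dd$id, dd$cycle_year, fw, control = cfg$mcmc,
      seed = substream_seed(cfg$seed, "vc", lv, md, "g"))),
      error = function(e) NULL)
    if (!is.null(fit_g))
      rows[[length(rows) + 1]] <- cbind(
        tibble::tibble(level = lv, mode = md, response = "overlap"),
        glance(fit_g))
    if (!is.null(dd$tracking) && dplyr::n_distinct(dd$tracking) == 2) {
      fit_b <- tryCatch(suppressWarnings(fit_binary_varcomp(
        dd$tracking, dd$id, dd$cycle_year, fw, control = cfg$mcmc,
        seed = substream_seed(cfg$seed, "vc", lv, md, "b"))),
        error = function(e) NULL)
      if (!is.null(fit_b))
        rows[[length(rows) + 1]] <- cbind(
          tibble::tibble(level = lv, mode = md, response = "tracking"),
          glance(fit_b))
    }
  }
  dplyr::bind_rows(rows)
}

write_run <- function(out, sim_cfg, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracks(out$tracks, file.path(dir, "tracks.csv"))
  for (lv in names(out$points))
    readr::write_csv(
      dplyr::mutate(out$points[[lv]],
                    timestamp = format(.data$timestamp,
                                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
      file.path(dir, sprintf("seasonal_points_%s.csv", lv)))
  for (fl in names(out$backgrounds)) {
    write_polygon_wkt(out$backgrounds[[fl]]$polygon,
                      file.path(dir, sprintf("background_polygon_%s.wkt", fl)))
    readr::write_csv(out$backgrounds[[fl]]$points,
                     file.path(dir, sprintf("background_points_%s.csv", fl)))
  }
  readr::write_csv(out$overlaps, file.path(dir, "overlap_results.csv"))
  readr::write_csv(out$overlap_summary, file.path(dir, "overlap_summary.csv"))
  if (nrow(out$tracking_rates))
    readr::write_csv(out$tracking_rates, file.path(dir, "tracking_rates.csv"))
  if (nrow(out$welch)) readr::write_csv(out$welch, file.path(dir, "welch.csv"))
  if (nrow(out$varcomp))
    readr::write_csv(out$varcomp, file.path(dir, "varcomp_summary.csv"))
  manifest <- list(
    package = "nichetrack",
    version = as.character(utils::packageVersion("nichetrack")),
    sim_config = sim_cfg[setdiff(names(sim_cfg), c("variables", "targets"))],
    run_config = cfg[setdiff(names(cfg), "mcmc")],
    config_hash = rlang::hash(list(sim_cfg, cfg)),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Summarize a completed analysis run from its persisted tables
#'
#' Recomputes the stratum summaries (mean and range of D, tracking
#' proportions, climate-vs-weather Welch tests) from the CSVs written by
#' [run_niche_analysis()], so every reported number is reproducible from
#' the intermediates on disk.
#'
#' @param dir run directory.
#' @return list of tibbles: `overlap_summary`, `tracking_rates`, `welch`.
#' @export
summarize_run <- function(dir) {
  f <- file.path(dir, "overlap_results.csv")
  if (!file.exists(f)) stop_cfg("missing stage output: %s", f)
  overlaps <- readr::read_csv(f, show_col_types = FALSE)
  overlap_summary <- overlaps |>
    dplyr::group_by(.data$level, .data$mode, .data$variable_set) |>
    dplyr::summarise(n = dplyr::n(), mean_D = mean(.data$D),
                     min_D = min(.data$D), max_D = max(.data$D),
                     .groups = "drop")
  tracking_rates <- if ("tracking" %in% names(overlaps))
    tracking_proportion(overlaps, .data$level, .data$mode,
                        .data$variable_set)
    else tibble::tibble()
  welch <- overlaps |>
    dplyr::filter(.data$variable_set == "all") |>
    (\(d) purrr::map(unique(d$level), function(lv) {
      dd <- d[d$level == lv, ]
      if (length(unique(dd$mode)) < 2 || min(table(dd$mode)) < 2 ||
          any(tapply(dd$D, dd$mode, sd) == 0)) return(NULL)
      cbind(tibble::tibble(level = lv),
            welch_t(dd$D[dd$mode == "climate"], dd$D[dd$mode == "weather"]))
    }))() |>
    dplyr::bind_rows()
  list(overlap_summary = overlap_summary, tracking_rates = tracking_rates,
       welch = welch)
}
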