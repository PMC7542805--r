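#' Clip a convex polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of
#' `rect = c(xmin, xmax, ymin, ymax)`. Used to keep buffered availability
#' polygons inside the mapped environment extent.
#'
#' @param poly 2-column vertex matrix.
#' @param rect numeric length 4: `xmin, xmax, ymin, ymax`.
#' @return clipped vertex matrix.
#' @export
clip_polygon_rect <- function(poly, rect) {
  clip_halfplane <- function(p, inside, intersect) {
    n <- nrow(p); out <- list()
    for (k in seq_len(n)) {
      a <- p[k, ]; b <- p[if (k == n) 1 else k + 1, ]
      ain <- inside(a); bin <- inside(b)
      if (ain) out[[length(out) + 1]] <- a
      if (xor(ain, bin)) out[[length(out) + 1]] <- intersect(a, b)
    }
    if (length(out) == 0) return(matrix(numeric(0), 0, 2))
    do.call(rbind, out)
  }
  cuts <- list(
    list(\(p) p[1] >= rect[1],
         \(a, b) c(rect[1], a[2] + (b[2] - a[2]) * (rect[1] - a[1]) / (b[1] - a[1]))),
    list(\(p) p[1] <= rect[2],
         \(a, b) c(rect[2], a[2] + (b[2] - a[2]) * (rect[2] - a[1]) / (b[1] - a[1]))),
    list(\(p) p[2] >= rect[3],
         \(a, b) c(a[1] + (b[1] - a[1]) * (rect[3] - a[2]) / (b[2] - a[2]), rect[3])),
    list(\(p) p[2] <= rect[4],
         \(a, b) c(a[1] + (b[1] - a[1]) * (rect[4] - a[2]) / (b[2] - a[2]), rect[4])))
  for (cut in cuts) {
    poly <- clip_halfplane(poly, cut[[1]], cut[[2]])
    if (nrow(poly) < 3) stop_cfg("polygon does not intersect the rectangle")
  }
  colnames(poly) <- c("x_km", "y_km")
  poly
}

env_rect <- function(env) {
  c(env$origin[1], env$origin[1] + env$extent[1],
    env$origin[2], env$origin[2] + env$extent[2])
}

# a year-round weather annotation of points: each point gets one random
# date among all season days of the simulated range
yearround_annotation <- function(points, env, seed = 1L) {
  days <- env$dates[env$months %in% unlist(SEASON_MONTHS)]
  out <- tibble::tibble(point_id = seq_len(nrow(points)),
                        x_km = points$x_km, y_km = points$y_km)
  out$date <- with_substream(substream_seed(seed, "yearround"),
                             days[sample.int(length(days), nrow(points),
                                             replace = TRUE)])
  for (v in env$variables)
    out[[v]] <- env_value(env, v, out$x_km, out$y_km, date = out$date,
                          mode = "weather")
  out
}

#' Null calibration of the niche similarity test
#'
#' Estimates the empirical rejection (tracking) rate of
#' [similarity_test()] under its own null: both seasons' occurrence
#' environments are independent uniform draws from the background
#' annotation, so the nominal rate is `alpha`. A synthetic environment is
#' generated, `n_background` points are annotated with year-round weather
#' values, and each replicate draws two independent occurrence sets from
#' the annotation and tests them.
#'
#' @param n_rep number of replicate season pairs.
#' @param n_points occurrence environments per season.
#' @param n_background annotated background points.
#' @param R bins per axis of the 3-D grid.
#' @param n_perm randomizations per test.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param config simulator configuration for the environment.
#' @return tibble with one row per replicate: `rep`, `D_obs`, `q95_sim`,
#'   `tracking`; attribute `"rate"` gives the tracking proportion.
#' @export
calibration_experiment <- function(n_rep = 200, n_points = 150,
                                   n_background = 10000, R = 20,
                                   n_perm = 200, alpha = 0.05, seed = 1L,
                                   config = sim_config(years = 1, nx = 30,
                                                       ny = 30,
                                                       seed = seed)) {
  env <- generate_environment(config)
  rect <- env_rect(env)
  poly <- cbind(rect[c(1, 2, 2, 1)], rect[c(3, 3, 4, 4)])
  pts <- sample_background(poly, n_background,
                           seed = substream_seed(seed, "calbg"))
  ann <- yearround_annotation(pts, env, seed = substream_seed(seed, "calann"))
  nb <- niche_background(ann, env$variables, R)
  rows <- purrr::map(seq_len(n_rep), function(r) {
    idx <- with_substream(substream_seed(seed, "calocc", r), {
      list(a = sample.int(nb$n, n_points), b = sample.int(nb$n, n_points))
    })
    st <- similarity_test(nb$values[idx$a, , drop = FALSE],
                          nb$values[idx$b, , drop = FALSE],
                          nb, n_perm = n_perm, alpha = alpha,
                          seed = substream_seed(seed, "caltest", r))
    tibble::tibble(rep = r, D_obs = st$D_obs, q95_sim = st$q95,
                   tracking = st$tracking)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rate") <- mean(out$tracking)
  out
}

# simulate one individual, preprocess, and return thinned weather-annotated
# occurrence values for a season pair plus the flyway background
simulate_unit_pair <- function(config, env, seasons = c("summer", "autumn"),
                               n_background = 2000, buffer_km = 300,
                               thin_cell_km = 1, n_per_day = 100) {
  trk <- generate_tracks(config, env)
  trk <- subsample_daily(trk, n_per_day, seed = config$seed)
  seas <- assign_seasons(trk)
  seas <- seas[as.character(seas$season) %in% seasons, , drop = FALSE]
  seas <- seas |>
    dplyr::group_by(.data$individual_id, .data$season, .data$cycle_year) |>
    dplyr::group_modify(~ spatial_thin(.x, thin_cell_km,
                                       seed = config$seed,
                                       origin = env$origin)) |>
    dplyr::ungroup()
  poly <- clip_polygon_rect(buffer_polygon(compute_mcp(trk), buffer_km),
                            env_rect(env))
  bg <- structure(list(flyway = trk$flyway[1], mcp = compute_mcp(trk),
                       polygon = poly,
                       points = sample_background(
                         poly, n_background,
                         seed = substream_seed(config$seed, "powbg")),
                       buffer_km = buffer_km, n = n_background,
                       seed = config$seed),
                  class = "background_sample")
  list(points = seas, background = bg)
}

#' Consistent three-variable preference targets
#'
#' Given a temperature preference, returns the precipitation and NDVI
#' values that co-occur with it under the default co-structured fields
#' (all three variables are affine in one latent insolation structure),
#' so a multivariate tracker has an attainable joint target.
#'
#' @param temperature preferred temperature.
#' @param x_frac across-grid position fraction entering the
#'   precipitation x-gradient (flyway centre).
#' @param variables field parameters (defaults assumed).
#' @return named list of length-4 season target vectors per variable.
#' @export
tracking_targets <- function(temperature, x_frac = 0.5,
                             variables = default_env_variables()) {
  s <- temperature - variables$temperature$base
  list(temperature = rep(temperature, 4),
       precipitation = rep(variables$precipitation$base +
                             variables$precipitation$gx * x_frac - 2.5 * s,
                           4),
       ndvi = rep(variables$ndvi$base + 0.015 * s, 4))
}

# one full-niche tracking individual per flyway: all three variables
# weighted in the movement bias
power_config <- function(...) {
  defaults <- list(
    n_individuals = 1, years = 1, nx = 20, ny = 20,
    fix_interval_min = 120,
    targets = list(eastern = tracking_targets(12, 0.75),
                   western = tracking_targets(10, 0.25)),
    target_weights = c(temperature = 1, precipitation = 1, ndvi = 1))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Power of the similarity test against generator tracking strength
#'
#' For each bias strength `kappa`, simulates replicate individuals moving
#' over the same synthetic environment, preprocesses their tracks
#' (daily subsampling, season assignment, 1-km spatial thinning), and runs
#' the weather-mode similarity test on a season pair. The tracking rate
#' should be about `alpha` at `kappa = 0` and increase towards 1 for
#' strong bias.
#'
#' @param kappa_levels numeric vector of bias strengths.
#' @param n_rep replicates per level.
#' @param seasons season pair tested.
#' @param n_perm,alpha similarity-test settings.
#' @param R bins per axis (3-D grid).
#' @param max_points equal-effort rarefaction of each season's
#'   occurrences before testing.
#' @param seed integer seed.
#' @param config base simulator configuration (kappa and seed are
#'   overridden per replicate).
#' @return tibble: `kappa`, `rep`, `D_obs`, `q95_sim`, `tracking`;
#'   attribute `"rates"` has the per-level tracking proportions.
#' @export
power_experiment <- function(kappa_levels = c(0, 2, 20), n_rep = 20,
                             seasons = c("summer", "autumn"),
                             n_perm = 200, alpha = 0.05, R = 20,
                             max_points = 150, seed = 1L,
                             config = power_config()) {
  env_cfg <- config
  env_cfg$seed <- substream_seed(seed, "powenv")
  env <- generate_environment(env_cfg)
  rows <- list()
  for (kappa in kappa_levels) {
    for (r in seq_len(n_rep)) {
      cfg <- config
      cfg$kappa <- kappa
      cfg$seed <- substream_seed(seed, "pow", kappa, r)
      up <- simulate_unit_pair(cfg, env, seasons = seasons)
      occ <- annotate_occurrences(up$points, env, mode = "weather")
      occ_a <- occ[as.character(occ$season) == seasons[1], , drop = FALSE]
      occ_b <- occ[as.character(occ$season) == seasons[2], , drop = FALSE]
      rare <- function(o, lab) {
        if (nrow(o) <= max_points) return(o)
        keep <- with_substream(substream_seed(cfg$seed, "rarefy", lab),
                               sample.int(nrow(o), max_points))
        o[keep, , drop = FALSE]
      }
      occ_a <- rare(occ_a, "a"); occ_b <- rare(occ_b, "b")
      ann_a <- annotate_background(up$background, env, season = seasons[1],
                                   mode = "weather",
                                   seed = substream_seed(cfg$seed, "pa"))
      ann_b <- annotate_background(up$background, env, season = seasons[2],
                                   mode = "weather",
                                   seed = substream_seed(cfg$seed, "pb"))
      grid <- build_grid(dplyr::bind_rows(ann_a, ann_b), env$variables, R)
      nb_a <- niche_background(ann_a, env$variables, grid = grid)
      nb_b <- niche_background(ann_b, env$variables, grid = grid)
      st <- similarity_test(as_axis_matrix(occ_a, env$variables),
                            as_axis_matrix(occ_b, env$variables),
                            nb_a, nb_b, n_perm = n_perm, alpha = alpha,
                            seed = substream_seed(cfg$seed, "powtest"))
      rows[[length(rows) + 1]] <- tibble::tibble(
        kappa = kappa, rep = r, D_obs = st$D_obs, q95_sim = st$q95,
        tracking = st$tracking)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "rates") <- tracking_proportion(out, .data$kappa)
  out
}

#' Default configuration of the bottom-up scenario
#'
#' Individuals follow daily weather (strong bias, large spatially
#' correlated temperature anomalies) with climate preferences
#' heterogeneous across individuals but centred per flyway.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
scenario_config <- function(...) {
  vars <- default_env_variables()
  # strong, season-persistent temperature anomalies: each individual's
  # siting in a season is dominated by the anomaly patches it happens to
  # ride, so its realized climate niche is displaced between seasons while
  # its weather niche stays on target
  vars$temperature$noise_sd <- 4
  vars$temperature$ar <- 0.98
  defaults <- list(n_individuals = 12, years = 2, kappa = 8,
                   indiv_sd = c(temperature = 1.5), noise_corr_cells = 3,
                   nx = 24, ny = 24, fix_interval_min = 120,
                   variables = vars)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Bottom-up (H2) scenario experiment
#'
#' Simulates two populations whose individuals steer towards daily weather
#' conditions, with climate preferences heterogeneous across individuals
#' but centred per population, then measures niche-tracking proportions at
#' both ecological levels and both environmental scales. Under this
#' generative structure, individual-level weather tracking should be at
#' least as frequent as individual-level climate tracking, and
#' population-level climate tracking at least as frequent as
#' individual-level climate tracking (climatic niche tracking emerging at
#' the population level).
#'
#' @param config simulator configuration; the default gives each
#'   individual a temperature-preference offset (sd 2) around its flyway
#'   target, a strong weather-following bias, and strong daily temperature
#'   anomalies (noise sd 6) so that siting decisions are dominated by
#'   transient weather rather than by the underlying climate surface.
#' @param n_background background points per flyway.
#' @param n_perm,alpha,R similarity-test settings (3-D grid).
#' @param thin_cell_km,n_per_day,min_points preprocessing settings.
#' @param max_points equal-effort rarefaction per unit-season (see
#'   [seasonal_overlaps()]); keeps individual- and population-level tests
#'   at comparable sample size.
#' @param seed integer seed.
#' @return list: `results` (per-unit tracking table across levels and
#'   modes) and `rates` (tracking proportion per level and mode).
#' @export
scenario_experiment <- function(config = scenario_config(),
                                n_background = 3000, n_perm = 200,
                                alpha = 0.05, R = 20, thin_cell_km = 1,
                                n_per_day = 100, min_points = 20,
                                max_points = 250, seed = 1L) {
  config$seed <- substream_seed(seed, "scenario")
  env <- generate_environment(config)
  trk <- generate_tracks(config, env)
  trk <- subsample_daily(trk, n_per_day, seed = config$seed)
  seas <- assign_seasons(trk)

  backgrounds <- lapply(split(trk, trk$flyway), function(tf) {
    build_background(tf, buffer_km = 300, n = n_background,
                     seed = config$seed, flyway = tf$flyway[1],
                     clip_rect = env_rect(env))
  })

  thin_unit <- function(points, by) {
    points |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ spatial_thin(.x, thin_cell_km,
                                         seed = config$seed,
                                         origin = env$origin)) |>
      dplyr::ungroup()
  }
  pts_ind <- thin_unit(seas, c("individual_id", "cycle_year", "season"))
  pts_pop <- thin_unit(seas, c("flyway", "cycle_year", "season"))

  res <- list()
  for (mode in c("climate", "weather")) {
    res[[paste0("individual_", mode)]] <- seasonal_overlaps(
      pts_ind, env, backgrounds, level = "individual", mode = mode,
      R = R, n_perm = n_perm, alpha = alpha, min_points = min_points,
      max_points = max_points,
      seed = substream_seed(seed, "scn", "individual", mode))
    res[[paste0("population_", mode)]] <- seasonal_overlaps(
      pts_pop, env, backgrounds, level = "population", mode = mode,
      R = R, n_perm = n_perm, alpha = alpha, min_points = min_points,
      max_points = max_points,
      seed = substream_seed(seed, "scn", "population", mode))
  }
  results <- dplyr::bind_rows(res)
  rates <- tracking_proportion(results, .data$level, .data$mode)
  list(results = results, rates = rates)
}
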