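#' Pool a flyway's background annotation across the four seasons
#'
#' Availability is year-round: the background points are annotated once per
#' season (climate: season-mean layers; weather: season-specific random
#' dates) and the four tables are stacked into one annotation representing
#' all environmental conditions available to the flyway throughout the
#' year.
#'
#' @param background a [build_background()] object (or points tibble).
#' @param env environment set.
#' @param mode `"climate"` or `"weather"`.
#' @param seed integer seed (weather-mode dates).
#' @return tibble with one block of rows per season.
#' @export
pooled_background_annotation <- function(background, env,
                                         mode = c("climate", "weather"),
                                         seed = 1L) {
  mode <- match.arg(mode)
  purrr::map(SEASON_LEVELS, function(s)
    annotate_background(background, env, season = s, mode = mode,
                        seed = substream_seed(seed, "pool", s))) |>
    dplyr::bind_rows()
}

variable_set_axes <- function(variable_set, env) {
  if (identical(variable_set, "all")) return(env$variables)
  if (!variable_set %in% env$variables)
    stop_cfg("unknown variable set `%s`", variable_set)
  variable_set
}

# enumerate season pairs for the units (unit key columns + season,
# cycle_year) of one analysis id
season_pairs <- function(units, pairing) {
  key <- paste(units$season, units$cycle_year)
  have <- function(s, y) paste(s, y) %in% key
  pairs <- list()
  add <- function(s1, y1, s2, y2) {
    if (have(s1, y1) && have(s2, y2))
      pairs[[length(pairs) + 1]] <<- tibble::tibble(
        season_a = s1, year_a = y1, season_b = s2, year_b = y2)
  }
  years <- sort(unique(units$cycle_year))
  for (y in years) {
    add("spring", y, "summer", y)
    add("summer", y, "autumn", y)
    add("autumn", y, "winter", y)
    add("winter", y, "spring", y + 1)
    if (pairing == "all") {
      add("spring", y, "autumn", y)
      add("spring", y, "winter", y)
      add("summer", y, "winter", y)
    }
  }
  dplyr::bind_rows(pairs)
}

#' Seasonal niche overlap (and optional tracking tests) for all units
#'
#' The central driver: for every analysis unit (an individual-year at the
#' individual level, or a flyway-year with all its individuals pooled at
#' the population level) it annotates the occurrence points in the chosen
#' mode, builds background-corrected kernel-density niches per season on
#' the flyway's pooled background, and computes Schoener's D for every
#' season pair (default: the four consecutive pairs of the annual cycle).
#' With `n_perm > 0` each pair additionally gets a permutation similarity
#' test ([similarity_test()]) and a niche-tracking flag.
#'
#' Units with fewer than `min_points` occurrences in a season are skipped;
#' the skips are recorded in attribute `"skipped"`.
#'
#' @param points preprocessed seasonal points (columns `individual_id`,
#'   `flyway`, `cycle_year`, `season`, `x_km`, `y_km`, `timestamp`),
#'   typically subsampled, season-assigned and spatially thinned.
#' @param env environment set.
#' @param backgrounds named list of [build_background()] objects per
#'   flyway (or a single object used for all).
#' @param level `"individual"` or `"population"`.
#' @param mode `"climate"` or `"weather"`.
#' @param variable_set `"all"` (3-D niche) or one variable name (1-D).
#' @param pairing `"consecutive"` (four pairs around the annual cycle,
#'   with winter paired to the following spring) or `"all"` (additionally
#'   the three non-adjacent same-year pairs, i.e. all six unordered pairs
#'   of the cycle).
#' @param R bins per axis (default 100 in 1-D, 50 in 3-D).
#' @param n_perm randomizations per pair (0 = overlap only).
#' @param alpha significance level of the similarity test.
#' @param min_points minimum occurrences per unit-season.
#' @param max_points equal-effort rarefaction: unit-seasons with more
#'   occurrences are subsampled to this count (seeded) before density
#'   estimation, so units of very different sample size (individuals vs
#'   pooled populations) are tested at comparable sensitivity. Default
#'   `Inf` (no rarefaction).
#' @param seed integer seed.
#' @param method null mechanism of the similarity test.
#' @return tibble with one row per unit and season pair: `level`, `id`,
#'   `flyway`, `cycle_year`, `season_pair`, `mode`, `variable_set`, `D`,
#'   `n1`, `n2`, `grid_R`, and for `n_perm > 0` also `q95_sim`,
#'   `tracking`, `n_perm`, `alpha`.
#' @export
seasonal_overlaps <- function(points, env, backgrounds,
                              level = c("individual", "population"),
                              mode = c("climate", "weather"),
                              variable_set = "all",
                              pairing = c("consecutive", "all"),
                              R = NULL, n_perm = 0, alpha = 0.05,
                              min_points = 5, max_points = Inf, seed = 1L,
                              method = "resample") {
  level <- match.arg(level)
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  if (inherits(backgrounds, "background_sample")) {
    fl <- unique(as.character(points$flyway))
    backgrounds <- stats::setNames(rep(list(backgrounds), length(fl)), fl)
  }
  axes <- variable_set_axes(variable_set, env)
  ann <- annotate_occurrences(points, env, mode = mode)
  ann$id <- if (level == "individual") ann$individual_id
            else as.character(ann$flyway)

  results <- list(); skipped <- list()
  for (fl in intersect(names(backgrounds), unique(as.character(ann$flyway)))) {
    # one background point sample per flyway, annotated per season; the
    # four seasonal availabilities share one grid spanning their pooled
    # range, and each season's occupancy is corrected by its own season's
    # background density
    bg_ann <- lapply(stats::setNames(SEASON_LEVELS, SEASON_LEVELS),
                     function(s) annotate_background(
                       backgrounds[[fl]], env, season = s, mode = mode,
                       seed = substream_seed(seed, mode, fl, s)))
    grid <- build_grid(dplyr::bind_rows(bg_ann), axes, R)
    nb <- lapply(bg_ann, function(a) niche_background(a, axes, grid = grid))
    fl_ann <- ann[as.character(ann$flyway) == fl, , drop = FALSE]
    for (uid in unique(fl_ann$id)) {
      u <- fl_ann[fl_ann$id == uid, , drop = FALSE]
      units <- dplyr::distinct(u, .data$season, .data$cycle_year)
      prs <- season_pairs(units, pairing)
      if (nrow(prs) == 0) next
      occ_cache <- list()
      get_occ <- function(s, y) {
        k <- paste(s, y)
        if (!is.null(occ_cache[[k]])) return(occ_cache[[k]])
        vals <- as_axis_matrix(
          u[as.character(u$season) == s & u$cycle_year == y, , drop = FALSE],
          axes)
        if (nrow(vals) > max_points) {
          keep <- with_substream(
            substream_seed(seed, "rarefy", uid, s, y),
            sample.int(nrow(vals), max_points))
          vals <- vals[keep, , drop = FALSE]
        }
        z <- tryCatch(niche_occupancy(vals, nb[[s]], min_points = min_points),
                      nichetrack_insufficient_data = function(e) e,
                      nichetrack_empty_niche = function(e) e)
        occ_cache[[k]] <<- list(z = z, values = vals, season = s)
        occ_cache[[k]]
      }
      for (p in seq_len(nrow(prs))) {
        a <- get_occ(prs$season_a[p], prs$year_a[p])
        b <- get_occ(prs$season_b[p], prs$year_b[p])
        pair_lab <- paste(prs$season_a[p], prs$season_b[p], sep = "-")
        if (inherits(a$z, "error") || inherits(b$z, "error")) {
          skipped[[length(skipped) + 1]] <- tibble::tibble(
            level = level, id = uid, flyway = fl,
            cycle_year = prs$year_a[p], season_pair = pair_lab,
            mode = mode, variable_set = variable_set,
            reason = conditionMessage(if (inherits(a$z, "error")) a$z else b$z))
          next
        }
        row <- tibble::tibble(
          level = level, id = uid, flyway = fl,
          cycle_year = prs$year_a[p], season_pair = pair_lab,
          mode = mode, variable_set = variable_set,
          D = schoener_d(a$z, b$z),
          n1 = nrow(a$values), n2 = nrow(b$values),
          grid_R = grid$R)
        if (n_perm > 0) {
          st <- similarity_test(
            a$values, b$values, nb[[a$season]], nb[[b$season]],
            n_perm = n_perm, alpha = alpha,
            min_points = min_points, method = method,
            seed = substream_seed(seed, "unit", uid, prs$year_a[p], pair_lab,
                                  mode, variable_set))
          row$q95_sim <- st$q95
          row$tracking <- st$tracking
          row$n_perm <- n_perm
          row$alpha <- alpha
        }
        results[[length(results) + 1]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(results)
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
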