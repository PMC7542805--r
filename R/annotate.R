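#' Build the available-environment sample for one flyway
#'
#' Pools all of a flyway's GPS locations across individuals, years and
#' seasons, computes the 100% MCP, dilates it by `buffer_km` (default 300
#' km, the maximum home-range scale), and samples `n` uniform background
#' points inside the buffered polygon. One background sample per flyway is
#' reused for every season, representing all environmental conditions
#' available to the flyway throughout the year.
#'
#' @param points tibble of the flyway's locations (`x_km`, `y_km`;
#'   optionally `flyway`).
#' @param buffer_km buffer distance around the MCP, km.
#' @param n number of background points.
#' @param seed integer seed.
#' @param flyway optional flyway label stored on the object.
#' @param clip_rect optional `c(xmin, xmax, ymin, ymax)`; the buffered
#'   polygon is clipped to this rectangle (typically the mapped
#'   environment extent) before sampling.
#' @return an object of class `background_sample`: `flyway`, `mcp`,
#'   `polygon` (buffered), `points` tibble.
#' @export
build_background <- function(points, buffer_km = 300, n = 10000, seed = 1L,
                             flyway = NULL, clip_rect = NULL) {
  flyway <- flyway %||% (if ("flyway" %in% names(points))
    as.character(points$flyway[1]) else NA_character_)
  mcp <- compute_mcp(points)
  poly <- buffer_polygon(mcp, buffer_km)
  if (!is.null(clip_rect)) poly <- clip_polygon_rect(poly, clip_rect)
  pts <- sample_background(poly, n, seed = substream_seed(seed, "bg", flyway))
  structure(list(flyway = flyway, mcp = mcp, polygon = poly, points = pts,
                 buffer_km = buffer_km, n = n, seed = seed),
            class = "background_sample")
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("<background_sample> flyway %s: %d points in %.0f km2 polygon (MCP + %g km buffer)\n",
              x$flyway, nrow(x$points), abs(polygon_area(x$polygon)),
              x$buffer_km))
  invisible(x)
}

season_dates <- function(env, season) {
  env$dates[env$months %in% SEASON_MONTHS[[season]]]
}

#' Annotate background points with environmental values for one season
#'
#' Climate mode: each variable is the unweighted mean of the season's two
#' monthly long-term-mean layers at the point, a pure lookup (identical
#' across repeated calls). Weather mode: each point is assigned an
#' independent random date drawn uniformly from the season's days over the
#' simulated years, then annotated with that day's field.
#'
#' @param background a [build_background()] object or a tibble with
#'   `x_km`/`y_km` (and optionally `point_id`).
#' @param env an [generate_environment()] environment set.
#' @param season one of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @param mode `"climate"` or `"weather"`.
#' @param seed integer seed for the weather-mode random dates.
#' @return tibble: `point_id`, `x_km`, `y_km`, `season`, `mode`, `date`
#'   (NA in climate mode) and one column per environmental variable.
#' @export
annotate_background <- function(background, env,
                                season = SEASON_LEVELS,
                                mode = c("climate", "weather"),
                                seed = 1L) {
  season <- match.arg(season)
  mode <- match.arg(mode)
  pts <- if (inherits(background, "background_sample")) background$points
         else background
  if (!"point_id" %in% names(pts)) pts$point_id <- seq_len(nrow(pts))
  out <- tibble::tibble(point_id = pts$point_id, x_km = pts$x_km,
                        y_km = pts$y_km, season = season, mode = mode,
                        date = as.Date(NA))
  if (mode == "weather") {
    days <- season_dates(env, season)
    out$date <- with_substream(
      substream_seed(seed, "annotate", season),
      days[sample.int(length(days), nrow(pts), replace = TRUE)])
    for (v in env$variables)
      out[[v]] <- env_value(env, v, pts$x_km, pts$y_km, date = out$date,
                            mode = "weather")
  } else {
    for (v in env$variables)
      out[[v]] <- env_climate_season(env, v, pts$x_km, pts$y_km, season)
  }
  out
}

#' Annotate occurrence (GPS) points with environmental values
#'
#' Weather mode uses each fix's own date; climate mode uses the mean of the
#' fix's season's two monthly climate layers. Nearest-cell extraction, no
#' interpolation.
#'
#' @param points tibble with `x_km`, `y_km`, `timestamp` and (climate mode)
#'   `season`.
#' @param env environment set.
#' @param mode `"climate"` or `"weather"`.
#' @return the input with one column per environmental variable added.
#' @export
annotate_occurrences <- function(points, env, mode = c("climate", "weather")) {
  mode <- match.arg(mode)
  out <- points
  if (mode == "weather") {
    d <- as.Date(points$timestamp, tz = "UTC")
    for (v in env$variables)
      out[[v]] <- env_value(env, v, points$x_km, points$y_km, date = d,
                            mode = "weather")
  } else {
    if (!"season" %in% names(points))
      stop_cfg("climate-mode annotation needs a `season` column")
    out[env$variables] <- NA_real_
    for (s in unique(as.character(points$season))) {
      idx <- which(as.character(points$season) == s)
      for (v in env$variables)
        out[[v]][idx] <- env_climate_season(env, v, points$x_km[idx],
                                            points$y_km[idx], s)
    }
  }
  out
}
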