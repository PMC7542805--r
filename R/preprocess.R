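#' Randomly subsample GPS fixes to a daily cap
#'
#' For every individual and calendar day with more than `n_per_day` fixes,
#' keeps exactly `n_per_day` fixes drawn uniformly without replacement; days
#' at or below the cap are untouched. Temporal order is preserved. Used to
#' limit over-representation of stationary behaviour (e.g. nesting) before
#' niche estimation; the conventional cap is 100 locations per day.
#'
#' @param tracks tibble with `individual_id` and `timestamp` columns.
#' @param n_per_day maximum fixes retained per individual-day (>= 1).
#' @param seed integer; the draw is deterministic given the seed and is
#'   independent of row order (per individual-day substreams).
#' @return the subsampled tibble, original row order preserved.
#' @export
subsample_daily <- function(tracks, n_per_day = 100, seed = 1L) {
  if (n_per_day < 1) stop_cfg("`n_per_day` must be >= 1")
  if (nrow(tracks) == 0) return(tracks)
  day <- as.character(as.Date(tracks$timestamp, tz = "UTC"))
  key <- paste(tracks$individual_id, day, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(tracks)), key), function(idx) {
    if (length(idx) <= n_per_day) return(idx)
    with_substream(substream_seed(seed, "subsample", key[idx[1]]),
                   sort(sample(idx, n_per_day)))
  }), use.names = FALSE)
  tracks[sort(keep), , drop = FALSE]
}

#' Assign two-month seasons to GPS fixes
#'
#' Seasons are two-month blocks separated by one-month gaps: spring
#' (March-April), summer (June-July), autumn (September-October) and winter
#' (December-January). Fixes in the gap months (February, May, August,
#' November) are discarded. Winter is December-anchored: its `cycle_year` is
#' the year of the December, so a December fix and the following January fix
#' belong to the same winter unit.
#'
#' @param tracks tibble with a POSIXct/Date `timestamp` column.
#' @return the input rows that fall in a season, with `season` (factor
#'   spring/summer/autumn/winter) and `cycle_year` columns added.
#' @export
#' @examples
#' tr <- tibble::tibble(individual_id = "a", flyway = "eastern",
#'   timestamp = as.POSIXct(c("2014-07-15 12:00", "2014-05-10 12:00",
#'                            "2014-12-31 23:00", "2015-01-01 01:00"),
#'                          tz = "UTC"), x_km = 0, y_km = 0)
#' assign_seasons(tr)
assign_seasons <- function(tracks) {
  dt <- as.Date(tracks$timestamp, tz = "UTC")
  month <- as.integer(format(dt, "%m"))
  year <- as.integer(format(dt, "%Y"))
  season <- rep(NA_character_, length(month))
  for (s in names(SEASON_MONTHS)) season[month %in% SEASON_MONTHS[[s]]] <- s
  cycle_year <- year
  cycle_year[!is.na(season) & season == "winter" & month == 1L] <-
    year[!is.na(season) & season == "winter" & month == 1L] - 1L
  out <- tracks[!is.na(season), , drop = FALSE]
  out$season <- factor(season[!is.na(season)], levels = SEASON_LEVELS)
  out$cycle_year <- cycle_year[!is.na(season)]
  out
}

#' Keep only individuals tracked for at least one full year
#'
#' Retains individuals whose tracking span is at least 365 days and who have
#' at least one fix in each of the four seasons; all others are dropped. The
#' dropped individuals and the reason are attached as attribute
#' `"dropped"` and reported with a message.
#'
#' @param tracks tibble with `individual_id` and `timestamp`.
#' @return the filtered tibble.
#' @export
filter_full_year <- function(tracks) {
  if (nrow(tracks) == 0) return(tracks)
  seas <- assign_seasons(tracks)
  info <- tracks |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      span = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                 units = "days")),
      .groups = "drop") |>
    dplyr::left_join(
      seas |>
        dplyr::group_by(.data$individual_id) |>
        dplyr::summarise(n_seasons = dplyr::n_distinct(.data$season),
                         .groups = "drop"),
      by = "individual_id")
  info$n_seasons[is.na(info$n_seasons)] <- 0L
  dropped <- info |>
    dplyr::filter(.data$span < 365 | .data$n_seasons < 4) |>
    dplyr::mutate(reason = dplyr::if_else(.data$span < 365,
                                          "tracked < 365 days",
                                          "missing a season")) |>
    dplyr::select("individual_id", "reason")
  if (nrow(dropped) > 0)
    message(sprintf("filter_full_year: dropped %d individual(s): %s",
                    nrow(dropped),
                    paste(dropped$individual_id, collapse = ", ")))
  out <- tracks[!(tracks$individual_id %in% dropped$individual_id), ,
                drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Spatially thin points to one per grid cell
#'
#' Overlays a square grid of `cell_km` anchored at `origin` and keeps one
#' uniformly chosen point per occupied cell, removing duplicate
#' environmental sampling of the same 1-km pixel. The grid anchor is fixed
#' (not data-dependent) so the result is stable under point reordering, and
#' the draw is deterministic given the seed.
#'
#' @param points tibble with `x_km` and `y_km` columns (one analysis unit).
#' @param cell_km thinning cell size, km (> 0).
#' @param seed integer seed.
#' @param origin numeric length 2 grid anchor, km.
#' @return the surviving rows, one per occupied cell, original order.
#' @export
spatial_thin <- function(points, cell_km = 1, seed = 1L, origin = c(0, 0)) {
  assert_positive(cell_km, "cell_km")
  if (nrow(points) == 0) return(points)
  ci <- floor((points$x_km - origin[1]) / cell_km)
  cj <- floor((points$y_km - origin[2]) / cell_km)
  cell <- paste(ci, cj, sep = ",")
  keep <- with_substream(substream_seed(seed, "thin"),
    vapply(split(seq_len(nrow(points)), cell), function(idx)
      if (length(idx) == 1L) idx else sample(idx, 1L), integer(1)))
  points[sort(unname(keep)), , drop = FALSE]
}

#' Read a Movebank-style track CSV
#'
#' @param path CSV file with one row per fix.
#' @param col_map named character vector mapping the canonical columns
#'   (`individual_id`, `timestamp`, `x_km`, `y_km`, `flyway`) to the file's
#'   column names.
#' @return a track tibble with POSIXct UTC timestamps, ordered by
#'   individual and time.
#' @export
read_tracks <- function(path,
                        col_map = c(individual_id = "individual_id",
                                    timestamp = "timestamp",
                                    x_km = "x_km", y_km = "y_km",
                                    flyway = "flyway")) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(unname(col_map), names(raw))
  if (length(missing))
    stop_cfg("track file lacks column(s): %s", paste(missing, collapse = ", "))
  out <- tibble::tibble(
    individual_id = as.character(raw[[col_map[["individual_id"]]]]),
    flyway = as.character(raw[[col_map[["flyway"]]]]),
    timestamp = as.POSIXct(raw[[col_map[["timestamp"]]]], tz = "UTC"),
    x_km = as.numeric(raw[[col_map[["x_km"]]]]),
    y_km = as.numeric(raw[[col_map[["y_km"]]]]))
  dplyr::arrange(out, .data$individual_id, .data$timestamp)
}

#' Write tracks as Movebank-style CSV
#'
#' @param tracks track tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}
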