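#' Configuration for the synthetic movement-and-environment simulator
#'
#' Builds the single configuration object consumed by
#' [generate_environment()] and [generate_tracks()]. The simulator emulates
#' the data situation of a two-flyway migratory bird study: gridded daily
#' "weather" fields (temperature, precipitation, NDVI) whose long-term
#' monthly means define the "climate" layers, and multi-year GPS tracks of
#' individuals that may or may not steer towards preferred environmental
#' conditions.
#'
#' Movement is a biased correlated random walk. At every fix the heading is
#' a weighted sum of the previous heading (weight `persistence`), the
#' direction of steepest approach to the individual's seasonal preferred
#' environmental value (weight `kappa`), and isotropic noise. `kappa = 0`
#' gives an environment-blind walk confined to the grid extent.
#'
#' @param n_individuals individuals per flyway.
#' @param years number of simulated calendar years (>= 1).
#' @param start_year first simulated calendar year.
#' @param fix_interval_min minutes between GPS fixes.
#' @param kappa bias weight towards the preferred environment (>= 0,
#'   dimensionless; 0 = environment-blind).
#' @param step_km Rayleigh scale of per-fix step lengths, km.
#' @param persistence weight of the previous heading in the new heading.
#' @param dir_noise standard deviation of the isotropic heading noise.
#' @param nx,ny grid cells in x and y.
#' @param cell_km cell size, km (planar coordinates; no projection).
#' @param origin numeric length 2, lower-left corner of the grid, km.
#' @param variables list of per-variable field parameters; see
#'   [default_env_variables()].
#' @param noise_corr_cells Gaussian correlation length of the daily noise
#'   fields, in cells.
#' @param targets named list (`eastern`, `western`) of named lists
#'   (variable -> length-4 numeric, seasons spring/summer/autumn/winter)
#'   giving preferred environmental values. Defaults to a
#'   constant-temperature preference that differs between flyways.
#' @param target_weights named numeric, weight of each variable in the
#'   movement suitability score.
#' @param indiv_sd named numeric, per-variable standard deviation of
#'   individual preference offsets around the flyway target (0 = all
#'   individuals share the flyway target).
#' @param target_field `"weather"` (individuals respond to daily fields)
#'   or `"climate"` (monthly long-term means).
#' @param seed global integer seed; all randomness flows from it through
#'   named substreams (see [substream_seed()]).
#' @return a list with class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 2, years = 1, fix_interval_min = 240)
#' cfg$kappa
sim_config <- function(n_individuals = 5,
                       years = 2,
                       start_year = 2013,
                       fix_interval_min = 60,
                       kappa = 4,
                       step_km = 15,
                       persistence = 0.5,
                       dir_noise = 1,
                       nx = 40, ny = 40, cell_km = 25,
                       origin = c(0, 0),
                       variables = default_env_variables(),
                       noise_corr_cells = 5,
                       targets = NULL,
                       target_weights = c(temperature = 1),
                       indiv_sd = c(temperature = 0),
                       target_field = c("weather", "climate"),
                       seed = 1L) {
  if (kappa < 0) stop_cfg("`kappa` must be >= 0")
  if (years < 1) stop_cfg("`years` must be >= 1")
  assert_positive(nx, "nx"); assert_positive(ny, "ny")
  assert_positive(cell_km, "cell_km")
  assert_positive(fix_interval_min, "fix_interval_min")
  target_field <- match.arg(target_field)
  if (is.null(targets)) {
    targets <- list(
      eastern = list(temperature = rep(12, 4)),
      western = list(temperature = rep(10, 4))
    )
  }
  targets <- lapply(targets, function(fl) {
    lapply(fl, function(v) {
      v <- rep_len(as.numeric(v), 4L)
      names(v) <- SEASON_LEVELS
      v
    })
  })
  structure(list(
    n_individuals = as.integer(n_individuals),
    years = as.integer(years),
    start_year = as.integer(start_year),
    fix_interval_min = fix_interval_min,
    kappa = kappa, step_km = step_km,
    persistence = persistence, dir_noise = dir_noise,
    nx = as.integer(nx), ny = as.integer(ny), cell_km = cell_km,
    origin = as.numeric(origin),
    variables = variables,
    noise_corr_cells = noise_corr_cells,
    targets = targets,
    target_weights = target_weights,
    indiv_sd = indiv_sd,
    target_field = target_field,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default synthetic environmental field parameters
#'
#' Three variables on a shared grid. Each field is
#' `base + gx * x/extent + gy * y/extent + (amp0 + amp_y * y/extent) *
#' cos(2 pi (month - peak_month)/12) + noise`, clamped to `clamp`.
#' The deterministic parts of all three variables are affine functions of
#' one latent "insolation" structure (a latitudinal gradient whose
#' seasonal cycle is amplified in the north), emulating how temperature,
#' precipitation and vegetation greenness co-vary along real flyways: a
#' constant temperature preference then forces north-in-summer /
#' south-in-winter migration and simultaneously keeps the other two
#' variables near matched values, up to their independent daily noise.
#' Daily noise fields carry AR(1) temporal persistence (`ar`), emulating
#' weather systems that last days to weeks.
#'
#' @return named list of per-variable parameter lists.
#' @export
default_env_variables <- function() {
  list(
    temperature = list(base = 16, gx = 0, gy = -16, amp0 = 3, amp_y = 5,
                       peak_month = 7, noise_sd = 3, ar = 0.7,
                       clamp = c(-Inf, Inf)),
    precipitation = list(base = 60, gx = 10, gy = 40, amp0 = 7.5,
                         amp_y = 12.5, peak_month = 1, noise_sd = 15,
                         ar = 0.5, clamp = c(0, Inf)),
    ndvi = list(base = 0.55, gx = 0, gy = -0.24, amp0 = 0.045,
                amp_y = 0.075, peak_month = 7, noise_sd = 0.06, ar = 0.9,
                clamp = c(-0.2, 0.95))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals/flyway, %d year(s) from %d, fixes every %g min\n",
              x$n_individuals, x$years, x$start_year, x$fix_interval_min))
  cat(sprintf("  grid %d x %d cells of %g km; kappa = %g (%s field); seed %d\n",
              x$nx, x$ny, x$cell_km, x$kappa, x$target_field, x$seed))
  invisible(x)
}
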