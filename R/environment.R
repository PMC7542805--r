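SEASON_LEVELS <- c("spring", "summer", "autumn", "winter")

# months (two each) defining the seasons; intervening months are gaps
SEASON_MONTHS <- list(spring = c(3L, 4L), summer = c(6L, 7L),
                      autumn = c(9L, 10L), winter = c(12L, 1L))

#' Generate a synthetic environment set
#'
#' Builds daily "weather" grids for temperature, precipitation and NDVI as a
#' smooth spatial gradient plus a monthly seasonal cycle plus spatially
#' correlated daily noise, and derives the "climate" layers as the
#' across-year monthly means of the weather stack. By construction every
#' climate layer equals the temporal mean of its month's weather layers, and
#' with zero noise every weather day equals its month's climate layer.
#'
#' @param config a [sim_config()].
#' @return an object of class `env_set`: per-variable weather arrays
#'   (`nx x ny x n_days`), climate arrays (`nx x ny x 12`), grid geometry
#'   and the daily date index.
#' @export
#' @examples
#' env <- generate_environment(sim_config(years = 1, nx = 10, ny = 10))
#' env
generate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nx <- config$nx; ny <- config$ny
  dates <- seq(as.Date(sprintf("%d-01-01", config$start_year)),
               as.Date(sprintf("%d-12-31", config$start_year + config$years - 1)),
               by = "day")
  months <- as.integer(format(dates, "%m"))
  n_days <- length(dates)
  ext_x <- nx * config$cell_km; ext_y <- ny * config$cell_km
  # cell-midpoint coordinate fractions of the extent
  fx <- (seq_len(nx) - 0.5) / nx
  fy <- (seq_len(ny) - 0.5) / ny
  FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)

  kern_fft <- noise_kernel_fft(nx, ny, config$noise_corr_cells)

  weather <- vector("list", length(config$variables))
  names(weather) <- names(config$variables)
  for (v in names(config$variables)) {
    p <- config$variables[[v]]
    det <- array(0, c(nx, ny, 12))
    for (m in 1:12) {
      seas <- cos(2 * pi * (m - p$peak_month) / 12)
      det[, , m] <- p$base + p$gx * FX + p$gy * FY +
        (p$amp0 + p$amp_y * FY) * seas
    }
    w <- array(0, c(nx, ny, n_days))
    if (p$noise_sd > 0) {
      # spatially correlated daily anomalies with AR(1) temporal
      # persistence (unit marginal variance by stationary initialization)
      rho <- p$ar %||% 0
      noise <- with_substream(
        substream_seed(config$seed, "environment", v), {
          out <- array(0, c(nx, ny, n_days))
          prev <- smooth_field(matrix(rnorm(nx * ny), nx, ny), kern_fft)
          out[, , 1] <- prev
          innov_sd <- sqrt(1 - rho^2)
          for (d in seq_len(n_days)[-1]) {
            prev <- rho * prev +
              innov_sd * smooth_field(matrix(rnorm(nx * ny), nx, ny),
                                      kern_fft)
            out[, , d] <- prev
          }
          out
        })
      for (d in seq_len(n_days))
        w[, , d] <- det[, , months[d]] + p$noise_sd * noise[, , d]
    } else {
      for (d in seq_len(n_days)) w[, , d] <- det[, , months[d]]
    }
    w[w < p$clamp[1]] <- p$clamp[1]
    w[w > p$clamp[2]] <- p$clamp[2]
    weather[[v]] <- w
  }

  climate <- lapply(weather, function(w) {
    cl <- array(0, c(nx, ny, 12))
    for (m in 1:12) {
      idx <- which(months == m)
      cl[, , m] <- apply(w[, , idx, drop = FALSE], c(1, 2), mean)
    }
    cl
  })

  structure(list(
    variables = names(config$variables),
    weather = weather, climate = climate,
    origin = config$origin, cell_km = config$cell_km,
    nx = nx, ny = ny, extent = c(ext_x, ext_y),
    dates = dates, months = months,
    years = config$years, start_year = config$start_year,
    seed = config$seed, config = config
  ), class = "env_set")
}

# FFT of a periodic (torus) Gaussian smoothing kernel with unit l2 norm,
# so smoothing preserves the unit variance of white noise.
noise_kernel_fft <- function(nx, ny, corr_cells) {
  if (corr_cells <= 0) {
    k <- matrix(0, nx, ny); k[1, 1] <- 1
    return(fft(k))
  }
  dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
  dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  k <- exp(-0.5 * (outer(dx^2, dy^2, `+`)) / corr_cells^2)
  k <- k / sqrt(sum(k^2))
  fft(k)
}

smooth_field <- function(z, kern_fft) {
  Re(fft(fft(z) * kern_fft, inverse = TRUE)) / length(z)
}

#' @export
print.env_set <- function(x, ...) {
  cat("<env_set>\n")
  cat(sprintf("  variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  grid %d x %d cells of %g km (extent %g x %g km)\n",
              x$nx, x$ny, x$cell_km, x$extent[1], x$extent[2]))
  cat(sprintf("  weather: %d daily layers (%s .. %s); climate: 12 monthly layers\n",
              length(x$dates), min(x$dates), max(x$dates)))
  invisible(x)
}

# nearest-cell (no interpolation) grid indices; error if outside extent
cell_index <- function(env, x, y) {
  i <- floor((x - env$origin[1]) / env$cell_km) + 1L
  j <- floor((y - env$origin[2]) / env$cell_km) + 1L
  # points exactly on the upper boundary belong to the last cell
  i[x == env$origin[1] + env$extent[1]] <- env$nx
  j[y == env$origin[2] + env$extent[2]] <- env$ny
  bad <- which(i < 1L | i > env$nx | j < 1L | j > env$ny)
  if (length(bad))
    stop_cfg("point outside environment extent: (%g, %g)", x[bad[1]], y[bad[1]])
  list(i = i, j = j)
}

# value of one variable at planar points for given dates (weather) or
# months (climate); vectorized pure lookup
env_value <- function(env, variable, x, y, date = NULL, month = NULL,
                      mode = c("weather", "climate")) {
  mode <- match.arg(mode)
  ij <- cell_index(env, x, y)
  if (mode == "weather") {
    d <- match(as.Date(date), env$dates)
    if (anyNA(d)) stop_cfg("date outside the simulated range")
    arr <- env$weather[[variable]]
    arr[cbind(ij$i, ij$j, d)]
  } else {
    arr <- env$climate[[variable]]
    arr[cbind(ij$i, ij$j, as.integer(month))]
  }
}

# season-mean climate value (unweighted mean of the two monthly layers)
env_climate_season <- function(env, variable, x, y, season) {
  m <- SEASON_MONTHS[[season]]
  (env_value(env, variable, x, y, month = m[1], mode = "climate") +
     env_value(env, variable, x, y, month = m[2], mode = "climate")) / 2
}

#' Write environmental layers as ESRI ASCII grids
#'
#' Persists climate (12 monthly layers per variable) and optionally
#' weather (one layer per day) as plain-text ESRI ASCII grid files
#' (`<variable>_<label>.asc`) plus a JSON manifest recording the grid
#' geometry, simulated period and seed.
#'
#' @param env an `env_set`.
#' @param dir output directory (created if missing).
#' @param what `"climate"` or `"weather"`.
#' @param dates for `what = "weather"`, the dates to write (default: all).
#' @return the manifest path, invisibly.
#' @export
write_env_layers <- function(env, dir, what = c("climate", "weather"),
                             dates = NULL) {
  what <- match.arg(what)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asc <- function(mat, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("ncols %d", nrow(mat)),
                 sprintf("nrows %d", ncol(mat)),
                 sprintf("xllcorner %g", env$origin[1]),
                 sprintf("yllcorner %g", env$origin[2]),
                 sprintf("cellsize %g", env$cell_km),
                 "NODATA_value -9999"), con)
    # ASCII grids store rows north-to-south
    for (j in rev(seq_len(ncol(mat))))
      writeLines(paste(signif(mat[, j], 8), collapse = " "), con)
  }
  for (v in env$variables) {
    if (what == "climate") {
      for (m in 1:12)
        write_asc(env$climate[[v]][, , m],
                  file.path(dir, sprintf("%s_climate_%02d.asc", v, m)))
    } else {
      dts <- as.Date(dates %||% env$dates)
      idx <- match(dts, env$dates)
      if (anyNA(idx)) stop_cfg("date outside the simulated range")
      for (k in seq_along(idx))
        write_asc(env$weather[[v]][, , idx[k]],
                  file.path(dir, sprintf("%s_weather_%s.asc", v, dts[k])))
    }
  }
  manifest <- file.path(dir, "env_manifest.json")
  jsonlite::write_json(list(
    variables = env$variables, nx = env$nx, ny = env$ny,
    cell_km = env$cell_km, origin = env$origin,
    start_year = env$start_year, years = env$years, seed = env$seed,
    layers = what), manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
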