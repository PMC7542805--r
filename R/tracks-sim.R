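#' Simulate individual movement tracks over a synthetic environment
#'
#' Each individual performs a biased correlated random walk: the heading at
#' every fix is a weighted combination of the previous heading
#' (`persistence`), the direction of steepest approach to the individual's
#' seasonal preferred environmental value (`kappa`), and isotropic noise;
#' step lengths are Rayleigh with scale `step_km`. `kappa = 0` gives an
#' environment-blind walk. Walks are reflected at the grid boundary, so
#' positions never leave the extent. Individuals are split evenly between an
#' eastern and a western flyway with distinct home regions and preferred
#' environmental targets; per-individual preference offsets with standard
#' deviation `indiv_sd` induce between-individual niche heterogeneity.
#'
#' Every individual runs on its own random substream derived from the global
#' seed by a stable hash of its id, so tracks are reproducible independently
#' of generation order.
#'
#' @param config a [sim_config()].
#' @param env the matching [generate_environment()] output.
#' @return a tibble with columns `individual_id`, `flyway`, `timestamp`
#'   (POSIXct UTC), `x_km`, `y_km`, ordered by individual and time.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 1, years = 1, nx = 10, ny = 10,
#'                   fix_interval_min = 720)
#' env <- generate_environment(cfg)
#' trk <- generate_tracks(cfg, env)
#' dplyr::count(trk, individual_id)
generate_tracks <- function(config, env) {
  stopifnot(inherits(config, "sim_config"), inherits(env, "env_set"))
  if (config$kappa < 0) stop_cfg("`kappa` must be >= 0")
  ids <- c(sprintf("E%02d", seq_len(config$n_individuals)),
           sprintf("W%02d", seq_len(config$n_individuals)))
  flyways <- rep(c("eastern", "western"), each = config$n_individuals)
  out <- purrr::map2(ids, flyways, function(id, fl)
    simulate_one_track(id, fl, config, env))
  dplyr::bind_rows(out)
}

# preferred value per calendar month for one variable: season months carry
# the season target, gap months the mean of the two adjacent seasons
monthly_targets <- function(target4) {
  m <- numeric(12)
  for (s in SEASON_LEVELS) m[SEASON_MONTHS[[s]]] <- target4[[s]]
  m[2] <- (target4[["winter"]] + target4[["spring"]]) / 2
  m[5] <- (target4[["spring"]] + target4[["summer"]]) / 2
  m[8] <- (target4[["summer"]] + target4[["autumn"]]) / 2
  m[11] <- (target4[["autumn"]] + target4[["winter"]]) / 2
  m
}

simulate_one_track <- function(id, flyway, config, env) {
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$start_year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:59:59",
                           config$start_year + config$years - 1), tz = "UTC")
  times <- seq(t0, t1, by = config$fix_interval_min * 60)
  day_idx <- as.integer(as.Date(times, tz = "UTC") - env$dates[1]) + 1L
  month_idx <- env$months[day_idx]
  n <- length(times)

  vars <- names(config$target_weights)[config$target_weights > 0]
  weights <- config$target_weights[vars]
  scales <- vapply(vars, function(v) {
    s <- config$variables[[v]]$noise_sd
    if (s <= 0) s <- max(abs(config$variables[[v]]$amp0), 1)
    s
  }, numeric(1))

  ext <- env$extent; o <- env$origin
  xr <- if (flyway == "western") c(0.05, 0.45) else c(0.55, 0.95)

  with_substream(substream_seed(config$seed, "track", id), {
    # individual preference offsets around the flyway target
    tgt <- lapply(vars, function(v) {
      base <- config$targets[[flyway]][[v]]
      off <- if (!is.na(config$indiv_sd[v]) && config$indiv_sd[v] > 0)
        rnorm(1, 0, config$indiv_sd[v]) else 0
      monthly_targets(as.list(base + off))
    })
    names(tgt) <- vars

    pos <- c(o[1] + runif(1, xr[1], xr[2]) * ext[1],
             o[2] + runif(1, 0.75, 0.90) * ext[2])
    h <- c(rnorm(1), rnorm(1)); h <- h / sqrt(sum(h^2))
    steps <- matrix(rweibull(2 * n, shape = 2, scale = config$step_km), n, 2)
    step_len <- steps[, 1]
    noise <- matrix(rnorm(2 * n, sd = config$dir_noise), n, 2)

    xs <- numeric(n); ys <- numeric(n)
    use_weather <- config$target_field == "weather"
    for (k in seq_len(n)) {
      xs[k] <- pos[1]; ys[k] <- pos[2]
      g <- c(0, 0)
      if (config$kappa > 0) {
        g <- suitability_gradient(env, pos, day_idx[k], month_idx[k],
                                  vars, weights, scales, tgt, use_weather)
      }
      d <- config$persistence * h + config$kappa * g + noise[k, ]
      nd <- sqrt(sum(d^2))
      if (nd > 1e-12) h <- d / nd
      pos <- reflect_into(pos + step_len[k] * h, o, ext)
    }
    tibble::tibble(individual_id = id, flyway = flyway,
                   timestamp = times, x_km = xs, y_km = ys)
  })
}

# unit direction of steepest increase of the (negative squared mismatch)
# suitability, by central differences over neighbouring grid cells
suitability_gradient <- function(env, pos, day, month, vars, weights, scales,
                                 tgt, use_weather) {
  i <- floor((pos[1] - env$origin[1]) / env$cell_km) + 1L
  j <- floor((pos[2] - env$origin[2]) / env$cell_km) + 1L
  i <- min(max(i, 1L), env$nx); j <- min(max(j, 1L), env$ny)
  im <- max(i - 1L, 1L); ip <- min(i + 1L, env$nx)
  jm <- max(j - 1L, 1L); jp <- min(j + 1L, env$ny)
  sx <- 0; sy <- 0
  for (v in seq_along(vars)) {
    arr <- if (use_weather) env$weather[[vars[v]]] else env$climate[[vars[v]]]
    t3 <- if (use_weather) day else month
    T0 <- tgt[[v]][month]
    mis <- function(ii, jj) -((arr[ii, jj, t3] - T0) / scales[v])^2
    sx <- sx + weights[v] * (mis(ip, j) - mis(im, j)) / ((ip - im) * env$cell_km)
    sy <- sy + weights[v] * (mis(i, jp) - mis(i, jm)) / ((jp - jm) * env$cell_km)
  }
  nrm <- sqrt(sx^2 + sy^2)
  if (nrm < 1e-12) c(0, 0) else c(sx, sy) / nrm
}

# reflect a proposed position back inside [origin, origin + extent]
reflect_into <- function(p, origin, extent) {
  for (k in 1:2) {
    lo <- origin[k]; hi <- origin[k] + extent[k]
    span <- 2 * (hi - lo)
    z <- (p[k] - lo) %% span
    p[k] <- lo + ifelse(z > (hi - lo), span - z, z)
  }
  p
}
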