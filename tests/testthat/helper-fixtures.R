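# small shared fixtures; everything is generated in code at test time

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_individuals = 1, years = 1, nx = 12, ny = 12,
         fix_interval_min = 720, seed = 42), list(...))
  do.call(sim_config, args)
}

tiny_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_environment(tiny_config())
    cache
  }
})

# deterministic toy seasonal points tibble
toy_points <- function(n = 40, season = "summer", year = 2013,
                       id = "E01", flyway = "eastern", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    individual_id = id, flyway = flyway,
    timestamp = as.POSIXct(sprintf("%d-07-01 12:00:00", year), tz = "UTC") +
      seq_len(n) * 3600,
    x_km = runif(n, 10, 290), y_km = runif(n, 10, 290),
    season = factor(season, levels = c("spring", "summer", "autumn",
                                       "winter")),
    cycle_year = year))
}

# brute-force, double-loop product-Gaussian KDE at cell midpoints
# (independent oracle for kernel_density)
naive_kde <- function(values, grid, bw = NULL) {
  values <- as.matrix(values)
  d <- ncol(values)
  mids <- grid$mids
  h <- numeric(d)
  for (k in seq_len(d)) {
    v <- values[, k]
    e <- grid$edges[[k]]
    values[, k] <- pmin(pmax(v, e[1]), e[length(e)])
    h[k] <- if (!is.null(bw)) bw[k] else stats::bw.nrd0(values[, k])
    h[k] <- max(h[k], diff(e[1:2]) / 2, na.rm = TRUE)
  }
  dims <- rep(grid$R, d)
  z <- array(0, dims)
  idx <- as.matrix(expand.grid(lapply(dims, seq_len)))
  for (r in seq_len(nrow(idx))) {
    tot <- 0
    for (i in seq_len(nrow(values))) {
      k <- 1
      for (a in seq_len(d))
        k <- k * exp(-0.5 * ((mids[[a]][idx[r, a]] - values[i, a]) / h[a])^2)
      tot <- tot + k
    }
    z[matrix(idx[r, ], 1)] <- tot
  }
  z / sum(z)
}

# naive occupancy + Schoener D chain (oracle for the full pipeline piece);
# mirrors the default availability floor of 1% of the uniform cell mass
naive_occupancy <- function(z_occ, z_bkg) {
  z <- array(0, dim(z_occ) %||% length(z_occ))
  for (i in seq_along(z_occ))
    if (z_bkg[i] > 0.01 / length(z_bkg)) z[i] <- z_occ[i] / z_bkg[i]
  z / sum(z)
}

naive_schoener <- function(z1, z2) {
  tot <- 0
  for (i in seq_along(z1)) tot <- tot + abs(z1[i] - z2[i])
  1 - tot / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
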