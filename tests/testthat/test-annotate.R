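test_that("climate annotation is a pure lookup and season-mean of layers", {
  env <- tiny_env()
  bg <- tibble::tibble(point_id = 1:20,
                       x_km = seq(5, 295, length.out = 20),
                       y_km = seq(295, 5, length.out = 20))
  a1 <- annotate_background(bg, env, season = "summer", mode = "climate")
  a2 <- annotate_background(bg, env, season = "summer", mode = "climate")
  expect_identical(a1, a2)
  expect_true(all(is.na(a1$date)))
  # season value = unweighted mean of the two monthly climate layers
  ij <- nichetrack:::cell_index(env, bg$x_km[3], bg$y_km[3])
  expect_equal(a1$temperature[3],
               (env$climate$temperature[ij$i, ij$j, 6] +
                  env$climate$temperature[ij$i, ij$j, 7]) / 2)
  # permuting point order permutes rows identically
  perm <- c(5:1, 6:20)
  a3 <- annotate_background(bg[perm, ], env, season = "summer",
                            mode = "climate")
  expect_equal(a3$temperature, a1$temperature[perm])
})

test_that("weather annotation uses uniform random season dates", {
  env <- generate_environment(tiny_config(years = 2))
  bg <- tibble::tibble(point_id = 1, x_km = 150, y_km = 150)
  bg10k <- bg[rep(1, 10000), ]
  a <- annotate_background(bg10k, env, season = "spring", mode = "weather",
                           seed = 3)
  mo <- as.integer(format(a$date, "%m"))
  expect_true(all(mo %in% c(3, 4)))
  # uniform over 61 days x 2 years
  tab <- table(factor(as.character(a$date),
                      levels = as.character(season_dates(env, "spring"))))
  expect_length(tab, 122)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  # deterministic given seed
  b <- annotate_background(bg10k, env, season = "spring", mode = "weather",
                           seed = 3)
  expect_identical(a$date, b$date)
})

test_that("zero-noise environment makes weather equal climate annotation", {
  vars <- default_env_variables()
  for (v in names(vars)) vars[[v]]$noise_sd <- 0
  env <- generate_environment(tiny_config(variables = vars))
  bg <- tibble::tibble(point_id = 1:30,
                       x_km = runif(30, 0, 299), y_km = runif(30, 0, 299))
  aw <- annotate_background(bg, env, season = "autumn", mode = "weather",
                            seed = 1)
  ac <- annotate_background(bg, env, season = "autumn", mode = "climate")
  # weather value equals its month's (constant) layer; the climate season
  # value averages the two months, so compare within each month's rows
  for (v in env$variables) {
    mo <- as.integer(format(aw$date, "%m"))
    for (m in unique(mo)) {
      idx <- which(mo == m)
      ref <- env_value(env, v, bg$x_km[idx], bg$y_km[idx],
                       month = m, mode = "climate")
      expect_equal(aw[[v]][idx], ref, tolerance = 1e-12)
    }
  }
  # and the season climate annotation is the mean over the two months
  a1 <- env_value(env, "ndvi", bg$x_km, bg$y_km, month = 9,
                  mode = "climate")
  a2 <- env_value(env, "ndvi", bg$x_km, bg$y_km, month = 10,
                  mode = "climate")
  expect_equal(ac$ndvi, (a1 + a2) / 2)
})

test_that("occurrence annotation respects mode and errors outside extent", {
  env <- tiny_env()
  pts <- tibble::tibble(
    individual_id = "E01", flyway = "eastern",
    timestamp = as.POSIXct("2013-06-15 06:00", tz = "UTC") + (0:9) * 86400,
    x_km = seq(10, 100, 10), y_km = seq(10, 100, 10),
    season = factor("summer", levels = SEASON_LEVELS),
    cycle_year = 2013)
  aw <- annotate_occurrences(pts, env, mode = "weather")
  d <- as.Date(pts$timestamp[1])
  expect_equal(aw$temperature[1],
               env_value(env, "temperature", 10, 10, date = d,
                         mode = "weather"))
  ac <- annotate_occurrences(pts, env, mode = "climate")
  expect_equal(ac$temperature[2],
               nichetrack:::env_climate_season(env, "temperature", 20, 20,
                                               "summer"))
  bad <- pts; bad$x_km[1] <- 1e5
  expect_error(annotate_occurrences(bad, env, mode = "weather"), "outside")
})

test_that("flyway backgrounds contain their occurrence points", {
  cfg <- tiny_config(n_individuals = 2, fix_interval_min = 360)
  env <- tiny_env()
  trk <- generate_tracks(cfg, env)
  east <- trk[trk$flyway == "eastern", ]
  bg <- build_background(east, buffer_km = 50, n = 500, seed = 1,
                         clip_rect = nichetrack:::env_rect(env))
  expect_true(all(points_in_polygon(bg$polygon, east)))
  expect_equal(nrow(bg$points), 500)
  expect_true(all(points_in_polygon(bg$polygon, bg$points)))
})
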