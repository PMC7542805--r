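test_that("a full day at 5-min fixes yields 288 fixes and stays in extent", {
  cfg <- tiny_config(fix_interval_min = 5)
  env <- tiny_env()
  trk <- generate_tracks(cfg, env)
  one_day <- trk[trk$individual_id == "E01" &
                   as.Date(trk$timestamp, tz = "UTC") == as.Date("2013-03-10"), ]
  expect_equal(nrow(one_day), 288)
  expect_true(all(trk$x_km >= 0 & trk$x_km <= env$extent[1]))
  expect_true(all(trk$y_km >= 0 & trk$y_km <= env$extent[2]))
})

test_that("track generation is deterministic and id-keyed", {
  cfg <- tiny_config(n_individuals = 2, fix_interval_min = 360)
  env <- tiny_env()
  t1 <- generate_tracks(cfg, env)
  t2 <- generate_tracks(cfg, env)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$individual_id), c("E01", "E02", "W01", "W02"))
  expect_identical(unique(t1$flyway[t1$individual_id == "W01"]), "western")
})

test_that("kappa = 0 walks are rejected only for negative kappa", {
  expect_error(sim_config(kappa = -0.1))
  cfg <- tiny_config(kappa = 0, fix_interval_min = 720)
  expect_silent(trk <- generate_tracks(cfg, tiny_env()))
  expect_gt(nrow(trk), 300)
})

test_that("daily subsampling caps busy days, leaves quiet days, is stable", {
  cfg <- tiny_config(fix_interval_min = 5)  # 288/day
  trk <- generate_tracks(cfg, tiny_env())
  sub <- subsample_daily(trk, 100, seed = 9)
  days <- table(sub$individual_id, as.Date(sub$timestamp, tz = "UTC"))
  expect_true(all(days == 100))
  expect_true(all(tapply(sub$timestamp, sub$individual_id,
                         function(x) !is.unsorted(x))))
  # quiet days untouched
  quiet <- trk[1:50, ]
  expect_identical(subsample_daily(quiet, 100, seed = 9), quiet)
  # deterministic given seed, different under another seed
  expect_identical(subsample_daily(trk, 100, seed = 9), sub)
  expect_false(identical(subsample_daily(trk, 100, seed = 10), sub))
  # 3 days x 200 fixes -> 300 retained
  three <- trk[trk$individual_id == "E01" &
                 as.Date(trk$timestamp, tz = "UTC") %in%
                 as.Date(c("2013-06-01", "2013-06-02", "2013-06-03")), ]
  three <- three[sort(withr::with_seed(1, sample(nrow(three), 600))), ]
  expect_equal(nrow(subsample_daily(three, 100, seed = 1)), 300)
  expect_equal(nrow(subsample_daily(tibble::tibble(
    individual_id = character(), timestamp = as.POSIXct(character())),
    100)), 0)
})

test_that("season assignment follows the two-month blocks with gaps", {
  ts <- as.POSIXct(c("2014-07-15 12:00", "2014-05-10 12:00",
                     "2014-12-31 23:00", "2015-01-01 01:00",
                     "2014-03-01 00:00", "2014-10-31 23:59",
                     "2014-02-15 12:00", "2014-08-01 12:00",
                     "2014-11-30 12:00"), tz = "UTC")
  tr <- tibble::tibble(individual_id = "a", flyway = "eastern",
                       timestamp = ts, x_km = 0, y_km = 0)
  out <- assign_seasons(tr)
  # gap months discarded: May, Feb, Aug, Nov
  expect_equal(nrow(out), 5)
  got <- setNames(as.character(out$season), format(out$timestamp, "%m-%d"))
  expect_equal(unname(got[c("07-15", "03-01", "10-31")]),
               c("summer", "spring", "autumn"))
  # December and following January share the December-anchored winter
  win <- out[out$season == "winter", ]
  expect_equal(nrow(win), 2)
  expect_equal(unique(win$cycle_year), 2014)
  expect_equal(out$cycle_year[format(out$timestamp, "%m-%d") == "07-15"],
               2014)
  # partition: every fix is in exactly one season or discarded
  expect_equal(nrow(out) + 4, nrow(tr))
})

test_that("full-year filter keeps only individuals with a complete cycle", {
  mk <- function(id, from, to, by = "5 days") {
    ts <- seq(as.POSIXct(from, tz = "UTC"), as.POSIXct(to, tz = "UTC"),
              by = by)
    tibble::tibble(individual_id = id, flyway = "eastern", timestamp = ts,
                   x_km = 0, y_km = 0)
  }
  full <- mk("full", "2013-01-01", "2014-02-05")      # 400 days, all seasons
  short <- mk("short", "2013-01-01", "2013-07-20")    # 200 days
  nowinter <- mk("nowinter", "2013-02-01", "2014-02-06")
  nowinter <- nowinter[!format(nowinter$timestamp, "%m") %in%
                         c("12", "01"), ]             # >370 days, no winter
  tracks <- dplyr::bind_rows(full, short, nowinter)
  expect_message(kept <- filter_full_year(tracks), "dropped")
  expect_setequal(unique(kept$individual_id), "full")
  expect_setequal(attr(kept, "dropped")$individual_id,
                  c("short", "nowinter"))
  expect_equal(nrow(filter_full_year(full[0, ])), 0)
})

test_that("spatial thinning keeps one survivor per occupied cell", {
  pts <- tibble::tibble(x_km = c(0.2, 0.5, 0.9, 3.1, 7.7),
                        y_km = c(0.1, 0.8, 0.3, 2.2, 7.1))
  th <- spatial_thin(pts, 1, seed = 5)
  expect_equal(nrow(th), 3)  # cells (0,0), (3,2), (7,7)
  # all-distinct cells: unchanged
  apart <- tibble::tibble(x_km = c(0.5, 5.5, 9.5), y_km = c(0.5, 5.5, 9.5))
  expect_identical(spatial_thin(apart, 1, seed = 1), apart)
  # survivor count equals an independent cell census, uniform points
  many <- withr::with_seed(3, tibble::tibble(x_km = runif(1000, 0, 10),
                                             y_km = runif(1000, 0, 10)))
  th2 <- spatial_thin(many, 1, seed = 2)
  census <- length(unique(paste(floor(many$x_km), floor(many$y_km))))
  expect_equal(nrow(th2), census)
  # idempotent on its own output
  expect_identical(spatial_thin(th2, 1, seed = 7), th2)
  expect_identical(spatial_thin(many, 1, seed = 2), th2)
})

test_that("track CSV round-trips through the Movebank-style format", {
  cfg <- tiny_config(fix_interval_min = 720)
  trk <- generate_tracks(cfg, tiny_env())
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(trk, f)
  back <- read_tracks(f)
  expect_equal(back$x_km, trk$x_km, tolerance = 1e-6)
  expect_identical(back$timestamp, trk$timestamp)
  expect_identical(back$individual_id, trk$individual_id)
  expect_error(read_tracks(f, col_map = c(individual_id = "nope",
                                          timestamp = "timestamp",
                                          x_km = "x_km", y_km = "y_km",
                                          flyway = "flyway")),
               "lacks")
})
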