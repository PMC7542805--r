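sim_varcomp_data <- function(n_unit = 40, n_obs = 10, V_B = 2, V_W = 1,
                             beta_fw = 0, seed = 1) {
  withr::with_seed(seed, {
    unit <- rep(seq_len(n_unit), each = n_obs)
    year <- rep(rep(1:5, length.out = n_obs), n_unit)
    flyway <- rep(rep(c("eastern", "western"), each = n_unit / 2),
                  each = n_obs)
    b <- rnorm(n_unit, 0, sqrt(V_B))
    y <- b[unit] + beta_fw * (flyway == "western") +
      rnorm(n_unit * n_obs, 0, sqrt(V_W))
    list(y = y, unit = unit, year = year, flyway = flyway)
  })
}

test_that("standardize gives exact z-scores and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- withr::with_seed(1, rnorm(50, 5, 3))
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("Welch t matches the hand-computed example and stats::t.test", {
  w <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -1.549193, tolerance = 1e-6)
  expect_equal(w$df, 50 / 17, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(w$p, ref$p.value, tolerance = 1e-9)
  # same sample: t = 0, p = 1; antisymmetry
  x <- c(1, 3, 5, 7)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  y <- c(2, 3, 9)
  expect_equal(welch_t(x, y)$t, -welch_t(y, x)$t)
  expect_equal(welch_t(x, y)$p, welch_t(y, x)$p)
  # equal variances and n: df reduces to pooled n1 + n2 - 2
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  expect_equal(welch_t(a, b)$df, 6)
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("repeatability summaries follow the variance ratio", {
  expect_equal(repeatability(rep(1, 10), rep(1, 10))$mean, 0.5)
  expect_equal(repeatability(rep(3, 10), rep(1, 10))$mean, 0.75)
  r <- repeatability(rep(1e-8, 10), rep(1, 10))
  expect_lt(r$mean, 1e-6)
  expect_error(repeatability(c(1, -1), c(1, 1)))
})

test_that("Gaussian sampler recovers variance components against REML", {
  skip_if_not_installed("lme4")
  ctrl <- mcmc_control(iterations = 8000, burnin = 1000, thin = 5)
  rel_err <- function(a, b) abs(a - b) / b
  errs <- sapply(1:3, function(s) {
    d <- sim_varcomp_data(seed = s)
    fit <- suppressWarnings(
      fit_gaussian_varcomp(d$y, d$unit, d$year, d$flyway, ctrl, seed = s))
    td <- tidy(fit)
    m <- lme4::lmer(y ~ flyway + (1 | unit) + (1 | year),
                    data = data.frame(d), REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(m))
    c(rel_err(td$mean[td$parameter == "V_B"],
              vc$vcov[vc$grp == "unit"]),
      rel_err(td$mean[td$parameter == "V_W"],
              vc$vcov[vc$grp == "Residual"]))
  })
  expect_lt(mean(errs[1, ]), 0.15)
  expect_lt(mean(errs[2, ]), 0.15)
})

test_that("Gaussian sampler: null and fixed-effect recovery", {
  ctrl <- mcmc_control(iterations = 8000, burnin = 1000, thin = 5)
  # V_B = 0: repeatability posterior collapses towards 0
  d0 <- sim_varcomp_data(V_B = 0, seed = 4)
  f0 <- fit_gaussian_varcomp(d0$y, d0$unit, d0$year, NULL, ctrl, seed = 2)
  expect_lt(glance(f0)$repeatability, 0.15)
  # flyway effect of +1 residual sd: credible interval excludes 0
  d1 <- sim_varcomp_data(beta_fw = 1, seed = 5)
  f1 <- fit_gaussian_varcomp(d1$y, d1$unit, d1$year, d1$flyway, ctrl,
                             seed = 3)
  td <- tidy(f1)
  fw <- td[td$parameter == "flyway_western", ]
  expect_gt(fw$q2.5, 0)
  expect_true(fw$significant)
  # determinism given seed
  f1b <- fit_gaussian_varcomp(d1$y, d1$unit, d1$year, d1$flyway, ctrl,
                              seed = 3)
  expect_identical(f1$draws, f1b$draws)
})

test_that("binary sampler recovers latent repeatability and is label-symmetric", {
  ctrl <- mcmc_control(iterations = 8000, burnin = 1000, thin = 5)
  withr::local_seed(6)
  unit <- rep(1:40, each = 10)
  year <- rep(rep(1:5, 2), 40)
  b <- rnorm(40, 0, 1)  # latent V_B = 1 -> R = 0.5
  y <- rbinom(400, 1, pnorm(b[unit]))
  fit <- fit_binary_varcomp(y, unit, year, NULL, ctrl, seed = 9)
  g <- glance(fit)
  expect_gt(g$repeatability, 0.3)
  expect_lt(g$repeatability, 0.7)
  # iid response: R near 0
  y0 <- withr::with_seed(8, rbinom(400, 1, 0.5))
  f0 <- fit_binary_varcomp(y0, unit, year, NULL, ctrl, seed = 10)
  expect_lt(glance(f0)$repeatability, 0.15)
  # flipping labels leaves variance posteriors essentially unchanged
  ff <- fit_binary_varcomp(1 - y, unit, year, NULL, ctrl, seed = 9)
  expect_equal(glance(ff)$repeatability, g$repeatability, tolerance = 0.1)
  expect_error(fit_binary_varcomp(rep(1, 20), rep(1:4, 5), rep(1, 20)),
               "both classes")
})

test_that("mcmc diagnostics flag autocorrelated and degenerate chains", {
  withr::local_seed(11)
  good <- matrix(rnorm(4500 * 2), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  dg <- mcmc_diagnostics(good)
  expect_true(attr(dg, "pass"))
  ar <- as.numeric(arima.sim(list(ar = 0.5), 2000))
  bad <- cbind(a = ar, b = rnorm(2000))
  expect_false(attr(mcmc_diagnostics(bad), "pass"))
  expect_false(attr(mcmc_diagnostics(cbind(a = rep(1, 500))), "pass"))
})

test_that("tidy/glance expose draws summaries and mixing flag", {
  d <- sim_varcomp_data(n_unit = 10, n_obs = 4, seed = 12)
  ctrl <- mcmc_control(iterations = 2000, burnin = 500, thin = 5)
  fit <- fit_gaussian_varcomp(d$y, d$unit, d$year, d$flyway, ctrl, seed = 1)
  td <- tidy(fit)
  expect_setequal(td$parameter,
                  c("intercept", "flyway_western", "V_B", "V_Y", "V_W", "R"))
  expect_true(all(td$q2.5 <= td$q97.5))
  expect_equal(nrow(fit$draws), (2000 - 500) / 5)
  g <- glance(fit)
  expect_true(g$repeatability > 0 && g$repeatability < 1)
  expect_warning(fit_gaussian_varcomp(d$y, rep(1:2, 20), d$year, NULL,
                                      ctrl, seed = 2),
                 "weakly identified")
})

test_that("tidy_draws returns one row per draw and parameter", {
  d <- sim_varcomp_data(n_unit = 8, n_obs = 3, seed = 2)
  fit <- fit_gaussian_varcomp(d$y, d$unit, d$year, NULL,
                              mcmc_control(iterations = 1000, burnin = 200,
                                           thin = 10), seed = 1)
  td <- tidy_draws(fit)
  expect_equal(nrow(td), nrow(fit$draws) * ncol(fit$draws))
  expect_setequal(names(td), c("parameter", "draw", "value"))
  expect_equal(td$value[td$parameter == "R" & td$draw == 1],
               fit$draws$R[1])
})
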