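test_that("grid building spans the background with closed last bin", {
  bg <- data.frame(temperature = 0:10)
  g <- build_grid(bg, "temperature", R = 10)
  expect_equal(g$edges$temperature, 0:10)
  expect_equal(nichetrack:::bin_index(10, g$edges$temperature), 10)
  expect_equal(nichetrack:::bin_index(0, g$edges$temperature), 1)
  expect_equal(nichetrack:::bin_index(9.999, g$edges$temperature), 10)
  expect_error(build_grid(data.frame(temperature = rep(1, 5)),
                          "temperature"), "degenerate")
  expect_error(build_grid(bg, "temperature", R = 1), ">= 2")
})

test_that("kernel density normalizes, peaks at a lone point, clamps", {
  bg <- data.frame(temperature = seq(0, 10, 0.5))
  g <- build_grid(bg, "temperature", R = 20)
  vals <- matrix(c(2, 3, 4, 4.5, 5, 5.2, 6, 7, 2.5, 3.5), ncol = 1,
                 dimnames = list(NULL, "temperature"))
  z <- kernel_density(vals, g)
  expect_equal(sum(z), 1, tolerance = 1e-9)
  expect_true(all(z >= 0))
  # single point at a cell midpoint: maximal there, symmetric decay
  mid <- g$mids$temperature[10]
  z1 <- kernel_density(matrix(rep(mid, 6), ncol = 1,
                              dimnames = list(NULL, "temperature")), g,
                       bw = c(temperature = 1))
  expect_equal(which.max(z1), 10)
  expect_equal(z1[10 - 3], z1[10 + 3], tolerance = 1e-12)
  # out-of-range occurrences are clamped into boundary bins and counted
  z2 <- kernel_density(matrix(c(-5, 15, 5, 5, 5), ncol = 1,
                              dimnames = list(NULL, "temperature")), g)
  expect_equal(attr(z2, "n_clamped"), 2)
  expect_error(kernel_density(matrix(1:3, ncol = 1,
                                     dimnames = list(NULL, "temperature")),
                              g),
               class = "nichetrack_insufficient_data")
})

test_that("1-D kernel density matches the brute-force oracle", {
  bg <- data.frame(temperature = seq(-2, 8, 0.25))
  g <- build_grid(bg, "temperature", R = 10)
  vals <- matrix(withr::with_seed(2, runif(10, -1, 7)), ncol = 1,
                 dimnames = list(NULL, "temperature"))
  z <- kernel_density(vals, g)
  expect_equal(as.vector(z), as.vector(naive_kde(vals, g)),
               tolerance = 1e-9)
})

test_that("occupancy corrects for availability and masks empty support", {
  # hand example: z_occ=(0.8,0.2), z_bkg=(0.5,0.5) -> z=(0.8,0.2)
  expect_equal(as.vector(occupancy(c(0.8, 0.2), c(0.5, 0.5))), c(0.8, 0.2))
  # occurrence proportional to background -> uniform over support
  z <- occupancy(c(0.1, 0.3, 0.6), c(0.1, 0.3, 0.6))
  expect_equal(as.vector(z), rep(1 / 3, 3))
  # unsupported cells masked and mass reported
  z2 <- occupancy(c(0.5, 0.5), c(1, 0))
  expect_equal(as.vector(z2), c(1, 0))
  expect_equal(attr(z2, "masked_occurrence"), 0.5)
  expect_error(occupancy(c(1, 0), c(0, 1)),
               class = "nichetrack_empty_niche")
  expect_error(occupancy(c(1, 0, 0), c(1, 0)), "aligned")
})

test_that("Schoener's D analytic cases and symmetry hold", {
  expect_equal(schoener_d(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(schoener_d(c(1, 0), c(0, 1)), 0)
  expect_equal(schoener_d(c(1, 0), c(0.5, 0.5)), 0.5)
  z1 <- c(0.1, 0.2, 0.7); z2 <- c(0.3, 0.3, 0.4)
  expect_equal(schoener_d(z1, z2), schoener_d(z2, z1))
  # invariant under cell relabeling
  p <- c(3, 1, 2)
  expect_equal(schoener_d(z1[p], z2[p]), schoener_d(z1, z2))
  expect_error(schoener_d(c(1, 0), c(1, 0, 0)), "aligned")
})

test_that("density -> occupancy -> D chain matches a naive reimplementation", {
  withr::local_seed(7)
  for (d in c(1, 3)) {
    axes <- c("temperature", "precipitation", "ndvi")[seq_len(d)]
    bg <- as.data.frame(matrix(runif(200 * d, 0, 10), ncol = d,
                               dimnames = list(NULL, axes)))
    g <- build_grid(bg, axes, R = if (d == 1) 10 else 6)
    occ1 <- matrix(runif(60 * d, 1, 9), ncol = d,
                   dimnames = list(NULL, axes))
    occ2 <- matrix(runif(60 * d, 2, 8), ncol = d,
                   dimnames = list(NULL, axes))
    zb <- kernel_density(as.matrix(bg), g)
    z1 <- occupancy(kernel_density(occ1, g), zb)
    z2 <- occupancy(kernel_density(occ2, g), zb)
    D <- schoener_d(z1, z2)
    # naive double-loop route
    zb_n <- naive_kde(as.matrix(bg), g)
    z1_n <- naive_occupancy(naive_kde(occ1, g), zb_n)
    z2_n <- naive_occupancy(naive_kde(occ2, g), zb_n)
    expect_equal(D, naive_schoener(z1_n, z2_n), tolerance = 1e-8)
  }
})

test_that("niche_background reuses a shared grid across seasons", {
  withr::local_seed(1)
  ann1 <- data.frame(temperature = rnorm(100, 10, 2))
  ann2 <- data.frame(temperature = rnorm(100, 14, 2))
  g <- build_grid(rbind(ann1, ann2), "temperature", R = 25)
  nb1 <- niche_background(ann1, "temperature", grid = g)
  nb2 <- niche_background(ann2, "temperature", grid = g)
  expect_identical(nb1$grid, nb2$grid)
  z <- niche_occupancy(matrix(rnorm(30, 10, 1), ncol = 1,
                              dimnames = list(NULL, "temperature")), nb1)
  expect_equal(sum(z), 1, tolerance = 1e-9)
})

test_that("doubling grid resolution changes D only slightly on smooth niches", {
  withr::local_seed(5)
  bg <- data.frame(temperature = runif(400, 0, 20),
                   precipitation = runif(400, 0, 100))
  occ1 <- cbind(temperature = rnorm(120, 8, 2),
                precipitation = rnorm(120, 40, 10))
  occ2 <- cbind(temperature = rnorm(120, 11, 2),
                precipitation = rnorm(120, 55, 10))
  D_at <- function(R) {
    g <- build_grid(bg, c("temperature", "precipitation"), R = R)
    zb <- kernel_density(as.matrix(bg), g)
    schoener_d(occupancy(kernel_density(occ1, g), zb),
               occupancy(kernel_density(occ2, g), zb))
  }
  expect_lt(abs(D_at(50) - D_at(25)), 0.05)
})
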