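#' Define a binned environmental-space grid from background values
#'
#' Per axis, `R` equal-width bins spanning the `[min, max]` of the
#' background values. Bins are half-open with the last bin closed, so a
#' value exactly at the maximum falls in the last bin.
#'
#' @param background data frame/matrix of background environmental values
#'   containing the `axes` columns.
#' @param axes character, ordered subset of the environmental variables.
#' @param R bins per axis (>= 2); default 100 for one axis, 50 otherwise.
#' @return list of class `niche_grid_def`: `axes`, `R`, per-axis `edges`
#'   and midpoints `mids`.
#' @export
build_grid <- function(background, axes = colnames(background), R = NULL) {
  R <- R %||% (if (length(axes) == 1L) 100L else 50L)
  if (R < 2) stop_cfg("`R` must be >= 2")
  edges <- mids <- stats::setNames(vector("list", length(axes)), axes)
  for (a in axes) {
    v <- if (is.matrix(background)) background[, a] else background[[a]]
    rng <- range(v)
    if (!all(is.finite(rng)) || diff(rng) <= 0)
      stop_cfg("background axis `%s` is degenerate (constant)", a)
    edges[[a]] <- seq(rng[1], rng[2], length.out = R + 1)
    mids[[a]] <- (edges[[a]][-1] + edges[[a]][-(R + 1)]) / 2
  }
  structure(list(axes = axes, R = as.integer(R), edges = edges, mids = mids),
            class = "niche_grid_def")
}

# clamp values into the grid's background range; count clamped points
clamp_to_grid <- function(values, grid) {
  n_clamped <- 0L
  for (a in grid$axes) {
    e <- grid$edges[[a]]
    v <- values[, a]
    out <- v < e[1] | v > e[length(e)]
    n_clamped <- n_clamped + sum(out)
    values[, a] <- pmin(pmax(v, e[1]), e[length(e)])
  }
  attr(values, "n_clamped") <- n_clamped
  values
}

# bin index per axis value: half-open bins, last bin closed
bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  i
}

#' Product-Gaussian kernel density on an environmental grid
#'
#' Evaluates a product-Gaussian kernel density smoother at the grid cell
#' midpoints, with per-axis bandwidths from Silverman's rule of thumb
#' ([stats::bw.nrd0()]) on the input values, and normalizes so the cell sum
#' is 1. Values outside the grid's background range are clamped into the
#' boundary bins (count recorded in attribute `n_clamped`). Because the
#' density is only resolved at bin scale, bandwidths are floored at half
#' the bin width; otherwise point masses much tighter than a cell make the
#' midpoint evaluation numerically degenerate.
#'
#' @param values matrix/data frame of environmental values with the grid's
#'   axes as columns.
#' @param grid a [build_grid()] definition.
#' @param bw optional named per-axis bandwidths overriding Silverman's rule.
#' @param min_points minimum number of points required (default 5).
#' @return array of dimension `rep(R, n_axes)` summing to 1, with
#'   attributes `n` and `n_clamped`.
#' @export
kernel_density <- function(values, grid, bw = NULL, min_points = 5) {
  values <- as_axis_matrix(values, grid$axes)
  n <- nrow(values)
  if (n < min_points)
    stop(errorCondition(
      sprintf("kernel_density: %d point(s) < minimum %d", n, min_points),
      class = c("nichetrack_insufficient_data", "error")))
  values <- clamp_to_grid(values, grid)
  d <- length(grid$axes)
  M <- vector("list", d)
  for (k in seq_len(d)) {
    a <- grid$axes[k]
    h <- if (!is.null(bw)) bw[[a]] else silverman_bw(values[, a])
    h <- max(h, diff(grid$edges[[a]][1:2]) / 2, na.rm = TRUE)
    M[[k]] <- exp(-0.5 * (outer(grid$mids[[a]], values[, a], `-`) / h)^2)
  }
  z <- contract_product_kernels(M)
  z <- z / sum(z)
  z <- array(z, dim = rep(grid$R, d))
  attr(z, "n") <- n
  attr(z, "n_clamped") <- attr(values, "n_clamped")
  z
}

silverman_bw <- function(v) {
  if (length(unique(v)) < 2) return(0)
  bw.nrd0(v)
}

as_axis_matrix <- function(values, axes) {
  if (is.matrix(values)) {
    if (!is.null(colnames(values)) && all(axes %in% colnames(values)))
      return(values[, axes, drop = FALSE])
    stopifnot(ncol(values) == length(axes))
    colnames(values) <- axes
    return(values)
  }
  as.matrix(values[, axes, drop = FALSE])
}

# sum over points of the outer product of per-axis kernel columns
contract_product_kernels <- function(M) {
  d <- length(M)
  if (d == 1) return(rowSums(M[[1]]))
  if (d == 2) return(M[[1]] %*% t(M[[2]]))
  if (d == 3) {
    R1 <- nrow(M[[1]]); R2 <- nrow(M[[2]]); R3 <- nrow(M[[3]])
    z <- array(0, c(R1, R2, R3))
    tM2 <- t(M[[2]])
    for (k in seq_len(R3)) z[, , k] <- M[[1]] %*% (tM2 * M[[3]][k, ])
    return(z)
  }
  stop_cfg("grids with more than 3 axes are not supported")
}

#' Background-corrected niche occupancy
#'
#' Divides the occurrence density by the background density cell-wise to
#' correct for the relative availability of environments, zeroing cells
#' without background support, and renormalizes to sum 1.
#'
#' @param z_occ occurrence density array (sums to 1).
#' @param z_bkg background density array on the same grid (sums to 1).
#' @param floor cells with background density `<= floor` are masked.
#'   Default (`NULL`): 1% of the uniform cell mass, i.e.
#'   `0.01 / n_cells`, which excludes essentially-unavailable
#'   environments; without this floor the density ratio is dominated by
#'   spurious spikes where the background kernel density underflows.
#'   Pass 0 to mask exact zeros only.
#' @return corrected occupancy array summing to 1; attribute
#'   `masked_occurrence` gives the occurrence mass discarded in masked
#'   cells.
#' @export
occupancy <- function(z_occ, z_bkg, floor = NULL) {
  floor <- floor %||% (0.01 / length(z_bkg))
  if (!identical(dim(z_occ) %||% length(z_occ),
                 dim(z_bkg) %||% length(z_bkg)))
    stop_cfg("occurrence and background grids are not aligned")
  supported <- z_bkg > floor
  z_raw <- ifelse(supported, z_occ / z_bkg, 0)
  tot <- sum(z_raw)
  if (tot <= 0)
    stop(errorCondition("occupancy: no occurrence mass on background support",
                        class = c("nichetrack_empty_niche", "error")))
  z <- z_raw / tot
  attr(z, "masked_occurrence") <- sum(z_occ[!supported])
  z
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` over aligned, normalized density grids;
#' 0 means no overlap, 1 perfect overlap; symmetric in its arguments.
#'
#' @param z1,z2 normalized density arrays on the same grid.
#' @return Schoener's D in `[0, 1]`.
#' @export
#' @examples
#' schoener_d(c(1, 0), c(0.5, 0.5))  # 0.5
schoener_d <- function(z1, z2) {
  if (!identical(dim(z1) %||% length(z1), dim(z2) %||% length(z2)))
    stop_cfg("grids are not aligned")
  min(1, max(0, 1 - 0.5 * sum(abs(z1 - z2))))
}

#' Precompute a background niche density for reuse
#'
#' Builds the grid definition from a background annotation table and the
#' background kernel density once, so that many occupancy computations and
#' permutation tests against the same availability sample can share them.
#'
#' @param annotation background annotation table (rows = background points,
#'   columns include the axes).
#' @param axes environmental axes to use.
#' @param R bins per axis (default 100 in 1-D, 50 otherwise).
#' @param grid optional prebuilt [build_grid()] definition; when several
#'   seasonal availabilities must share one grid frame, build the grid on
#'   their pooled values and pass it here.
#' @return list of class `niche_background`: `grid`, `z_bkg`, `values`
#'   (annotation matrix), `n`.
#' @export
niche_background <- function(annotation, axes, R = NULL, grid = NULL) {
  values <- as_axis_matrix(annotation, axes)
  if (is.null(grid)) grid <- build_grid(values, axes, R)
  z_bkg <- kernel_density(values, grid)
  structure(list(grid = grid, z_bkg = z_bkg, values = values,
                 n = nrow(values)),
            class = "niche_background")
}

#' Background-corrected occupancy of a set of occurrence environments
#'
#' Chains [kernel_density()] and [occupancy()] against a prebuilt
#' [niche_background()].
#'
#' @param values occurrence environmental values (matrix or data frame).
#' @param background a [niche_background()].
#' @param min_points minimum occurrence count.
#' @return corrected occupancy array.
#' @export
niche_occupancy <- function(values, background, min_points = 5) {
  z_occ <- kernel_density(values, background$grid, min_points = min_points)
  z <- occupancy(z_occ, background$z_bkg)
  attr(z, "n") <- attr(z_occ, "n")
  attr(z, "n_clamped") <- attr(z_occ, "n_clamped")
  z
}
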