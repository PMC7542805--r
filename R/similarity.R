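#' Draw null occurrence environments from the background
#'
#' The null model of the niche similarity test: the analysis unit uses
#' environments at random given availability, so simulated occurrence
#' environments are drawn uniformly without replacement from the rows of
#' the background annotation.
#'
#' @param n number of simulated occurrences.
#' @param annotation background annotation table or matrix (rows =
#'   annotated background points).
#' @param seed integer seed.
#' @return `n` rows of `annotation`. If `n` exceeds the background size the
#'   draw falls back to sampling with replacement (with a message).
#' @export
permute_occurrences <- function(n, annotation, seed = 1L) {
  N <- nrow(annotation)
  replace <- n > N
  if (replace)
    message(sprintf("permute_occurrences: n = %d > background size %d; sampling with replacement", n, N))
  idx <- with_substream(substream_seed(seed, "permute"),
                        sample.int(N, n, replace = replace))
  annotation[idx, , drop = FALSE]
}

#' Permutation-based niche similarity test for one season pair
#'
#' Tests whether the observed Schoener's D between two seasons' background-
#' corrected niches exceeds what is expected by chance given the available
#' environment ("niche tracking"). Half of the `n_perm` randomizations keep
#' season A observed and randomize season B within the background, the
#' other half vice versa; each simulated density is divided by the
#' background density exactly as the observed ones are. The unit tracks its
#' niche if the observed D is strictly greater than the empirical 95%
#' quantile of the simulated D values (ties count as non-tracking; the test
#' is one-sided).
#'
#' Each season's occurrence density is corrected by (and its null is drawn
#' from) that season's background annotation; the two backgrounds share one
#' grid frame. Passing a single `background` applies the same availability
#' to both seasons.
#'
#' @param occ1,occ2 occurrence environmental values of the two seasons
#'   (matrix or data frame with the background's axes as columns).
#' @param background availability of season 1: a [niche_background()], or
#'   a background annotation table (then `axes`/`R` are used to build one).
#' @param background2 availability of season 2 (a [niche_background()] on
#'   the same grid); defaults to `background`.
#' @param n_perm total number of randomizations (default 200: 100 per
#'   direction). Values below 20 give unstable quantiles and warn.
#' @param alpha significance level (default 0.05; the criterion uses the
#'   `1 - alpha` empirical quantile).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param axes,R forwarded to [niche_background()] when `background` is a
#'   raw annotation table.
#' @param min_points minimum occurrence count per season.
#' @param method null mechanism: `"resample"` draws simulated occurrences
#'   uniformly from the background annotation (default); `"shift"`
#'   translates the observed values by a random offset per axis, wrapped
#'   within the background range (sensitivity alternative).
#' @return object of class `similarity_result`: `D_obs`, `sims`, `q95`,
#'   `tracking`, `rank` (number of simulated values below `D_obs`),
#'   `n_perm`, `alpha`, `n1`, `n2`, `seed`, `method`.
#' @export
similarity_test <- function(occ1, occ2, background, background2 = NULL,
                            n_perm = 200,
                            alpha = 0.05, seed = 1L, axes = NULL, R = NULL,
                            min_points = 5,
                            method = c("resample", "shift")) {
  method <- match.arg(method)
  if (!inherits(background, "niche_background")) {
    axes <- axes %||% intersect(colnames(background),
                                c("temperature", "precipitation", "ndvi"))
    background <- niche_background(background, axes, R)
  }
  background2 <- background2 %||% background
  if (!identical(background$grid, background2$grid))
    stop_cfg("the two seasonal backgrounds must share one grid")
  if (n_perm < 20)
    warning("n_perm < 20 gives an unstable 95% quantile", call. = FALSE)
  v1 <- as_axis_matrix(occ1, background$grid$axes)
  v2 <- as_axis_matrix(occ2, background$grid$axes)
  z1 <- niche_occupancy(v1, background, min_points = min_points)
  z2 <- niche_occupancy(v2, background2, min_points = min_points)
  D_obs <- schoener_d(z1, z2)

  n_a <- n_perm %/% 2
  sims <- with_substream(substream_seed(seed, "simtest"), {
    sim_one <- function(v_perm, z_fixed, bkg) {
      v_sim <- if (method == "resample") {
        n_sim <- nrow(v_perm)
        bkg$values[sample.int(bkg$n, min(n_sim, bkg$n),
                              replace = n_sim > bkg$n), , drop = FALSE]
      } else {
        shift_values(v_perm, bkg$grid)
      }
      # a simulated niche entirely outside the availability support
      # overlaps nothing
      z_sim <- tryCatch(niche_occupancy(v_sim, bkg, min_points = 1),
                        nichetrack_empty_niche = function(e) NULL)
      if (is.null(z_sim)) return(0)
      schoener_d(z_sim, z_fixed)
    }
    c(vapply(seq_len(n_a), function(i) sim_one(v1, z2, background),
             numeric(1)),
      vapply(seq_len(n_perm - n_a), function(i) sim_one(v2, z1, background2),
             numeric(1)))
  })
  q95 <- sort(sims)[ceiling((1 - alpha) * n_perm)]
  structure(list(D_obs = D_obs, sims = sims, q95 = q95,
                 tracking = D_obs > q95, rank = sum(sims < D_obs),
                 n_perm = n_perm, alpha = alpha,
                 n1 = nrow(v1), n2 = nrow(v2), seed = seed,
                 method = method),
            class = "similarity_result")
}

# translate observed values by one random offset per axis, wrapping within
# the background range (alternative null: niche position is random)
shift_values <- function(values, grid) {
  for (a in grid$axes) {
    e <- grid$edges[[a]]
    lo <- e[1]; span <- e[length(e)] - lo
    off <- runif(1, 0, span)
    values[, a] <- lo + (values[, a] - lo + off) %% span
  }
  values
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> D_obs = %.4f vs null q95 = %.4f (%d randomizations): %s\n",
              x$D_obs, x$q95, x$n_perm,
              if (x$tracking) "niche tracking" else "no tracking"))
  invisible(x)
}

#' Proportion of significant niche tracking
#'
#' Percentage of units flagged as tracking within strata of a results
#' table.
#'
#' @param results tibble with a logical/0-1 `tracking` column.
#' @param ... optional grouping columns (tidy-select), e.g. `level, mode`.
#' @return tibble with the grouping columns, `n` and `tracking_pct`
#'   (0-100). With no grouping, a one-row tibble. An empty stratum yields
#'   no row (undefined proportion).
#' @export
tracking_proportion <- function(results, ...) {
  results |>
    dplyr::group_by(...) |>
    dplyr::summarise(n = dplyr::n(),
                     tracking_pct = 100 * mean(as.logical(.data$tracking)),
                     .groups = "drop")
}
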