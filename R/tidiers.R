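#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a variance-component fit
#'
#' One row per parameter with posterior mean, sd, 95% credible interval and
#' a significance flag (interval excluding 0) for the fixed effects.
#'
#' @param x a `varcomp_fit`.
#' @param ... unused.
#' @return tibble: `parameter`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `significant`.
#' @export
tidy.varcomp_fit <- function(x, ...) {
  d <- as.matrix(x$draws)
  out <- tibble::tibble(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, sd),
    q2.5 = apply(d, 2, quantile, 0.025),
    q97.5 = apply(d, 2, quantile, 0.975))
  fixed <- !out$parameter %in% c("V_B", "V_Y", "V_W", "R")
  out$significant <- fixed & (out$q2.5 > 0 | out$q97.5 < 0)
  out
}

#' One-line summary of a variance-component fit
#'
#' @param x a `varcomp_fit`.
#' @param ... unused.
#' @return one-row tibble: response kind, stored draws, posterior mean and
#'   95% CI of the repeatability, and whether the lag-1 autocorrelation
#'   check passed.
#' @export
glance.varcomp_fit <- function(x, ...) {
  V_W <- if (x$kind == "gaussian") x$draws$V_W
         else rep(x$link_variance, nrow(x$draws))
  R <- repeatability(x$draws$V_B, V_W)
  tibble::tibble(kind = x$kind, n_draws = nrow(x$draws),
                 repeatability = R$mean, R_q2.5 = R$q2.5, R_q97.5 = R$q97.5,
                 mixing_ok = isTRUE(attr(x$diagnostics, "pass")))
}

#' Tidy the null distribution of a similarity test
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return tibble with one row per randomization: `draw`, `D_sim`.
#' @export
tidy.similarity_result <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$sims), D_sim = x$sims)
}

#' One-row summary of a similarity test
#'
#' @param x a `similarity_result`.
#' @param ... unused.
#' @return one-row tibble: `D_obs`, `q95_sim`, `rank`, `tracking`,
#'   `n_perm`, `alpha`, `n1`, `n2`, `method`.
#' @export
glance.similarity_result <- function(x, ...) {
  tibble::tibble(D_obs = x$D_obs, q95_sim = x$q95, rank = x$rank,
                 tracking = x$tracking, n_perm = x$n_perm, alpha = x$alpha,
                 n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Long-format posterior draws of a variance-component fit
#'
#' @param x a `varcomp_fit`.
#' @return tibble with `parameter`, `draw`, `value` (one row per stored
#'   draw and parameter), ready for CSV export or plotting.
#' @export
tidy_draws <- function(x) {
  stopifnot(inherits(x, "varcomp_fit"))
  d <- x$draws
  d$draw <- seq_len(nrow(d))
  tidyr::pivot_longer(d, -"draw", names_to = "parameter",
                      values_to = "value")[, c("parameter", "draw",
                                               "value")]
}
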