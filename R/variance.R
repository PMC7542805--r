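#' Standardize values to z-scores
#'
#' Centring to mean 0 and scaling to sample standard deviation 1 (n - 1),
#' the conventional preparation of the overlap response before variance
#' partitioning.
#'
#' @param values numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
standardize <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s <= 0) stop_cfg("cannot standardize constant input")
  (values - mean(values)) / s
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @return one-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))  # t ~ -1.549, df ~ 2.941
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_cfg("need at least 2 observations per group")
  v1 <- var(x) / n1; v2 <- var(y) / n2
  se2 <- v1 + v2
  if (se2 <= 0) stop_cfg("zero pooled standard error")
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df),
                 mean_x = mean(x), mean_y = mean(y))
}

#' MCMC settings for the variance-component models
#'
#' Defaults are scaled for routine use (20 000 iterations, thinning 10,
#' burn-in 2 000, i.e. 1 800 stored draws). The heavier classical setting
#' (500 000 iterations, thinning 100, burn-in 50 000) is available by
#' passing those values. Priors: residual variance
#' scaled-inverse-chi-square with scale `V_r` and belief `nu_r`;
#' random-effect variances parameter-expanded (`sd = |alpha| * eta_sd`,
#' `alpha ~ N(alpha_mu, alpha_V)`), a half-t-like weakly informative prior.
#'
#' @param iterations total MCMC iterations.
#' @param burnin discarded initial iterations.
#' @param thin thinning interval.
#' @param V_r,nu_r residual-variance prior scale and belief.
#' @param V_g,nu_g expanded-prior scale and belief for random-effect
#'   variances.
#' @param alpha_mu,alpha_V mean and variance of the expansion parameter.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 20000, burnin = 2000, thin = 10,
                         V_r = 1, nu_r = 0.002,
                         V_g = 1, nu_g = 0.02,
                         alpha_mu = 0, alpha_V = 1000) {
  stopifnot(iterations > burnin, thin >= 1)
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 V_r = V_r, nu_r = nu_r, V_g = V_g, nu_g = nu_g,
                 alpha_mu = alpha_mu, alpha_V = alpha_V),
            class = "mcmc_control")
}

rinvgamma1 <- function(shape, rate) 1 / rgamma(1, shape = shape, rate = rate)

# one parameter-expanded random-intercept block: u = alpha * eta
# returns updated state after Gibbs updates of eta, alpha, eta_var
update_px_block <- function(state, resid_minus, group, n_groups, sigma2_e,
                            ctrl) {
  # eta_j | .
  S <- rowsum_vec(resid_minus, group, n_groups)
  cnt <- state$count
  prec <- state$alpha^2 * cnt / sigma2_e + 1 / state$eta_var
  mu <- (state$alpha * S / sigma2_e) / prec
  state$eta <- rnorm(n_groups, mu, sqrt(1 / prec))
  # alpha | . : regression of resid on eta[group]
  xg <- state$eta[group]
  prec_a <- sum(xg^2) / sigma2_e + 1 / ctrl$alpha_V
  mu_a <- (sum(xg * resid_minus) / sigma2_e + ctrl$alpha_mu / ctrl$alpha_V) /
    prec_a
  state$alpha <- rnorm(1, mu_a, sqrt(1 / prec_a))
  # eta_var | .
  state$eta_var <- rinvgamma1((ctrl$nu_g + n_groups) / 2,
                              (ctrl$nu_g * ctrl$V_g + sum(state$eta^2)) / 2)
  state$u <- state$alpha * state$eta
  state
}

rowsum_vec <- function(x, group, n_groups) {
  out <- numeric(n_groups)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s
  out
}

new_px_state <- function(group, n_groups) {
  list(eta = rep(0, n_groups), alpha = 1, eta_var = 1,
       u = rep(0, n_groups),
       count = tabulate(group, n_groups))
}

# shared Gibbs engine for the Gaussian and probit models
run_gibbs <- function(y, X, unit, year, ctrl, seed, binary, link_variance) {
  n <- length(y)
  n_unit <- max(unit); n_year <- max(year)
  p <- ncol(X)
  XtX <- crossprod(X)
  prior_beta_prec <- diag(1e-8, p)

  n_store <- floor((ctrl$iterations - ctrl$burnin) / ctrl$thin)
  draws <- matrix(NA_real_, n_store,
                  p + 3 + as.integer(!binary))
  par_names <- c(colnames(X), "V_B", "V_Y", if (!binary) "V_W", "R")
  colnames(draws) <- par_names

  with_substream(substream_seed(seed, "gibbs"), {
    beta <- rep(0, p)
    su <- new_px_state(unit, n_unit)
    sy <- new_px_state(year, n_year)
    sigma2_e <- 1
    l <- if (binary) ifelse(y > 0, 0.5, -0.5) else y
    stored <- 0L
    for (it in seq_len(ctrl$iterations)) {
      eta_lin_re <- su$u[unit] + sy$u[year]
      if (binary) {
        # latent threshold (probit) data augmentation, residual var 1
        mu <- drop(X %*% beta) + eta_lin_re
        u01 <- runif(n)
        pl <- pnorm(-mu)
        l <- mu + qnorm(ifelse(y > 0, pl + u01 * (1 - pl), u01 * pl))
        l[!is.finite(l)] <- mu[!is.finite(l)]  # guard extreme tails
        sigma2_e <- 1
      }
      # beta | .
      prec_b <- XtX / sigma2_e + prior_beta_prec
      mu_b <- solve(prec_b, crossprod(X, l - eta_lin_re) / sigma2_e)
      beta <- drop(mu_b + backsolve(chol(prec_b),
                                    rnorm(p)))
      xb <- drop(X %*% beta)
      # unit block | .
      su <- update_px_block(su, l - xb - sy$u[year], unit, n_unit,
                            sigma2_e, ctrl)
      # year block | .
      sy <- update_px_block(sy, l - xb - su$u[unit], year, n_year,
                            sigma2_e, ctrl)
      resid <- l - xb - su$u[unit] - sy$u[year]
      if (!binary) {
        sigma2_e <- rinvgamma1((ctrl$nu_r + n) / 2,
                               (ctrl$nu_r * ctrl$V_r + sum(resid^2)) / 2)
      }
      if (it > ctrl$burnin && (it - ctrl$burnin) %% ctrl$thin == 0) {
        stored <- stored + 1L
        V_B <- su$alpha^2 * su$eta_var
        V_Y <- sy$alpha^2 * sy$eta_var
        V_W <- if (binary) link_variance else sigma2_e
        draws[stored, ] <- c(beta, V_B, V_Y, if (!binary) sigma2_e,
                             V_B / (V_B + V_W))
      }
    }
  })
  draws
}

finish_varcomp <- function(draws, kind, ctrl, seed, link_variance = NULL) {
  diag_tab <- mcmc_diagnostics(draws)
  structure(list(draws = tibble::as_tibble(draws), kind = kind,
                 control = ctrl, seed = seed,
                 link_variance = link_variance,
                 diagnostics = diag_tab),
            class = "varcomp_fit")
}

build_design <- function(flyway, n) {
  if (is.null(flyway)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  f <- factor(flyway)
  if (nlevels(f) < 2) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- cbind(1, as.integer(f) - 1L)
  colnames(X) <- c("intercept", paste0("flyway_", levels(f)[2]))
  X
}

#' Bayesian variance partitioning of a Gaussian response
#'
#' Random-intercept model `y = X beta + u_unit + v_year + e` fitted by a
#' conjugate Gibbs sampler. The "nested individual within year" structure
#' is implemented as two additive random intercepts (unit and year);
#' repeatability uses the unit and residual components only,
#' `R = V_B / (V_B + V_W)`, with the year variance reported but excluded
#' from the denominator. Random-effect variances get parameter-expanded
#' (half-t-like) priors, the residual a scaled-inverse-chi-square prior
#' (see [mcmc_control()]).
#'
#' @param y numeric response (e.g. standardized niche overlap).
#' @param unit unit (individual or population) identifier per observation.
#' @param year year identifier per observation.
#' @param flyway optional two-level fixed effect (NULL = intercept only).
#' @param control an [mcmc_control()].
#' @param seed integer seed; the chain is deterministic given the seed.
#' @return object of class `varcomp_fit` holding the thinned post-burn-in
#'   draws of the fixed effects, `V_B` (between-unit), `V_Y` (year),
#'   `V_W` (residual) and repeatability `R`, plus lag-1 autocorrelation
#'   diagnostics. Use [tidy()]/[glance()] to summarise.
#' @export
fit_gaussian_varcomp <- function(y, unit, year, flyway = NULL,
                                 control = mcmc_control(), seed = 1L) {
  unit <- as.integer(factor(unit)); year <- as.integer(factor(year))
  if (max(unit) < 2) stop_cfg("need at least 2 units")
  if (max(unit) == 2)
    warning("only 2 units: the between-unit variance is weakly identified",
            call. = FALSE)
  X <- build_design(flyway, length(y))
  draws <- run_gibbs(y, X, unit, year, control, seed, binary = FALSE,
                     link_variance = NULL)
  finish_varcomp(draws, "gaussian", control, seed)
}

#' Bayesian variance partitioning of a binary response
#'
#' Latent-threshold (probit data augmentation) version of
#' [fit_gaussian_varcomp()] for a yes/no response such as niche tracking.
#' The residual variance is fixed at 1 on the latent scale; repeatability
#' is computed on the latent scale as `V_B / (V_B + link_variance)`.
#'
#' @param y01 0/1 (or logical) response; both classes must be present.
#' @param unit,year,flyway,control,seed as in [fit_gaussian_varcomp()].
#' @param link_variance the within-unit variance used in the repeatability
#'   denominator: 1 (probit latent residual, default) or `pi^2/3` for
#'   logit-comparable values.
#' @return a `varcomp_fit` (no `V_W` column; `R` uses `link_variance`).
#' @export
fit_binary_varcomp <- function(y01, unit, year, flyway = NULL,
                               control = mcmc_control(), seed = 1L,
                               link_variance = 1) {
  y01 <- as.integer(as.logical(y01))
  if (length(unique(y01)) < 2)
    stop_cfg("binary response must contain both classes")
  unit <- as.integer(factor(unit)); year <- as.integer(factor(year))
  if (max(unit) < 2) stop_cfg("need at least 2 units")
  if (max(unit) == 2)
    warning("only 2 units: the between-unit variance is weakly identified",
            call. = FALSE)
  X <- build_design(flyway, length(y01))
  draws <- run_gibbs(y01, X, unit, year, control, seed, binary = TRUE,
                     link_variance = link_variance)
  finish_varcomp(draws, "binary", control, seed, link_variance)
}

#' Repeatability from variance draws
#'
#' Per-draw `R = V_B / (V_B + V_W)` with posterior mean and 95% credible
#' interval. R runs from 0 (all variance within units) to 1 (all variance
#' between units).
#'
#' @param V_B,V_W equal-length vectors of positive variance draws.
#' @return one-row tibble: `mean`, `q2.5`, `q97.5`.
#' @export
repeatability <- function(V_B, V_W) {
  stopifnot(length(V_B) == length(V_W), all(V_B > 0), all(V_W > 0))
  R <- V_B / (V_B + V_W)
  tibble::tibble(mean = mean(R),
                 q2.5 = unname(quantile(R, 0.025)),
                 q97.5 = unname(quantile(R, 0.975)))
}

#' Lag-1 autocorrelation diagnostics for MCMC draws
#'
#' Chains are considered well mixed when every parameter's lag-1
#' autocorrelation is below 0.1 in absolute value.
#'
#' @param draws matrix or tibble of stored draws (columns = parameters).
#' @return tibble: `parameter`, `lag1_ac`, `mean`, `sd`, and attribute
#'   `"pass"` (logical).
#' @export
mcmc_diagnostics <- function(draws) {
  draws <- as.matrix(draws)
  ac1 <- apply(draws, 2, function(v) {
    if (sd(v) <= 0) return(NA_real_)
    acf(v, lag.max = 1, plot = FALSE)$acf[2]
  })
  out <- tibble::tibble(parameter = colnames(draws), lag1_ac = ac1,
                        mean = colMeans(draws),
                        sd = apply(draws, 2, sd))
  attr(out, "pass") <- all(is.finite(ac1)) && all(abs(ac1) < 0.1)
  out
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("<varcomp_fit> %s response, %d stored draws\n", x$kind,
              nrow(x$draws)))
  R <- repeatability(x$draws$V_B,
                     if (x$kind == "gaussian") x$draws$V_W
                     else rep(x$link_variance, nrow(x$draws)))
  cat(sprintf("  repeatability R = %.3f [%.3f, %.3f]\n",
              R$mean, R$q2.5, R$q97.5))
  if (!isTRUE(attr(x$diagnostics, "pass")))
    cat("  warning: lag-1 autocorrelation >= 0.1 for some parameter\n")
  invisible(x)
}
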