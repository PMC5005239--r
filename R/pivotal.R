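#' Pivotal quantities of a lower record sample
#'
#' For records from an EHLD with parameters `(theta, lambda)`, the
#' transforms \eqn{Z_i = -\log F(x_{L(i)})} are the partial sums of i.i.d.
#' standard exponential spacings \eqn{S_i}; the partial sums
#' \eqn{T_j = \sum_{i\le j} S_i} are Gamma(j, 1); the ratios
#' \eqn{U_j = (T_j/T_{j+1})^j} are i.i.d. Uniform(0,1); and
#' \eqn{W(\theta) = -2\sum_{j<k}\log U_j} is chi-squared with `2k - 2`
#' degrees of freedom.  `W` does not depend on `lambda` (the shape cancels
#' in the ratios), which is what lets it pivot the nuisance `theta` out.
#'
#' @param theta reciprocal scale at which to evaluate the transforms.
#' @param sample a [record_sample] (`k >= 2` for the `u`/`w` components).
#' @param lambda shape used for the `z`/`s`/`t` components (default 1;
#'   `w` is invariant to it).
#' @return list with components `z`, `s`, `t`, `u`, `w`.
#' @examples
#' r <- rehld_records(8, 1, 2, seed = 3)
#' ps <- pivotal_state(1, r)
#' all(ps$u > 0 & ps$u < 1)
#' @export
pivotal_state <- function(theta, sample, lambda = 1) {
  check_params(theta, lambda)
  x <- as_record_sample(sample)
  k <- length(x)
  t_base <- neglog_tanh_half(theta * x)   # T_j at lambda = 1, increasing in j
  z <- lambda * t_base
  s <- diff(c(0, z))
  u <- if (k >= 2) (t_base[-k] / t_base[-1])^(seq_len(k - 1)) else numeric(0)
  list(z = z, s = s, t = z, u = u,
       w = if (k >= 2) -2 * sum(log(u)) else NA_real_)
}

#' The record pivot W(theta)
#'
#' Evaluates \eqn{W(\theta) = -2 \sum_{j=1}^{k-1} \log U_j(\theta)} in the
#' numerically robust log form
#' \eqn{W = -2[\sum_{j<k} \log T_j - (k-1)\log T_k]}, vectorized over
#' `theta`.  `W` is strictly increasing in `theta`, from 0 at
#' `theta -> 0+` to infinity, and is chi-squared `2k - 2` at the true
#' `theta`.
#'
#' @param theta numeric vector of evaluation points, all `> 0`.
#' @param sample a [record_sample] with `k >= 2`.
#' @param deriv logical; also return the derivative `dW/dtheta`.
#' @return numeric vector `W(theta)`; with `deriv = TRUE`, a list
#'   `list(w, dw)`.
#' @export
w_statistic <- function(theta, sample, deriv = FALSE) {
  x <- as_record_sample(sample)
  k <- length(x)
  if (k < 2) stop("W(theta) requires k >= 2 records", call. = FALSE)
  if (any(!is.finite(theta) | theta <= 0))
    stop("'theta' must be > 0", call. = FALSE)
  U <- outer(theta, as.numeric(x))               # n x k matrix of theta * x_j
  LT <- matrix(log_neglog_tanh_half(U), nrow = length(theta))
  w <- -2 * (rowSums(LT[, -k, drop = FALSE]) - (k - 1) * LT[, k])
  if (!deriv) return(w)
  R <- matrix(dlog_neglog_tanh_half(U) * rep(as.numeric(x), each = length(theta)),
              nrow = length(theta))              # d log T_j / d theta
  dw <- -2 * (rowSums(R[, -k, drop = FALSE]) - (k - 1) * R[, k])
  list(w = w, dw = dw)
}

# Solve W(theta) = w for many targets at once: bracket by geometric
# expansion, seed with a monotone spline of log(theta) against W on a
# log-spaced grid, then polish with safeguarded Newton steps.  Used by the
# GPQ interval, where thousands of roots are needed per sample.
solve_w_equation <- function(targets, sample, tol = 1e-10, grid_n = 200) {
  x <- as_record_sample(sample)
  lo <- 1e-6; hi <- 10
  it <- 0
  while (w_statistic(lo, x) > min(targets)) {
    lo <- lo / 10; it <- it + 1
    if (it > 400) stop("failed to bracket W(theta) from below", call. = FALSE)
  }
  it <- 0
  while (w_statistic(hi, x) < max(targets)) {
    hi <- hi * 2; it <- it + 1
    if (it > 400) stop("failed to bracket W(theta) from above", call. = FALSE)
  }
  grid <- exp(seq(log(lo), log(hi), length.out = grid_n))
  wg <- w_statistic(grid, x)
  seed_fun <- stats::splinefun(wg, log(grid), method = "hyman")
  th <- exp(seed_fun(targets))
  for (iter in 1:4) {
    wd <- w_statistic(th, x, deriv = TRUE)
    resid <- wd$w - targets
    if (max(abs(resid)) < tol) break
    th <- pmin(pmax(th - resid / wd$dw, lo), hi)
  }
  resid <- w_statistic(th, x) - targets
  bad <- which(abs(resid) > 1e-6 * pmax(1, abs(targets)))
  for (b in bad) {  # rare fall-back: guaranteed bisection
    r <- stats::uniroot(function(t) w_statistic(t, x) - targets[b],
                        c(lo, hi), tol = tol)
    th[b] <- r$root
  }
  th
}

#' Pivotal estimator of the reciprocal scale
#'
#' Solves \eqn{W(\theta) = 2k - 4} for `theta`.  The left side is strictly
#' increasing and `W/(2k-4)` converges in probability to 1 with growing
#' `k`, so the root is unique and consistent.
#'
#' @param sample a [record_sample] with `k >= 3`.
#' @param tol root tolerance on `|W - (2k - 4)|`.
#' @return the estimate (scalar), with attribute `"w_residual"`.
#' @examples
#' r <- rehld_records(10, 1, 2, seed = 1)
#' theta_pivotal(r)
#' @export
theta_pivotal <- function(sample, tol = 1e-10) {
  x <- as_record_sample(sample)
  k <- length(x)
  if (k < 3) stop("theta_pivotal requires k >= 3 (so that 2k - 4 > 0)",
                  call. = FALSE)
  th <- solve_w_equation(2 * k - 4, x, tol = tol)
  structure(th, w_residual = w_statistic(th, x) - (2 * k - 4))
}

#' Pivotal (unbiased-type) estimator of the shape
#'
#' With `theta` known, \eqn{\hat\lambda_p(\theta) = (k-1)/h_1(\theta)} is
#' exactly unbiased with MSE \eqn{\lambda^2/(k-2)}.  With `theta` unknown
#' the pivotal estimate [theta_pivotal()] is plugged in (and unbiasedness
#' is no longer exact).
#'
#' @param sample a [record_sample] (`k >= 2` with `theta` supplied,
#'   `k >= 3` otherwise).
#' @param theta optional known reciprocal scale.
#' @return list with `lambda`, `theta`, and `theta_estimated` flag.
#' @export
lambda_pivotal <- function(sample, theta = NULL) {
  x <- as_record_sample(sample)
  k <- length(x)
  estimated <- is.null(theta)
  if (estimated) theta <- as.numeric(theta_pivotal(x))
  else if (k < 2) stop("requires k >= 2", call. = FALSE)
  list(lambda = (k - 1) / pivot_scale(theta, x), theta = theta,
       theta_estimated = estimated)
}

#' Exact confidence interval for the shape with known scale
#'
#' Uses \eqn{2\lambda h_1(\theta) \sim \chi^2_{2k}} to invert an exact
#' equal-tail interval \eqn{(\chi^2_{1-\alpha/2,2k},\ \chi^2_{\alpha/2,2k})
#' / (2 h_1(\theta))} (quantiles written as upper percentiles).
#'
#' @param sample a [record_sample].
#' @param theta the known reciprocal scale.
#' @param level confidence level in (0, 1).
#' @return named vector `c(lower, upper)`, both positive.
#' @export
exact_ci_lambda <- function(sample, theta, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  x <- as_record_sample(sample)
  k <- length(x)
  h1 <- pivot_scale(theta, x)
  alpha <- 1 - level
  c(lower = stats::qchisq(alpha / 2, 2 * k) / (2 * h1),
    upper = stats::qchisq(1 - alpha / 2, 2 * k) / (2 * h1))
}

#' Generalized-pivotal confidence interval for the shape
#'
#' Monte-Carlo interval for `lambda` with the scale pivoted out: per draw,
#' sample \eqn{W \sim \chi^2_{2(k-1)}} and solve \eqn{W(\theta^*) = W} for
#' the pseudo-scale \eqn{\theta^*}; sample \eqn{2T_k \sim \chi^2_{2k}};
#' the generalized pivot is \eqn{T_k / h_1(\theta^*)}.  The equal-tail
#' empirical percentiles (type-7) of `n_draws` such values form the
#' interval; it is exact in coverage for every `k >= 2`.
#'
#' @param sample a [record_sample] with `k >= 2`.
#' @param level confidence level.
#' @param n_draws Monte-Carlo size (default 10000).
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return list with `interval` (`c(lower, upper)`), `level`, `n_draws`,
#'   `seed`, and `draws_summary`.
#' @examples
#' r <- rehld_records(10, 1, 2, seed = 1)
#' gpq_ci_lambda(r, n_draws = 2000, seed = 7)$interval
#' @export
gpq_ci_lambda <- function(sample, level = 0.95, n_draws = 10000,
                          seed = NULL) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must be in (0, 1)", call. = FALSE)
  if (n_draws < 100) stop("'n_draws' must be >= 100", call. = FALSE)
  x <- as_record_sample(sample)
  k <- length(x)
  if (k < 2) stop("GPQ interval requires k >= 2 records", call. = FALSE)
  run <- function() {
    w <- stats::rchisq(n_draws, 2 * (k - 1))
    t_k <- stats::rchisq(n_draws, 2 * k) / 2
    theta_star <- solve_w_equation(w, x)
    t_k / exp(pivot_scale(theta_star, x, log = TRUE))
  }
  g <- if (is.null(seed)) run() else with_seed(seed, run())
  alpha <- 1 - level
  ci <- stats::quantile(g, c(alpha / 2, 1 - alpha / 2), type = 7,
                        names = FALSE)
  list(interval = c(lower = ci[1], upper = ci[2]), level = level,
       n_draws = n_draws, seed = seed,
       draws_summary = summary(g))
}
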