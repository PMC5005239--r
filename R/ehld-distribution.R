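#' The exponentiated half-logistic distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the exponentiated half-logistic distribution (EHLD) with
#' reciprocal-scale parameter `theta` and shape parameter `lambda`:
#' \deqn{F(x) = \left(\frac{1 - e^{-\theta x}}{1 + e^{-\theta x}}\right)^\lambda
#'            = \tanh(\theta x / 2)^\lambda, \quad x > 0.}
#'
#' The density is decreasing on \eqn{(0,\infty)} for `lambda <= 1` and
#' right-skewed unimodal for `lambda > 1`.  `theta` has units of 1/x;
#' `lambda` is dimensionless.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param theta reciprocal scale parameter, `> 0`.
#' @param lambda shape parameter, `> 0`.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#'
#' @return `dehld` the density, `pehld` the distribution function, `qehld`
#'   the quantile function, `rehld` random draws.
#'
#' @examples
#' pehld(log(3), theta = 1, lambda = 1)   # exactly 0.5
#' qehld(0.5, theta = 1, lambda = 1)      # log(3)
#' integrate(dehld, 0, Inf, theta = 0.2, lambda = 8)
#' @name ehld
NULL

#' @rdname ehld
#' @export
dehld <- function(x, theta, lambda, log = FALSE) {
  check_params(theta, lambda)
  stopifnot(is.numeric(x))
  ld <- rep(-Inf, length(x))
  pos <- is.finite(x) & x > 0
  ld[pos] <- log(theta) + log(lambda) +
    lambda * log_tanh_half(theta * x[pos]) - log_sinh(theta * x[pos])
  if (log) ld else exp(ld)
}

#' @rdname ehld
#' @export
pehld <- function(q, theta, lambda, log.p = FALSE) {
  check_params(theta, lambda)
  stopifnot(is.numeric(q))
  lp <- rep(-Inf, length(q))
  pos <- is.finite(q) & q > 0
  lp[pos] <- lambda * log_tanh_half(theta * q[pos])
  if (log.p) lp else exp(lp)
}

#' @rdname ehld
#' @export
qehld <- function(p, theta, lambda) {
  check_params(theta, lambda)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  (2 / theta) * atanh(p^(1 / lambda))
}

#' @rdname ehld
#' @export
rehld <- function(n, theta, lambda) {
  qehld(stats::runif(n), theta, lambda)
}

#' Simulate lower record values from the EHLD
#'
#' Draws the first `k` lower record values of an i.i.d. EHLD sequence using
#' the exact exponential-spacings construction: the negative log CDF values
#' \eqn{Z_i = -\log F(X_{L(i)})} of successive lower records are partial
#' sums of i.i.d. standard exponentials, so
#' \eqn{X_{L(i)} = F^{-1}(e^{-Z_i})}.  This is exact and does not require
#' simulating the (exponentially rare) raw record process.
#'
#' @param k number of records, `>= 1`.
#' @param theta,lambda EHLD parameters, both `> 0`.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return a [record_sample] of length `k` (strictly decreasing, positive).
#'
#' @examples
#' r <- rehld_records(10, theta = 1, lambda = 2, seed = 1)
#' all(diff(r) < 0)
#' @export
rehld_records <- function(k, theta, lambda, seed = NULL) {
  check_params(theta, lambda)
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != round(k))
    stop("'k' must be a single integer >= 1", call. = FALSE)
  draw <- function() {
    z <- cumsum(stats::rexp(k))
    # x = F^{-1}(exp(-z)); exp(-z)^(1/lambda) computed on the log scale
    (2 / theta) * atanh(exp(-z / lambda))
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  record_sample(x)
}

# --- stable elementary transforms ------------------------------------------
#
# All record-value inference below reduces to T(u) = -log tanh(u/2), the
# negative log CDF of the baseline (lambda = 1) half-logistic distribution.
# T is evaluated in three regimes: a log(2/u) asymptote for tiny u (where
# exp(-u) rounds to 1), the exact log1p form in the bulk, and 2*exp(-u)
# asymptotics for large u where only log T stays representable.

# log tanh(u/2) for u > 0, stable at both ends
log_tanh_half <- function(u) {
  e <- exp(-u)
  log1p(-e) - log1p(e)
}

# log sinh(u), stable at both ends: sinh(u) = e^u (1 - e^{-2u}) / 2
log_sinh <- function(u) {
  u + log1p(-exp(-2 * u)) - log(2)
}

# T(u) = -log tanh(u/2)
neglog_tanh_half <- function(u) {
  out <- u
  small <- u < 1e-8
  out[small] <- log(2 / u[small])
  out[!small] <- -log_tanh_half(u[!small])
  out
}

# log T(u), representable even when T underflows (u > ~745)
log_neglog_tanh_half <- function(u) {
  out <- u
  small <- u < 1e-8
  big <- u > 30
  mid <- !small & !big
  out[small] <- log(log(2 / u[small]))
  out[big] <- log(2) - u[big]
  out[mid] <- log(-log_tanh_half(u[mid]))
  out
}

# d/du log T(u) = -1/(sinh(u) T(u)); returns T'(u)/T(u)
dlog_neglog_tanh_half <- function(u) {
  out <- u
  small <- u < 1e-8
  big <- u > 30
  mid <- !small & !big
  out[small] <- -1 / (u[small] * log(2 / u[small]))
  out[big] <- -1
  out[mid] <- -1 / (sinh(u[mid]) * neglog_tanh_half(u[mid]))
  out
}

check_params <- function(theta, lambda) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0)
    stop("'theta' must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single finite number > 0", call. = FALSE)
  invisible(TRUE)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
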