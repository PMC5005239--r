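#' Pivot scale of a record sample
#'
#' The statistic \eqn{h_1(\theta) = -\log F_0(x_{L(k)}; \theta)
#' = -\log\tanh(\theta x_{L(k)}/2)}, where \eqn{F_0} is the baseline
#' (`lambda = 1`) half-logistic CDF and \eqn{x_{L(k)}} is the smallest
#' observed record.  At the true parameters, `lambda * pivot_scale(theta,
#' sample)` is Gamma(k, 1) distributed, which makes this the scale of every
#' pivot-based procedure in the package; it also appears in the profile
#' likelihood (the profile MLE of the shape is `k / pivot_scale(theta, x)`).
#'
#' Strictly decreasing in `theta`, diverging as `theta -> 0` and vanishing
#' as `theta -> Inf`; evaluated stably at both ends.
#'
#' @param theta reciprocal scale, `> 0` (vectorized).
#' @param sample a [record_sample] (only the smallest record is used).
#' @param log logical; return the log of the statistic (representable even
#'   where the statistic itself underflows).
#' @return numeric vector, same length as `theta`.
#' @examples
#' r <- record_sample(c(5, 3, 2))
#' pivot_scale(c(0.5, 1, 2), r)
#' @export
pivot_scale <- function(theta, sample, log = FALSE) {
  sample <- as_record_sample(sample)
  if (any(!is.finite(theta) | theta <= 0))
    stop("'theta' must be > 0", call. = FALSE)
  u <- theta * sample[length(sample)]
  if (log) log_neglog_tanh_half(u) else neglog_tanh_half(u)
}

#' Expected-information series terms for the EHLD record likelihood
#'
#' Evaluates the two series that carry the `theta`-block of the expected
#' Fisher information of `k` lower EHLD records: `Q1` (with
#' \eqn{I_{\theta\theta} = Q_1(\lambda)/\theta^2}) and `Q2` (with
#' \eqn{I_{\theta\lambda} = Q_2(\lambda)/\theta}).  The underlying expansions
#' come from integrating the negative second derivatives of the record
#' log-likelihood against the marginal densities of the record values, term
#' by term in powers of \eqn{e^{-\theta x}}; each outer series is truncated
#' once its (multiplier-weighted) terms fall below `tol`.
#'
#' @param lambda shape parameter, `> 0`.
#' @param k number of records, `>= 1`.
#' @param tol absolute truncation tolerance on the contribution of a term
#'   to `Q1`/`Q2`.
#' @param max_terms hard cap on the number of outer-series terms; exceeding
#'   it raises an error rather than returning a silently unconverged value.
#' @return list with elements `Q1`, `Q2` and `terms` (outer terms used).
#' @examples
#' ehld_info_series(2, 5)
#' @export
ehld_info_series <- function(lambda, k, tol = 1e-12, max_terms = 1e6) {
  check_params(1, lambda)
  if (k < 1 || k != round(k)) stop("'k' must be an integer >= 1", call. = FALSE)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)

  i <- seq_len(k)
  lam_i <- lambda^i          # weights of the per-record series
  lam_k1 <- lambda^(k + 1)

  chunk <- 1024L
  j0 <- 0L
  q_even <- 0; q_alt <- 0; q_cross <- 0
  s_even <- numeric(k); s_alt <- numeric(k)
  H <- 0            # harmonic sum up to current j
  A <- 0            # alternating harmonic sum up to current 2j-1
  repeat {
    j <- j0 + seq_len(chunk)
    # cumulative inner sums continued across chunks
    Hj <- H + cumsum(1 / j)                                   # sum_{l<=j} 1/l
    l <- (2 * (j0 + 1) - 1):(2 * (j[chunk]) - 1)
    Aall <- A + cumsum((-1)^(l + 1) / l)
    A2jm1 <- Aall[seq(1, length(l), by = 2)]                  # at l = 2j-1
    H <- Hj[chunk]; A <- Aall[length(l)]

    even_w <- (1 + (-1)^(j + 1)) / (j + 1)                    # 2/(j+1), odd j
    # k-indexed series (feed Q1's lambda^{k+1} block and Q2)
    t_even <- even_w * (1 / (j - 1 + lambda)^k - 1 / (j + 3 + lambda)^k) * Hj
    t_alt  <- (1 / j) * (1 / (2 * j - 2 + lambda)^k -
                         1 / (2 * j + 2 + lambda)^k) * A2jm1
    t_cross <- (1 / (2 * j - 1)) * (1 / (2 * j - 2 + lambda)^k -
                                    1 / (2 * j + lambda)^k)
    q_even <- q_even + sum(t_even)
    q_alt <- q_alt + sum(t_alt)
    q_cross <- q_cross + sum(t_cross)
    # i-indexed series, i = 1..k (second-difference kernels)
    P1 <- outer(j - 1 + lambda, i, "^"); P2 <- outer(j + 3 + lambda, i, "^")
    P3 <- outer(j + 1 + lambda, i, "^")
    M_even <- (even_w * Hj) * (1 / P1 + 1 / P2 - 2 / P3)
    E1 <- outer(2 * j - 2 + lambda, i, "^"); E2 <- outer(2 * j + 2 + lambda, i, "^")
    E3 <- outer(2 * j + lambda, i, "^")
    M_alt <- (A2jm1 / j) * (1 / E1 + 1 / E2 - 2 / E3)
    s_even <- s_even + colSums(M_even)
    s_alt <- s_alt + colSums(M_alt)

    # truncation is judged on each series' contribution to Q1/Q2, i.e.
    # with the lambda-power multiplier it actually carries
    biggest <- max(max(abs(t_even[chunk]), abs(t_alt[chunk])) * lam_k1 / 2,
                   abs(t_cross[chunk]) * lambda^k,
                   abs(M_even[chunk, ]) * lam_i / 2,
                   abs(M_alt[chunk, ]) * lam_i / 2)
    j0 <- j0 + chunk
    if (biggest < tol) break
    if (j0 >= max_terms)
      stop(sprintf(
        "information series not converged after %d terms (last term %.3e)",
        j0, biggest), call. = FALSE)
  }
  Q1 <- k + lam_k1 * (q_even + q_alt) / 2 - sum(lam_i * (s_even + s_alt) / 2)
  Q2 <- -lambda^k * q_cross
  list(Q1 = Q1, Q2 = Q2, terms = j0)
}

#' Expected Fisher information of EHLD lower records
#'
#' The 2x2 expected information matrix for `(lambda, theta)` from `k` lower
#' records: \eqn{I_{\lambda\lambda} = k/\lambda^2},
#' \eqn{I_{\lambda\theta} = Q_2(\lambda)/\theta},
#' \eqn{I_{\theta\theta} = Q_1(\lambda)/\theta^2}, with the `Q` series from
#' [ehld_info_series()].  The matrix is positive definite iff
#' \eqn{[\lambda Q_2(\lambda)]^2 / Q_1(\lambda) < k}; outside that region
#' an error names the violated constraint.
#'
#' @inheritParams ehld_info_series
#' @param theta reciprocal scale, `> 0`.
#' @return object of class `fisher_info`: list with the matrix `I`, its
#'   inverse `V`, and asymptotic variances `var_lambda`, `var_theta`.
#' @examples
#' ehld_fisher_info(theta = 1, lambda = 2, k = 10)
#' @export
ehld_fisher_info <- function(theta, lambda, k, tol = 1e-12, max_terms = 1e6) {
  check_params(theta, lambda)
  q <- ehld_info_series(lambda, k, tol, max_terms)
  I <- matrix(c(k / lambda^2,    q$Q2 / theta,
                q$Q2 / theta,    q$Q1 / theta^2), 2, 2,
              dimnames = list(c("lambda", "theta"), c("lambda", "theta")))
  det <- I[1, 1] * I[2, 2] - I[1, 2]^2
  if (!is.finite(det) || det <= 0 || I[2, 2] <= 0)
    stop(sprintf(paste0(
      "information matrix not positive definite: ",
      "[lambda*Q2(lambda)]^2 / Q1(lambda) = %.4g is not < k = %d"),
      (lambda * q$Q2)^2 / q$Q1, k), call. = FALSE)
  V <- solve(I)
  structure(list(I = I, V = V, Q1 = q$Q1, Q2 = q$Q2,
                 var_lambda = V[1, 1], var_theta = V[2, 2], k = k,
                 theta = theta, lambda = lambda),
            class = "fisher_info")
}

#' @export
print.fisher_info <- function(x, ...) {
  cat(sprintf("Expected Fisher information, k = %d records at (lambda = %.4g, theta = %.4g)\n",
              x$k, x$lambda, x$theta))
  print(x$I)
  cat(sprintf("asymptotic variances: lambda %.4g, theta %.4g\n",
              x$var_lambda, x$var_theta))
  invisible(x)
}
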