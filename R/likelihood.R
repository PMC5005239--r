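#' Record-value log-likelihood for the EHLD
#'
#' Log-likelihood of `(lambda, theta)` given `k` lower record values:
#' \deqn{\ell = k\log\theta + k\log\lambda + k\log 2
#'   + \lambda \log\tanh(\theta x_{L(k)}/2)
#'   - \theta \sum_i x_{L(i)} - \sum_i \log(1 - e^{-2\theta x_{L(i)}}).}
#' For `k = 1` this reduces to the log density of a single EHLD draw.
#'
#' @param theta,lambda EHLD parameters, both `> 0`.
#' @param sample a [record_sample].
#' @return the log-likelihood (scalar).
#' @examples
#' r <- record_sample(c(5, 3, 2))
#' ehld_loglik(0.5, 2, r)
#' @export
ehld_loglik <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  x <- as_record_sample(sample)
  k <- length(x)
  k * log(theta) + k * log(lambda) + k * log(2) +
    lambda * log_tanh_half(theta * x[k]) -
    theta * sum(x) - sum(log1p(-exp(-2 * theta * x)))
}

#' Score of the record-value log-likelihood
#'
#' The two partial derivatives of [ehld_loglik()].  The `lambda` component
#' is `k/lambda - h1(theta)` with `h1` the [pivot_scale()]; setting it to
#' zero gives the closed-form profile MLE `lambda = k/h1(theta)`.
#'
#' @inheritParams ehld_loglik
#' @return named numeric vector `c(d_lambda, d_theta)`.
#' @export
ehld_score <- function(theta, lambda, sample) {
  check_params(theta, lambda)
  x <- as_record_sample(sample)
  k <- length(x)
  xk <- x[k]
  d_lambda <- k / lambda - pivot_scale(theta, x)
  e2 <- exp(-2 * theta * x)
  d_theta <- k / theta +
    lambda * 2 * exp(-theta * xk) / (1 - exp(-2 * theta * xk)) * xk -
    sum((1 + e2) / (1 - e2) * x)
  c(d_lambda = d_lambda, d_theta = d_theta)
}

#' Joint maximum-likelihood estimation from lower records
#'
#' Maximizes the record likelihood over `(lambda, theta)` by profiling:
#' the shape solves its score equation in closed form,
#' `lambda(theta) = k / h1(theta)`, and the resulting one-dimensional
#' profile log-likelihood is maximized over `theta` on a log-spaced bracket
#' (golden-section/parabolic refinement).  The joint score at the optimum
#' is verified; non-convergence is an error, not a warning.
#'
#' With `level` the Wald confidence intervals
#' \eqn{\hat\lambda \pm z_{\alpha/2}\sqrt{Var(\hat\lambda)}} (and likewise
#' for `theta`) are computed from the inverse expected information at the
#' MLE.  Their lower bounds can be negative; they are reported as computed
#' unless `floor_at_zero = TRUE`.
#'
#' @param sample a [record_sample] with `k >= 2`.
#' @param level confidence level for Wald intervals, or `NULL` to skip them.
#' @param floor_at_zero truncate negative Wald lower bounds at 0.
#' @param tol series truncation tolerance passed to [ehld_fisher_info()].
#' @param score_tol largest acceptable joint score norm at the optimum.
#' @return object of class `ehld_mle`: list with `theta`, `lambda`,
#'   `loglik`, `score`, optional `ci` (2x2 matrix) and `info`
#'   ([ehld_fisher_info()] result), and `diagnostics`.
#' @examples
#' r <- rehld_records(10, theta = 1, lambda = 2, seed = 1)
#' ehld_mle(r)
#' @export
ehld_mle <- function(sample, level = 0.95, floor_at_zero = FALSE,
                     tol = 1e-12, score_tol = 1e-6) {
  x <- as_record_sample(sample)
  k <- length(x)
  if (k < 2) stop("joint MLE requires k >= 2 records", call. = FALSE)
  xbar <- mean(x)
  profile <- function(theta)
    k * log(theta) - k * pivot_scale(theta, x, log = TRUE) -
      theta * sum(x) - sum(log1p(-exp(-2 * theta * x)))
  opt <- stats::optimize(profile, c(1e-6 / xbar, 100 / xbar),
                         maximum = TRUE, tol = 1e-12)
  theta_hat <- opt$maximum
  # Newton polish on the profile score (the envelope theorem makes the
  # partial theta-score the exact profile derivative)
  g <- function(t) ehld_score(t, k / pivot_scale(t, x), x)[["d_theta"]]
  for (it in 1:8) {
    g0 <- g(theta_hat)
    if (abs(g0) < 1e-10) break
    h <- 1e-6 * theta_hat
    dg <- (g(theta_hat + h) - g(theta_hat - h)) / (2 * h)
    step <- g0 / dg
    if (!is.finite(step) || abs(step) > theta_hat / 2) break
    theta_hat <- theta_hat - step
  }
  lambda_hat <- k / pivot_scale(theta_hat, x)
  sc <- ehld_score(theta_hat, lambda_hat, x)
  if (!all(is.finite(sc)) || abs(sc["d_theta"]) > score_tol * max(1, abs(opt$objective)))
    stop(sprintf("profile MLE did not converge: score = (%.3e, %.3e) at theta = %.6g",
                 sc[1], sc[2], theta_hat), call. = FALSE)
  out <- list(theta = theta_hat, lambda = lambda_hat,
              loglik = ehld_loglik(theta_hat, lambda_hat, x),
              score = sc, k = k,
              diagnostics = list(profile_objective = opt$objective,
                                 bracket = c(1e-6 / xbar, 100 / xbar)))
  if (!is.null(level)) {
    stopifnot(level > 0, level < 1)
    info <- ehld_fisher_info(theta_hat, lambda_hat, k, tol = tol)
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- rbind(lambda = lambda_hat + c(-1, 1) * z * sqrt(info$var_lambda),
                theta  = theta_hat  + c(-1, 1) * z * sqrt(info$var_theta))
    colnames(ci) <- c("lower", "upper")
    if (floor_at_zero) ci[, "lower"] <- pmax(ci[, "lower"], 0)
    out$ci <- ci
    out$level <- level
    out$info <- info
  }
  structure(out, class = "ehld_mle")
}

#' @export
print.ehld_mle <- function(x, ...) {
  cat(sprintf("EHLD record MLE (k = %d): lambda = %.4f, theta = %.4f\n",
              x$k, x$lambda, x$theta))
  cat(sprintf("log-likelihood %.4f, score norm %.2e\n",
              x$loglik, sqrt(sum(x$score^2))))
  if (!is.null(x$ci)) {
    cat(sprintf("%d%% Wald intervals:\n", round(100 * x$level)))
    print(round(x$ci, 4))
  }
  invisible(x)
}

#' Wald confidence intervals for the EHLD parameters
#'
#' Convenience wrapper around [ehld_mle()] returning the symmetric
#' large-sample intervals only.
#'
#' @inheritParams ehld_mle
#' @return 2x2 matrix with rows `lambda`, `theta`.
#' @export
wald_ci <- function(sample, level = 0.95, floor_at_zero = FALSE,
                    tol = 1e-12) {
  ehld_mle(sample, level = level, floor_at_zero = floor_at_zero,
           tol = tol)$ci
}
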