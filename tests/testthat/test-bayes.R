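test_that("vague-prior plug-in posterior is the stated gamma law", {
  r <- rainfall()
  post <- lambda_posterior_vague(r, 0.01, 0.01, interval = "equal-tail")
  expect_equal(post$theta_map, 0.156, tolerance = 0.005)
  expect_equal(post$mean, 7.051, tolerance = 0.005)
  h1 <- pivot_scale(post$theta_map, r)
  expect_equal(post$mean, (10 + 0.01) / (0.01 + h1), tolerance = 1e-10)
  expect_equal(unname(post$interval),
               qgamma(c(0.025, 0.975), 10.01, rate = 0.01 + h1),
               tolerance = 1e-9)
  # hyperparameters -> 0 recovers the known-scale MLE (mean) and the
  # unbiased estimator (mode) at the corresponding MAP scale
  p0 <- lambda_posterior_vague(r, 1e-9, 1e-9)
  h0 <- pivot_scale(p0$theta_map, r)
  expect_equal(p0$mean, 10 / h0, tolerance = 1e-6)
  expect_equal(p0$mode, 9 / h0, tolerance = 1e-6)
})

test_that("theta MAP maximizes the marginal posterior away from the zero spike", {
  r <- rainfall()
  tm <- theta_map(r)
  d <- num_deriv(function(t)
    log_marginal_posterior_theta(t, r, "vague"), tm, h = 1e-7)
  expect_lt(abs(d), 1e-4)
  # scale equivariance: scaling the data by s scales the profile by 1/s
  s <- 3.7
  r2 <- record_sample(as.numeric(r) / s)
  expect_equal(theta_map(r2), tm * s, tolerance = 1e-6)
})

test_that("hierarchical posterior reproduces the rainfall analysis and is robust to c", {
  r <- rainfall()
  means <- sapply(c(5, 100, 500), function(cc)
    lambda_posterior_hier(r, c = cc)$mean)
  expect_equal(means[1], 5.891, tolerance = 0.005)
  expect_lt(max(means) - min(means), 0.005)
  maps <- sapply(c(5, 100, 500), function(cc)
    theta_map(r, "hierarchical", c = cc))
  expect_true(all(abs(maps - 0.137) < 0.005))
  # posterior mean identity through the auxiliary constants
  hc <- hier_constants(maps[1], 5, r)
  expect_equal(means[1], 9 * hc[["h3"]] / hc[["h2"]], tolerance = 1e-9)
})

test_that("hierarchical posterior CDF matches quadrature of its density", {
  r <- rainfall()
  post <- lambda_posterior_hier(r, c = 5)
  h1 <- pivot_scale(post$theta_map, r)
  k <- length(r); cc <- 5
  dens <- function(l) {
    h2 <- 1 / h1^(k - 1) - (cc * k + h1) / (cc + h1)^k
    l^(k - 2) * (1 - (1 + cc * l) * exp(-cc * l)) * exp(-l * h1) /
      (gamma(k - 1) * h2)
  }
  expect_equal(stats::integrate(dens, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  for (q in c(2, 5, 9)) {
    quad <- stats::integrate(dens, 0, q, rel.tol = 1e-10)$value
    expect_equal(post$cdf(q), quad, tolerance = 1e-8)
  }
  # equal-tail endpoints sit at the right CDF levels
  et <- lambda_posterior_hier(r, c = 5, interval = "equal-tail")$interval
  expect_equal(post$cdf(et[["lower"]]), 0.025, tolerance = 1e-8)
  expect_equal(post$cdf(et[["upper"]]), 0.975, tolerance = 1e-8)
  # HPD is never longer than equal-tail at the same level
  expect_lte(diff(post$interval), et[["upper"]] - et[["lower"]])
})

test_that("hierarchical mean tends to the pivotal unbiased estimator as c grows", {
  r <- rainfall()
  big <- lambda_posterior_hier(r, c = 1e6)
  expect_equal(big$mean,
               (length(r) - 1) / pivot_scale(big$theta_map, r),
               tolerance = 1e-4)
  # h2/h3 limit directly, at fixed theta
  hc <- hier_constants(0.137, 1e8, r)
  expect_equal(9 * hc[["h3"]] / hc[["h2"]],
               9 / pivot_scale(0.137, r), tolerance = 1e-6)
})

test_that("auxiliary constants match closed arithmetic and quadrature", {
  # k = 2, h1 = 1, c = 1: h2 = 1 - 3/4 = 1/4; choose x so that theta = 1
  # gives h1 = 1, i.e. x_2 with -log tanh(x_2/2) = 1
  x2 <- 2 * atanh(exp(-1))
  r2 <- record_sample(c(10, x2))
  expect_equal(pivot_scale(1, r2), 1, tolerance = 1e-12)
  hc <- hier_constants(1, 1, r2)
  expect_equal(hc[["h2"]], 0.25, tolerance = 1e-12)
  # quadrature oracle for h2 at k = 10
  r <- rainfall(); k <- 10; cc <- 5; th <- 0.137
  h1 <- pivot_scale(th, r)
  quad <- stats::integrate(function(l)
    l^(k - 2) * (1 - (1 + cc * l) * exp(-cc * l)) * exp(-l * h1),
    0, Inf, rel.tol = 1e-12)$value / gamma(k - 1)
  expect_equal(hier_constants(th, cc, r)[["h2"]], quad, tolerance = 1e-9)
})

test_that("the printed theta-marginal variant has no interior mode on this data", {
  r <- rainfall()
  expect_warning(tp <- theta_map(r, "hierarchical", c = 5, form = "printed"),
                 "no interior mode")
  expect_true(is.na(tp))
  # while the integrated variant does, and the two differ pointwise
  g <- c(0.05, 0.1, 0.2)
  a <- log_marginal_posterior_theta(g, r, "hierarchical", form = "integrated")
  b <- log_marginal_posterior_theta(g, r, "hierarchical", form = "printed")
  expect_false(isTRUE(all.equal(diff(a), diff(b))))
})

test_that("noninformative priors factor as 1/theta and relate via sqrt(Q1)", {
  k <- 10
  pj1 <- noninformative_prior(1, 2, k, "jeffreys")
  pj2 <- noninformative_prior(2, 2, k, "jeffreys")
  expect_equal(pj2 * 2, pj1, tolerance = 1e-10)
  pr <- noninformative_prior(1, 2, k, "reference")
  q <- ehld_info_series(2, k)
  expect_equal(pj1 / pr, sqrt(q$Q1), tolerance = 1e-8)
  # positivity constraint holds but tightens with lambda:
  # [lambda Q2]^2/Q1 increases toward k, shrinking the radicand
  marg <- sapply(c(1, 5, 25, 125), function(l) {
    qq <- ehld_info_series(l, k); k - (l * qq$Q2)^2 / qq$Q1
  })
  expect_true(all(marg > 0))
  expect_true(all(diff(marg) < 0))
})
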