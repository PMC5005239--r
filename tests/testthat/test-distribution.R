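test_that("cdf matches its closed form, limits and a quadrature oracle", {
  # algebraic identity: e^{-x} = 1/3 gives ratio (2/3)/(4/3) = 1/2
  expect_equal(pehld(log(3), theta = 1, lambda = 1), 0.5, tolerance = 1e-12)
  # boundary behaviour
  expect_equal(pehld(1e-12, theta = 1, lambda = 2), 0, tolerance = 1e-10)
  expect_equal(pehld(1e4, theta = 1, lambda = 2), 1, tolerance = 1e-12)
  # monotone in x
  g <- seq(0.05, 12, length.out = 80)
  expect_true(all(diff(pehld(g, theta = 0.7, lambda = 3.2)) > 0))
  # quadrature oracle: integrate the density from 0 to x
  for (p in list(c(0.5, 3), c(1, 0.5), c(0.2, 8))) {
    q <- stats::integrate(function(t) dehld(t, p[1], p[2]), 0, 2,
                          rel.tol = 1e-10)$value
    expect_equal(pehld(2, p[1], p[2]), q, tolerance = 1e-8)
  }
  # matches the directly-coded textbook form
  expect_equal(pehld(g, 0.5, 3), cdf_direct(g, 0.5, 3), tolerance = 1e-12)
  expect_error(pehld(1, theta = -1, lambda = 2), "theta")
})

test_that("pdf normalizes, differentiates the cdf, and has the stated shape", {
  for (p in list(c(1, 0.5), c(1, 2), c(0.2, 8)))
    expect_equal(stats::integrate(function(t) dehld(t, p[1], p[2]), 0, Inf,
                                  rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  set.seed(11)
  xs <- runif(20, 0.1, 8)
  fd <- vapply(xs, function(x)
    num_deriv(function(t) pehld(t, 0.6, 2.5), x), numeric(1))
  expect_equal(dehld(xs, 0.6, 2.5), fd, tolerance = 1e-6)
  # decreasing for lambda <= 1, unimodal for lambda > 1
  g <- seq(0.01, 15, length.out = 400)
  expect_true(all(diff(dehld(g, 1, 0.8)) < 0))
  d <- dehld(g, 1, 3)
  peak <- which.max(d)
  expect_gt(peak, 1)
  expect_true(all(diff(d[1:peak]) > 0) && all(diff(d[peak:length(d)]) < 0))
  expect_equal(dehld(g, 0.5, 3), pdf_direct(g, 0.5, 3), tolerance = 1e-12)
})

test_that("quantile inverts the cdf", {
  expect_equal(qehld(0.5, 1, 1), log(3), tolerance = 1e-12)
  u <- seq(0.001, 0.999, length.out = 101)
  for (p in list(c(1, 1), c(0.156, 7.051), c(2, 0.4))) {
    expect_equal(pehld(qehld(u, p[1], p[2]), p[1], p[2]), u,
                 tolerance = 1e-9)
    x <- qehld(u, p[1], p[2])
    expect_equal(qehld(pehld(x, p[1], p[2]), p[1], p[2]), x,
                 tolerance = 1e-9)
  }
  # bisection oracle
  bis <- function(u, th, la) {
    lo <- 1e-12; hi <- 1e3
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pehld(mid, th, la) < u) lo <- mid else hi <- mid
    }
    mid
  }
  expect_equal(qehld(0.95, 0.156, 7.051), bis(0.95, 0.156, 7.051),
               tolerance = 1e-8)
  expect_error(qehld(1.2, 1, 1), "p")
})

test_that("record sampler produces exact lower records with the gamma pivot law", {
  r <- rehld_records(10, theta = 1, lambda = 2, seed = 5)
  expect_s3_class(r, "record_sample")
  expect_true(all(diff(r) < 0) && all(r > 0))
  # reproducible under seed, and seed does not disturb the caller's stream
  set.seed(1); before <- runif(1)
  r2 <- rehld_records(10, 1, 2, seed = 5)
  set.seed(1); expect_identical(runif(1), before)
  expect_identical(as.numeric(r), as.numeric(r2))

  # lambda * h1(true theta) ~ Gamma(k, 1): mean k, variance k, KS test
  k <- 10; lambda <- 2
  n <- 10000
  piv <- numeric(n)
  first <- numeric(n)
  set.seed(42)
  for (i in seq_len(n)) {
    x <- rehld_records(k, 1, lambda)
    piv[i] <- lambda * pivot_scale(1, x)
    first[i] <- x[1]
  }
  expect_lt(abs(mean(piv) - k), 3 * sqrt(k / n))
  expect_lt(abs(var(piv) - k) / k, 0.1)
  ks <- suppressWarnings(stats::ks.test(piv, "pgamma", shape = k, rate = 1))
  expect_gt(ks$p.value, 0.01)
  # the first record is an ordinary draw from the parent distribution
  ks1 <- suppressWarnings(stats::ks.test(first, function(q) pehld(q, 1, lambda)))
  expect_gt(ks1$p.value, 0.01)
  expect_error(rehld_records(0, 1, 1), "k")
})

test_that("pivot scale h1 is decreasing in theta with stable tails", {
  r <- rainfall()
  th <- exp(seq(log(1e-4), log(50), length.out = 60))
  h <- pivot_scale(th, r)
  expect_true(all(diff(h) < 0))
  expect_gt(pivot_scale(1e-12, r), 20)        # ~ log(2/(theta x_k))
  expect_equal(pivot_scale(1e-12, r, log = TRUE),
               log(log(2 / (1e-12 * 3.21))), tolerance = 1e-10)
  expect_equal(pivot_scale(500, r, log = TRUE), log(2) - 500 * 3.21,
               tolerance = 1e-8)
  # theta x_k with e^{-theta x_k} = 1/2 gives log 3
  th_half <- log(2) / 3.21
  expect_equal(pivot_scale(th_half, r), log(3), tolerance = 1e-12)
})
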