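test_that("pivotal state has the stated structure", {
  r <- rainfall()
  ps <- pivotal_state(0.2, r, lambda = 3)
  expect_true(all(diff(ps$z) > 0) && all(ps$z > 0))
  expect_true(all(ps$s > 0))
  expect_true(all(ps$u > 0 & ps$u < 1))
  expect_gt(ps$w, 0)
  # T_k = lambda * h1(theta)
  expect_equal(ps$t[length(r)], 3 * pivot_scale(0.2, r), tolerance = 1e-12)
  # W is invariant to the shape
  expect_equal(pivotal_state(0.2, r, lambda = 1)$w,
               pivotal_state(0.2, r, lambda = 7)$w, tolerance = 1e-10)
  expect_equal(w_statistic(0.2, r), ps$w, tolerance = 1e-10)
})

test_that("W(theta) is strictly increasing, 0 to Inf, on random samples", {
  set.seed(9)
  for (i in 1:25) {
    x <- rehld_records(8, runif(1, 0.5, 2), runif(1, 0.5, 6))
    th <- exp(seq(log(1e-5), log(100), length.out = 80))
    w <- w_statistic(th, x)
    expect_true(all(diff(w) > 0))
    expect_lt(w[1], w_statistic(1e-8, x) + w[40])  # small near 0
    expect_gt(w[80], w[40])
  }
})

test_that("W at the true scale is chi-squared with 2k - 2 df", {
  k <- 8
  n <- 10000
  w <- numeric(n)
  set.seed(123)
  for (i in seq_len(n)) w[i] <- w_statistic(1, rehld_records(k, 1, 2))
  expect_lt(abs(mean(w) - (2 * k - 2)), 3 * sd(w) / sqrt(n))
  ks <- suppressWarnings(stats::ks.test(w, "pchisq", df = 2 * k - 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("theta_pivotal solves its defining equation uniquely", {
  r <- rainfall()
  th <- theta_pivotal(r)
  expect_equal(as.numeric(th), 0.138, tolerance = 0.005)
  expect_lt(abs(w_statistic(as.numeric(th), r) - (2 * length(r) - 4)), 1e-8)
  expect_error(theta_pivotal(record_sample(c(3, 2))), "k >= 3")
  # plug-in shape estimate
  piv <- lambda_pivotal(r)
  expect_equal(piv$lambda, 5.897, tolerance = 0.005)
  expect_equal(piv$lambda,
               (length(r) - 1) / pivot_scale(as.numeric(th), r),
               tolerance = 1e-9)
})

test_that("theta_pivotal concentrates near the truth as k grows", {
  est <- function(k, n = 150) {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- theta_pivotal(rehld_records(k, 1, 2))
    out
  }
  set.seed(15)
  e10 <- est(10); e40 <- est(40)
  expect_lt(abs(median(e40) - 1), abs(median(e10) - 1) + 0.05)
  expect_lt(abs(median(e40) - 1), 0.2)
})

test_that("exact interval is exact in coverage and scales as 1/h1", {
  r <- rainfall()
  ci <- exact_ci_lambda(r, theta = 0.138, level = 0.95)
  expect_gt(ci["lower"], 0)
  expect_lt(ci["lower"], ci["upper"])
  # homogeneity: the interval is (chi-sq quantiles)/(2 h1)
  h1 <- pivot_scale(0.138, r)
  expect_equal(unname(ci["upper"] * 2 * h1),
               qchisq(0.975, 2 * length(r)), tolerance = 1e-10)
  # widening with level
  ci99 <- exact_ci_lambda(r, 0.138, 0.99)
  expect_lt(ci99["lower"], ci["lower"]); expect_gt(ci99["upper"], ci["upper"])
  # coverage at the true parameters
  n <- 4000; k <- 10; lambda <- 2
  set.seed(31)
  hit <- logical(n)
  for (i in seq_len(n)) {
    ci_i <- exact_ci_lambda(rehld_records(k, 1, lambda), theta = 1)
    hit[i] <- ci_i["lower"] < lambda && lambda < ci_i["upper"]
  }
  expect_lt(abs(mean(hit) - 0.95), 3 * sqrt(0.95 * 0.05 / n))
  expect_error(exact_ci_lambda(r, 0.138, level = 1.2), "level")
})

test_that("GPQ interval is seed-deterministic and covers like its nominal level", {
  r <- rainfall()
  g1 <- gpq_ci_lambda(r, n_draws = 2000, seed = 42)
  g2 <- gpq_ci_lambda(r, n_draws = 2000, seed = 42)
  expect_identical(g1$interval, g2$interval)
  expect_gt(g1$interval[1], 0)
  # solve_w_equation residuals are tiny on every draw
  set.seed(6)
  w_targets <- rchisq(500, 2 * (length(r) - 1))
  th <- ehldrec:::solve_w_equation(w_targets, r)
  expect_lt(max(abs(w_statistic(th, r) - w_targets)), 1e-8)
  # small-sample coverage, modest n to stay fast
  n <- 400; k <- 6; lambda <- 2
  set.seed(8)
  hit <- logical(n)
  for (i in seq_len(n)) {
    g <- gpq_ci_lambda(rehld_records(k, 1, lambda), n_draws = 1000)
    hit[i] <- g$interval[1] < lambda && lambda < g$interval[2]
  }
  expect_lt(abs(mean(hit) - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})
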