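test_that("time series prefix sums recover arbitrary segment sums", {
  set.seed(1)
  y <- rnorm(30)
  ts <- time_series(y)
  expect_equal(ts$prefix_sum[1], 0)
  expect_equal(ts$prefix_sumsq[1], 0)
  for (s in c(0, 3, 17)) {
    for (t in c(s + 1, 20, 30)) {
      if (t <= s) next
      expect_equal(ts$prefix_sum[t + 1] - ts$prefix_sum[s + 1],
                   sum(y[(s + 1):t]))
    }
  }
  expect_true(all(diff(ts$prefix_sumsq) >= 0))
  expect_error(time_series(c(1, NA)), "non-finite")
  expect_error(time_series(numeric(0)), "non-empty")
})

test_that("pointwise losses match their closed forms", {
  g <- cost_model("gaussian")
  expect_equal(pointwise_cost(g, 0, 0), 0)
  expect_equal(pointwise_cost(g, 3, 1), 2)
  g2 <- cost_model("gaussian", sigma = 2)
  expect_equal(pointwise_cost(g2, 3, 1), 0.5)
  p <- cost_model("poisson")
  expect_equal(pointwise_cost(p, 2, 2), 2 - 2 * log(2))
  expect_error(pointwise_cost(p, 2, -1), "domain")
  expect_error(pointwise_cost(p, 2, 0), "domain")
})

test_that("segment cost equals the numeric minimum of the pointwise sum", {
  set.seed(42)
  for (model in list(cost_model("gaussian"), cost_model("poisson"))) {
    for (rep in 1:50) {
      n <- sample(2:50, 1)
      y <- if (model$family == "gaussian") rnorm(n, sd = 2) else rpois(n, 4)
      ts <- time_series(y)
      s <- sample1(0:(n - 1))
      t <- sample1((s + 1):n)
      closed <- segment_cost(model, ts, s, t)
      numeric <- numeric_segment_cost(model, y[(s + 1):t])
      expect_equal(closed, numeric, tolerance = 1e-8)
    }
  }
})

test_that("explicit segment cost values and edge cases", {
  g <- cost_model("gaussian")
  expect_equal(segment_cost(g, c(1, 2, 3), 0, 3), 1.0)
  expect_equal(segment_cost(g, toy_step, 0, 6), 75.0)
  expect_equal(segment_cost(g, c(5.5), 0, 1), 0)        # single point
  expect_equal(segment_cost(g, rep(3.7, 12), 0, 12), 0) # constant series
  expect_error(segment_cost(g, toy_step, 3, 3), "indices")
  expect_error(segment_cost(g, toy_step, 4, 2), "indices")
  # all-zero Poisson segment costs 0 in the mu -> 0+ limit
  p <- cost_model("poisson")
  expect_equal(segment_cost(p, c(0, 0, 0), 0, 3), 0)
  expect_error(segment_cost(p, c(-1, 2), 0, 2), "non-negative")
})

test_that("subadditivity across any split holds with kappa = 0", {
  set.seed(99)
  for (model in list(cost_model("gaussian"), cost_model("poisson"))) {
    for (rep in 1:10) {
      n <- sample(4:20, 1)
      y <- if (model$family == "gaussian") rnorm(n) else rpois(n, 3)
      ts <- time_series(y)
      for (s in 0:(n - 2)) {
        for (t in (s + 1):(n - 1)) {
          lhs <- segment_cost(model, ts, s, t) + segment_cost(model, ts, t, n)
          expect_lte(lhs, segment_cost(model, ts, s, n) + 1e-9)
        }
      }
    }
  }
})
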