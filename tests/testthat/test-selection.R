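test_that("MAD noise estimate is consistent, scale-equivariant, shift-invariant", {
  spec <- signal_spec(n = 10000, changepoints = c(2000, 5000, 8000),
                      means = c(0, 4, -2, 1), sigma = 1, seed = 123)
  y <- generate_signal(spec)
  s1 <- mad_standardise(y)$sigma_hat
  expect_gt(s1, 0.95)
  expect_lt(s1, 1.05)
  expect_equal(mad_standardise(7 * y)$sigma_hat, 7 * s1, tolerance = 1e-12)
  expect_equal(mad_standardise(y + 100)$sigma_hat, s1, tolerance = 1e-12)
  expect_error(mad_standardise(rep(1, 50)), "degenerate")
  expect_error(mad_standardise(3.2), "at least 2")
})

test_that("penalty construction covers log-n, linear-n and explicit forms", {
  expect_equal(penalty_value(100), 2 * log(100))
  expect_equal(penalty_value(100, constant = 3), 3 * log(100))
  expect_equal(penalty_value(50, "const_times_n", 0.1), 5)
  expect_equal(penalty_value(50, "explicit", 7.5), 7.5)
  expect_error(penalty_value(10, constant = -1))
})

test_that("model selection over k matches the penalised solver", {
  fit <- segment_neighbourhood(toy_step, K = 3)
  expect_identical(select_k(fit, penalty = 1), 1L)       # toy series: one change
  expect_identical(select_k(fit, penalty = 1e6), 0L)     # huge penalty
  expect_identical(select_k(fit, penalty = 0), 1L)       # ties to smallest k
  expect_identical(select_k(fit, penalty = function(k, n) k), 1L)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(40:150, 1)
    y <- random_series(n, p_change = 0.04)
    fit <- segment_neighbourhood(y, K = 10)
    beta <- 2 * log(n)
    khat <- select_k(fit, beta)
    expect_identical(khat, length(fpop(y, beta)$changepoints))
  }
})

test_that("select_k with no penalty picks the smallest cost-attaining k", {
  C_final <- c(5, 1, 1, 1)
  expect_identical(select_k(C_final, penalty = 0), 1L)
})

test_that("verify_dominance accepts identical traces and rejects mismatches", {
  y <- random_series(60)
  fp <- fpop(y, 2 * log(60), trace_sets = TRUE)
  expect_true(verify_dominance(fp, fp))
  expect_error(verify_dominance(fp$sets, fp$sets[1:10]), "different lengths")
  expect_error(verify_dominance(fpop(y, 1), fp), "trace")
})

test_that("averaged candidate counts show functional pruning dominating", {
  spec <- signal_spec(seed = 42)
  counts <- candidate_count_experiment(spec, replicates = 25, K = 3)
  wide <- split(counts, counts$solver)
  expect_equal(wide$op$mean_count, as.numeric(1:100))
  # pointwise: mean fpop count <= mean pelt count <= unpruned count
  expect_true(all(wide$fpop$mean_count <= wide$pelt$mean_count + 1e-12))
  expect_true(all(wide$pelt$mean_count <= wide$op$mean_count + 1e-12))
  expect_lt(max(wide$fpop$mean_count), max(wide$pelt$mean_count))
  # constrained solvers, per k
  for (k in 1:3) {
    pd <- counts[counts$solver == "pdpa" & counts$k == k, ]
    sp <- counts[counts$solver == "snip" & counts$k == k, ]
    expect_true(all(pd$mean_count <= sp$mean_count + 1e-12))
  }
})
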