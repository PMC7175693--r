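test_that("the toy step series is split at its jump by every solver", {
  for (solver in list(optimal_partitioning, pelt, fpop)) {
    fit <- solver(toy_step, beta = 1)
    expect_identical(fit$changepoints, 3L)
    expect_equal(fit$F[7], 1)
    expect_equal(fit$F[1], -1)  # F(0) = -beta
  }
})

test_that("a constant series yields no changepoints at any positive beta", {
  y <- rep(2.5, 20)
  for (beta in c(0.1, 1, 10)) {
    fit <- fpop(y, beta)
    expect_identical(fit$changepoints, integer(0))
    expect_equal(fit$F[21], 0)
  }
})

test_that("all penalised solvers match exhaustive enumeration on small series", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    y <- random_series(n)
    beta <- sample(c(0.5, 1, 2 * log(n)), 1)
    oracle <- brute_force_penalised(y, beta)
    for (solver in list(optimal_partitioning, pelt, fpop)) {
      fit <- solver(y, beta)
      expect_equal(fit$F[n + 1], oracle$F_n, tolerance = 1e-8)
      expect_identical(fit$changepoints, oracle$changepoints)
    }
    # and the R engines agree with the compiled ones
    expect_equal(fpop(y, beta, engine = "r")$F,
                 fpop(y, beta, engine = "cpp")$F, tolerance = 1e-10)
    expect_identical(pelt(y, beta, engine = "r")$candidate_counts,
                     pelt(y, beta, engine = "cpp")$candidate_counts)
  }
})

test_that("PELT and FPOP reproduce Optimal Partitioning at larger n", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 200
    y <- random_series(n)
    beta <- runif(1, 1, 3) * log(n)
    op <- optimal_partitioning(y, beta)
    pe <- pelt(y, beta)
    fp <- fpop(y, beta)
    expect_equal(pe$F, op$F, tolerance = 1e-10)
    expect_equal(fp$F, op$F, tolerance = 1e-8 * n)
    expect_identical(pe$changepoints, op$changepoints)
    expect_identical(fp$changepoints, op$changepoints)
    expect_true(all(pe$candidate_counts <= op$candidate_counts))
    expect_true(all(fp$candidate_counts <= pe$candidate_counts))
  }
})

test_that("functional pruning discards every inequality-pruned candidate", {
  set.seed(55)
  for (rep in 1:10) {
    y <- random_series(150)
    beta <- 2 * log(150)
    fp <- fpop(y, beta, trace_sets = TRUE)
    pe <- pelt(y, beta, trace_sets = TRUE)
    expect_true(verify_dominance(fp, pe))
    for (t in seq_along(fp$sets))
      expect_true(all(fp$sets[[t]] %in% pe$sets[[t]]))
  }
})

test_that("the number of changepoints is non-increasing in beta", {
  set.seed(77)
  y <- random_series(300, p_change = 0.05)
  betas <- c(0.2, 0.5, 1, 2, 4, 8, 16, 32)
  ncps <- vapply(betas, function(b) length(fpop(y, b)$changepoints),
                 numeric(1))
  expect_true(all(diff(ncps) <= 0))
})

test_that("backtracking validates its backpointers", {
  expect_identical(backtrack_changepoints(c(0L, 0L, 0L)), integer(0))
  expect_identical(backtrack_changepoints(c(0L, 0L, 0L, 3L, 3L, 3L)), 3L)
  expect_error(backtrack_changepoints(c(0L, 2L)), "corrupt")
  expect_error(optimal_partitioning(toy_step, beta = -1), "non-negative")
})
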