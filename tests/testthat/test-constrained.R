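test_that("toy step series: constrained costs and segmentations", {
  for (solver in list(segment_neighbourhood, snip, pdpa)) {
    fit <- solver(toy_step, K = 2)
    expect_equal(unname(fit$C[1, 7]), 75)   # k = 0: one segment
    expect_equal(unname(fit$C[2, 7]), 0)    # k = 1: split at the jump
    expect_identical(fit$segmentations[[1]], 3L)
  }
  const <- segment_neighbourhood(rep(1.5, 10), K = 3)
  expect_equal(unname(const$C[, 11]), rep(0, 4))
})

test_that("constrained solvers match exhaustive enumeration on small series", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(5:10, 1)
    y <- random_series(n)
    K <- 3
    fits <- list(segment_neighbourhood(y, K), snip(y, K), pdpa(y, K))
    for (k in 1:K) {
      oracle <- brute_force_constrained(y, k)
      for (fit in fits) {
        expect_equal(unname(fit$C[k + 1, n + 1]), oracle$C_kn,
                     tolerance = 1e-8)
        expect_identical(fit$segmentations[[k]], oracle$changepoints)
      }
    }
  }
})

test_that("SNIP and pDPA reproduce Segment Neighbourhood at larger n", {
  set.seed(61)
  for (rep in 1:6) {
    n <- 400
    y <- random_series(n)
    K <- 5
    sn <- segment_neighbourhood(y, K)
    sp <- snip(y, K)
    pd <- pdpa(y, K)
    expect_equal(sp$C, sn$C, tolerance = 1e-10)
    expect_equal(pd$C, sn$C, tolerance = 1e-8)
    expect_identical(sp$segmentations, sn$segmentations)
    expect_identical(pd$segmentations, sn$segmentations)
    # pruning only removes candidates
    expect_true(all(sp$candidate_counts <= sn$candidate_counts, na.rm = TRUE))
    expect_true(all(pd$candidate_counts <= sp$candidate_counts, na.rm = TRUE))
    # R engines agree with the compiled path
    if (rep == 1) {
      expect_equal(pdpa(y, K, engine = "r")$C, pd$C, tolerance = 1e-8)
      expect_identical(snip(y, K, engine = "r")$candidate_counts,
                       sp$candidate_counts)
    }
  }
})

test_that("per-(k,t) functional sets are inside the inequality sets", {
  set.seed(83)
  for (rep in 1:5) {
    y <- random_series(120)
    K <- 4
    pd <- pdpa(y, K, trace_sets = TRUE)
    sp <- snip(y, K, trace_sets = TRUE)
    expect_true(verify_dominance(pd, sp))
    dd <- constrained_dominance(y, K)
    expect_true(dd$ok)
    expect_lt(dd$max_c_diff, 1e-8)
  }
})

test_that("optimal cost is non-increasing in the number of changes", {
  set.seed(19)
  y <- random_series(150)
  fit <- segment_neighbourhood(y, K = 8)
  expect_true(all(diff(fit$C[, 151]) <= 1e-12))
})

test_that("penalised and constrained optima satisfy the linear-penalty identity", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(50:200, 1)
    y <- random_series(n, p_change = 0.03)
    K <- 12
    fit <- segment_neighbourhood(y, K)
    for (beta in c(log(n), 2 * log(n))) {
      lhs <- min(fit$C[, n + 1] + beta * (0:K))
      rhs <- fpop(y, beta)$F[n + 1]
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("recovered segmentations re-score to their stated cost", {
  set.seed(29)
  y <- random_series(80)
  fit <- pdpa(y, K = 4)
  g <- cost_model("gaussian")
  for (k in 1:4) {
    cps <- fit$segmentations[[k]]
    expect_length(cps, k)
    expect_true(all(diff(cps) > 0))
    expect_equal(rescore(g, y, cps), unname(fit$C[k + 1, 81]),
                 tolerance = 1e-8)
  }
  expect_error(backtrack_constrained(fit$backpointers, 9), "1..K")
  expect_error(segment_neighbourhood(y, K = 80), "n - 1")
})
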