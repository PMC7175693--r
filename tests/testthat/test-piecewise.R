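test_that("absorbing observations updates the quadratic coefficients", {
  g <- cost_model("gaussian")
  cand <- candidate_cost(g, tau = 0, init_value = 5)
  cand <- add_observation(cand, 2)
  expect_equal(unname(cand$coef), c(0.5, -2, 7))
  # adding y then evaluating at mu = y adds nothing at that mu
  before <- candidate_cost(g, 0, init_value = 1.5)
  for (y in c(-1, 0.3, 2)) {
    after <- add_observation(before, y)
    expect_equal(evaluate_candidate(after, y), evaluate_candidate(before, y))
    before <- after
  }
})

test_that("candidate minimum is the vertex / sample mean", {
  g <- cost_model("gaussian")
  cand <- candidate_cost(g, 0, init_value = 5)
  cand <- add_observation(cand, 2)
  m <- candidate_minimum(cand)
  expect_equal(m$mu_hat, 2)
  expect_equal(m$value, 5)
  expect_equal(candidate_minimum(candidate_cost(g, 0, init_value = 3))$value, 3)
  # after absorbing y1..ym into a constant, the minimiser is the sample mean
  set.seed(5)
  for (model in list(g, cost_model("poisson"))) {
    ys <- if (model$family == "gaussian") rnorm(7) else rpois(7, 5) + 1
    cand <- candidate_cost(model, 0, init_value = 2.25)
    for (y in ys) cand <- add_observation(cand, y)
    m <- candidate_minimum(cand)
    expect_equal(m$mu_hat, mean(ys), tolerance = 1e-10)
    grid <- seq(max(1e-6, mean(ys) - 2), mean(ys) + 2, length.out = 20001)
    expect_equal(m$value, min(evaluate_candidate(cand, grid)), tolerance = 1e-6)
  }
})

test_that("gaussian level sets are the root intervals", {
  g <- cost_model("gaussian")
  # mu^2: two observations at 0 give coef (1, 0, 0)
  cand <- candidate_cost(g, 0, 0)
  cand <- add_observation(add_observation(cand, 0), 0)
  expect_equal(unname(cand$coef), c(1, 0, 0))
  ls <- level_set(cand, 1)
  expect_equal(unclass(ls)[1, ], c(-1, 1))
  # shifted above the threshold: empty
  cand2 <- cand; cand2$coef["c"] <- 2
  expect_true(interval_is_empty(level_set(cand2, 1)))
  # endpoints sit on the threshold
  set.seed(8)
  for (rep in 1:20) {
    cand <- candidate_cost(g, 0, runif(1, -2, 2))
    for (y in rnorm(sample(1:6, 1))) cand <- add_observation(cand, y)
    thr <- candidate_minimum(cand)$value + runif(1, 0.01, 3)
    ls <- level_set(cand, thr)
    expect_false(interval_is_empty(ls))
    for (e in as.numeric(unclass(ls))) {
      expect_lt(abs(evaluate_candidate(cand, e) - thr), 1e-6 * (1 + abs(thr)))
    }
  }
})

test_that("poisson level sets agree with a bisection-refined oracle", {
  p <- cost_model("poisson")
  set.seed(3)
  for (rep in 1:20) {
    cand <- candidate_cost(p, 0, runif(1, -1, 1))
    for (y in rpois(sample(2:6, 1), 4)) cand <- add_observation(cand, y)
    mv <- candidate_minimum(cand)
    thr <- mv$value + runif(1, 0.05, 2)
    ls <- level_set(cand, thr)
    expect_false(interval_is_empty(ls))
    lo <- ls[1, 1]; hi <- ls[1, 2]
    # independent root refinement with uniroot on each monotone side
    f <- function(mu) evaluate_candidate(cand, mu) - thr
    if (cand$coef[["s"]] > 0) {
      left <- stats::uniroot(f, c(1e-12, mv$mu_hat), tol = 1e-12)$root
      expect_equal(lo, left, tolerance = 1e-8)
    }
    right <- stats::uniroot(f, c(max(mv$mu_hat, 1e-10), mv$mu_hat + 1e3),
                            tol = 1e-12)$root
    expect_equal(hi, right, tolerance = 1e-8)
  }
})

test_that("interval algebra matches a grid membership oracle", {
  expect_equal(unclass(interval_intersect(interval_set(-1, 1),
                                          interval_set(0, 2)))[1, ],
               c(0, 1))
  expect_true(interval_is_empty(interval_intersect(interval_set(-1, 1),
                                                   interval_set(2, 3))))
  expect_equal(nrow(interval_complement_union(list(), c(-Inf, Inf))), 1)
  set.seed(11)
  grid <- seq(-5, 5, by = 0.01)
  for (rep in 1:25) {
    mk <- function() {
      k <- sample(0:3, 1)
      if (k == 0) return(interval_set())
      lo <- sort(runif(k, -5, 5)); hi <- lo + runif(k, 0, 2)
      interval_set(lo, hi)
    }
    a <- mk(); b <- mk()
    got <- grid_membership(interval_intersect(a, b), grid)
    want <- grid_membership(a, grid) & grid_membership(b, grid)
    expect_identical(got, want)
    sets <- list(mk(), mk(), mk())
    comp <- interval_complement_union(sets, c(-6, 6))
    inside_any <- Reduce(`|`, lapply(sets, grid_membership, grid = grid))
    # away from boundary points (closed-set convention), complement flips
    bnd <- unlist(lapply(sets, function(s) as.numeric(unclass(s))))
    off_bnd <- sapply(grid, function(x) all(abs(x - bnd) > 1e-9)) |
      !length(bnd)
    expect_identical(grid_membership(comp, grid)[off_bnd],
                     (!inside_any)[off_bnd])
  }
})

test_that("a union covering the domain leaves the new candidate no room", {
  covered <- interval_complement_union(
    list(interval_set(-10, 0), interval_set(-1, 12)), c(-10, 12))
  expect_true(interval_is_empty(covered))
})

test_that("live candidate sets partition the domain and certify optimality", {
  # run the R functional-pruning engine and inspect its candidate state by
  # replaying it: at each step the kept sets must tile the domain and each
  # candidate must be pointwise-minimal on its own set
  set.seed(21)
  y <- random_series(40)
  beta <- 2 * log(40)
  g <- cost_model("gaussian")
  F <- c(-beta, rep(NA_real_, 40))
  cands <- list(candidate_cost(g, 0L, 0))
  for (t in 1:40) {
    cands <- lapply(cands, add_observation, y = y[t])
    mins <- vapply(cands, function(cd) candidate_minimum(cd)$value, numeric(1))
    F[t + 1] <- min(mins)
    thr <- F[t + 1] + beta
    Is <- lapply(cands, level_set, threshold = thr)
    for (j in seq_along(cands))
      cands[[j]]$set <- interval_intersect(cands[[j]]$set, Is[[j]])
    cands <- cands[!vapply(cands, function(cd) interval_is_empty(cd$set),
                           logical(1))]
    ns <- interval_complement_union(Is, g$domain)
    if (!interval_is_empty(ns))
      cands <- c(cands, list(candidate_cost(g, t, thr, set = ns)))
    # partition: total width of pairwise intersections is 0, union covers R
    ivs <- do.call(rbind, lapply(cands, function(cd) unclass(cd$set)))
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    expect_true(all(ivs[-1, 1] - ivs[-nrow(ivs), 2] >= -1e-9))
    expect_identical(ivs[1, 1], -Inf)
    expect_identical(ivs[nrow(ivs), 2], Inf)
    # pointwise optimality of each candidate on (samples of) its own set
    for (cd in cands) {
      iv <- unclass(cd$set)
      mus <- as.numeric(iv[is.finite(iv)])
      # interior points of each piece (finite pieces only)
      fin <- iv[, 1] > -Inf & iv[, 2] < Inf
      if (any(fin))
        mus <- c(mus, stats::runif(sum(fin), iv[fin, 1], iv[fin, 2]))
      for (mu in mus) {
        v <- evaluate_candidate(cd, mu)
        for (other in cands)
          expect_lte(v, evaluate_candidate(other, mu) + 1e-7 * (1 + abs(v)))
      }
    }
  }
})
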