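# Shared fixtures and independent numeric oracles for the solver tests.

toy_step <- c(0, 0, 0, 10, 10, 10)

# minimise the summed pointwise loss over mu numerically; independent of the
# closed-form prefix-sum segment costs it is used to check
numeric_segment_cost <- function(model, y) {
  f <- function(mu) sum(pointwise_cost(model, y, mu))
  if (model$family == "gaussian") {
    rng <- range(y)
    span <- max(1, diff(rng))
    stats::optimize(f, lower = rng[1] - span, upper = rng[2] + span,
                    tol = 1e-10)$objective
  } else {
    up <- max(mean(y), max(y), 1) * 3 + 1
    stats::optimize(f, lower = 1e-12, upper = up, tol = 1e-12)$objective
  }
}

# random piecewise-constant Gaussian series with a few shifts
random_series <- function(n, shift = 3, p_change = 0.15) {
  state <- cumsum(stats::runif(n) < p_change) %% 2
  state * shift + stats::rnorm(n)
}

# total cost of a given changepoint vector, scored segment by segment
rescore <- function(model, y, cps) {
  ts <- time_series(y)
  bounds <- c(0L, as.integer(cps), ts$n)
  sum(vapply(seq_len(length(bounds) - 1L), function(j) {
    segment_cost(model, ts, bounds[j], bounds[j + 1L])
  }, numeric(1)))
}

# draw one element from a vector, safe for length-1 vectors
sample1 <- function(v) v[sample.int(length(v), 1L)]

# grid membership oracle for interval-set algebra
grid_membership <- function(set, grid) {
  if (interval_is_empty(set)) return(rep(FALSE, length(grid)))
  sapply(grid, function(x) any(set[, 1] <= x & x <= set[, 2]))
}
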