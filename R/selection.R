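#' Robust MAD standardisation of a signal
#'
#' Estimates the noise standard deviation from the median absolute first
#' difference, `sigma_hat = median(|y[i+1] - y[i]|) / (sqrt(2) * qnorm(0.75))`,
#' and returns the signal divided by it. Differencing removes the
#' piecewise-constant mean everywhere except at the (few) changepoints, and
#' the median is insensitive to those, so the estimate is consistent for the
#' noise s.d. of Gaussian data regardless of the segmentation. Standardising
#' first is what makes unit-variance costs and log(n)-scale penalties
#' comparable across signals.
#'
#' @param series numeric vector or [time_series()], length at least 2.
#' @return list with `values` (the standardised signal), `sigma_hat`, and
#'   `series` (the standardised [time_series()]).
#' @examples
#' y <- generate_signal(signal_spec(seed = 1, sigma = 3))
#' mad_standardise(y)$sigma_hat  # close to 3
#' @export
mad_standardise <- function(series) {
  series <- time_series(series)
  if (series$n < 2L) stop("need at least 2 observations", call. = FALSE)
  d <- abs(diff(series$values))
  sigma_hat <- stats::median(d) / (sqrt(2) * stats::qnorm(0.75))
  if (sigma_hat <= 0)
    stop("degenerate signal: median absolute difference is zero",
         call. = FALSE)
  values <- series$values / sigma_hat
  list(values = values, sigma_hat = sigma_hat, series = time_series(values))
}

#' Penalty per changepoint
#'
#' Builds the linear-in-k penalty constant `beta` for the penalised problem.
#' The default `2 * log(n)` on a MAD-standardised signal is a robust
#' general-purpose choice; `const_times_n` supports penalties proportional
#' to the series length (as used when a per-point rate `lambda` is tuned
#' externally), and `explicit` passes `constant` through unchanged.
#'
#' @param n series length.
#' @param form `"const_times_logn"`, `"const_times_n"` or `"explicit"`.
#' @param constant multiplier (or the value itself for `"explicit"`).
#' @return a single non-negative number.
#' @examples
#' penalty_value(100)                      # 2 log(100)
#' penalty_value(100, constant = 3)        # 3 log(100)
#' penalty_value(100, "explicit", 7.5)     # 7.5
#' @export
penalty_value <- function(n, form = c("const_times_logn", "const_times_n",
                                      "explicit"),
                          constant = 2) {
  form <- match.arg(form)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(constant), length(constant) == 1L, constant >= 0)
  beta <- switch(form,
    const_times_logn = constant * log(n),
    const_times_n = constant * n,
    explicit = constant)
  if (beta < 0) stop("penalty must be non-negative", call. = FALSE)
  beta
}

#' Select the number of changepoints from a constrained fit
#'
#' Minimises `C[k, n] + f(k, n)` over `k = 0..K`. With a linear penalty
#' `f(k, n) = beta * k` this reproduces the penalised problem's optimal
#' number of changes for the same `beta`.
#'
#' @param C_final numeric vector of optimal costs `C[k, n]`, `k = 0..K`
#'   (e.g. `fit$C[, n + 1]`), or a `"constrained_fit"`.
#' @param penalty either a single number `beta` (linear penalty) or a
#'   function `f(k, n)`.
#' @param n series length (required when `penalty` is a function and
#'   `C_final` is a bare vector; taken from the fit otherwise).
#' @return the selected number of changepoints (ties to the smallest `k`).
#' @examples
#' fit <- segment_neighbourhood(c(0, 0, 0, 10, 10, 10), K = 3)
#' select_k(fit, penalty = 1)  # 1
#' @export
select_k <- function(C_final, penalty, n = NULL) {
  if (inherits(C_final, "constrained_fit")) {
    n <- C_final$n
    C_final <- C_final$C[, n + 1L]
  }
  ks <- seq_along(C_final) - 1L
  pen <- if (is.function(penalty)) {
    if (is.null(n)) stop("'n' required with a penalty function", call. = FALSE)
    vapply(ks, penalty, numeric(1), n)
  } else {
    penalty * ks
  }
  crit <- C_final + pen
  ks[which.min(crit)]
}

#' Verify functional-over-inequality pruning dominance
#'
#' Checks that at every step the candidate set kept by a functional-pruning
#' solver is a subset of the one kept by the corresponding inequality-based
#' solver on the same input: any candidate discarded by the cost inequality
#' is also discarded, at the same time, by the level-set test. Accepts the
#' `sets` traces of two penalised fits (lists of integer vectors, see
#' [fpop()] / [pelt()] with `trace_sets = TRUE`) or two constrained traces
#' (lists over `k` of lists over `t`, see [pdpa()] / [snip()]).
#'
#' @param functional,inequality traces, or fits carrying a `sets` element.
#' @return `TRUE` if the subset relation holds everywhere, else `FALSE`.
#' @export
verify_dominance <- function(functional, inequality) {
  get_sets <- function(x) {
    if (inherits(x, "penalised_fit") || inherits(x, "constrained_fit")) {
      if (is.null(x$sets))
        stop("fit has no candidate-set trace; rerun with trace_sets = TRUE",
             call. = FALSE)
      x$sets
    } else x
  }
  a <- get_sets(functional)
  b <- get_sets(inequality)
  if (length(a) != length(b))
    stop("traces have different lengths; were the solvers run on the same ",
         "input and settings?", call. = FALSE)
  flat_ok <- function(u, v) {
    if (is.list(u) || is.list(v)) {
      if (!is.list(u) || !is.list(v) || length(u) != length(v))
        stop("mismatched trace structure", call. = FALSE)
      return(all(mapply(flat_ok, u, v)))
    }
    all(u %in% v)
  }
  isTRUE(flat_ok(a, b))
}

#' Lock-step dominance check for the constrained solvers
#'
#' Runs pDPA and SNIP side by side over every `(k, t)` cell (Gaussian
#' family, compiled path) and verifies the subset relation on the fly, so
#' that no full candidate-set trace needs to be stored. Suitable for long
#' series where SNIP's unpruned low-`k` rows would make a stored trace
#' enormous.
#'
#' @param series numeric vector or [time_series()].
#' @param K maximum number of changepoints.
#' @param kappa the C2 constant for the inequality rule.
#' @return list with `ok` (logical), `max_c_diff` (largest discrepancy
#'   between the two solvers' optimal costs, a numerical-agreement
#'   diagnostic), and the per-(k, t) candidate-count matrices
#'   `counts_functional`, `counts_inequality`.
#' @export
constrained_dominance <- function(series, K, kappa = 0) {
  series <- time_series(series)
  check_constrained_args(series, cost_model("gaussian"), K)
  .constrained_dominance_gauss(series$values, as.integer(K), kappa)
}

#' Mean candidate-set size over replicated signals
#'
#' Replays the pruning diagnostics experiment: simulate many
#' piecewise-constant Gaussian signals from one [signal_spec()] design and
#' record, at every time step, how many candidate last changepoints each
#' solver still holds, averaged over replicates. For the penalised problem
#' the solvers compared are FPOP (functional pruning) and PELT (inequality
#' pruning), with the unpruned count `t` as reference; for the constrained
#' problem, pDPA and SNIP at each `k`.
#'
#' @param spec a [signal_spec()]; its `seed` seeds replicate `r` as
#'   `seed + r`.
#' @param replicates number of simulated series.
#' @param beta penalty for the penalised solvers (default `2 log n`).
#' @param K if non-`NULL`, also run the constrained solvers up to `K`.
#' @return a data.frame with columns `step`, `solver`, `k` (`NA` for the
#'   penalised solvers) and `mean_count`.
#' @examples
#' counts <- candidate_count_experiment(signal_spec(seed = 7), replicates = 10)
#' aggregate(mean_count ~ solver, counts, max)
#' @export
candidate_count_experiment <- function(spec, replicates = 1000,
                                       beta = penalty_value(spec$n),
                                       K = NULL) {
  stopifnot(inherits(spec, "signal_spec"), replicates >= 1)
  n <- spec$n
  fpop_tot <- numeric(n)
  pelt_tot <- numeric(n)
  pdpa_tot <- if (!is.null(K)) matrix(0, K, n) else NULL
  snip_tot <- if (!is.null(K)) matrix(0, K, n) else NULL
  for (r in seq_len(replicates)) {
    sp <- spec; sp$seed <- spec$seed + r
    y <- generate_signal(sp)
    fpop_tot <- fpop_tot + fpop(y, beta)$candidate_counts
    pelt_tot <- pelt_tot + pelt(y, beta)$candidate_counts
    if (!is.null(K)) {
      dom <- constrained_dominance(y, K)
      cf <- dom$counts_functional[-1L, -1L, drop = FALSE]
      ci <- dom$counts_inequality[-1L, -1L, drop = FALSE]
      cf[is.na(cf)] <- 0; ci[is.na(ci)] <- 0
      pdpa_tot <- pdpa_tot + cf
      snip_tot <- snip_tot + ci
    }
  }
  out <- rbind(
    data.frame(step = seq_len(n), solver = "fpop", k = NA_integer_,
               mean_count = fpop_tot / replicates),
    data.frame(step = seq_len(n), solver = "pelt", k = NA_integer_,
               mean_count = pelt_tot / replicates),
    data.frame(step = seq_len(n), solver = "op", k = NA_integer_,
               mean_count = as.numeric(seq_len(n)))
  )
  if (!is.null(K)) {
    for (k in seq_len(K)) {
      steps <- (k + 1L):n
      out <- rbind(out,
        data.frame(step = steps, solver = "pdpa", k = k,
                   mean_count = pdpa_tot[k, steps] / replicates),
        data.frame(step = steps, solver = "snip", k = k,
                   mean_count = snip_tot[k, steps] / replicates))
    }
  }
  rownames(out) <- NULL
  out
}
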