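#' @useDynLib fpseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_penalised_fit <- function(method, F, last_change, counts, beta, sets,
                              model, n) {
  structure(list(
    method = method,
    F = F,
    last_change = as.integer(last_change),
    changepoints = backtrack_changepoints(last_change),
    candidate_counts = as.integer(counts),
    beta = beta,
    sets = sets,
    family = model$family,
    n = n
  ), class = "penalised_fit")
}

#' @export
print.penalised_fit <- function(x, ...) {
  cat("<penalised_fit> method =", x$method, " family =", x$family,
      " n =", x$n, " beta =", signif(x$beta, 6), "\n")
  cat("  F(n) =", format(x$F[x$n + 1], digits = 10), "\n")
  cat("  changepoints (", length(x$changepoints), "): ",
      paste(utils::head(x$changepoints, 12L), collapse = ", "),
      if (length(x$changepoints) > 12L) ", ..." else "", "\n", sep = "")
  cat("  candidate set size: max", max(x$candidate_counts),
      " mean", signif(mean(x$candidate_counts), 4), "\n")
  invisible(x)
}

check_penalised_args <- function(series, model, beta) {
  if (!inherits(model, "cost_model"))
    stop("'model' must be a cost_model", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a single non-negative number", call. = FALSE)
  if (model$family == "poisson" && any(series$values < 0))
    stop("Poisson loss requires non-negative data", call. = FALSE)
}

# scale data so the C++ unit-variance kernel computes cost / (2 sigma^2)
scaled_values <- function(series, model) {
  if (model$sigma == 1) series$values else series$values / model$sigma
}

#' Optimal Partitioning: exact penalised segmentation without pruning
#'
#' Solves the penalised minimisation problem: minimise the total segment
#' cost plus a penalty `beta` per changepoint, via the O(n^2) dynamic
#' programming recursion over the position of the last changepoint,
#' `F(t) = min_{0 <= tau < t} F(tau) + C(y[(tau+1):t]) + beta`, with
#' `F(0) = -beta`.
#'
#' @param series numeric vector or [time_series()].
#' @param beta non-negative penalty per changepoint (e.g. `penalty_value(n)`).
#' @param model a [cost_model()]; default Gaussian change in mean.
#' @param engine `"auto"` (C++ for Gaussian, R otherwise), `"cpp"` or `"r"`.
#' @return a `"penalised_fit"`: list with `F` (optimal costs, index `t + 1`
#'   holds `F(t)`, `F[1] = -beta`), `last_change` (backpointers),
#'   `changepoints`, `candidate_counts` (candidates scanned at each step;
#'   here always `t`), `beta`.
#' @examples
#' fit <- optimal_partitioning(c(0, 0, 0, 10, 10, 10), beta = 1)
#' fit$changepoints  # 3
#' @seealso [pelt()], [fpop()] which return identical optima faster.
#' @export
optimal_partitioning <- function(series, beta, model = cost_model("gaussian"),
                                 engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_penalised_args(series, model, beta)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .op_gauss(scaled_values(series, model), beta)
  } else {
    res <- r_op(series, model, beta)
  }
  new_penalised_fit("op", res$F, res$last_change, res$candidate_counts,
                    beta, NULL, model, series$n)
}

#' PELT: penalised segmentation with inequality-based pruning
#'
#' Identical output to [optimal_partitioning()], but candidates `tau` whose
#' cost-so-far can provably never win again,
#' `F(tau) + C(y[(tau+1):t]) + kappa > F(t)`, are removed from the search
#' set permanently. Valid for any cost satisfying the C2 subadditivity
#' condition; both built-in families satisfy it with `kappa = 0`.
#'
#' @inheritParams optimal_partitioning
#' @param kappa the C2 constant (0 for both built-in families).
#' @param trace_sets keep the candidate set at every step (for
#'   [verify_dominance()] and pruning diagnostics).
#' @return a `"penalised_fit"`; if `trace_sets` the element `sets` is a list
#'   whose `t`-th entry is the candidate set the minimisation at time `t`
#'   ran over.
#' @export
pelt <- function(series, beta, model = cost_model("gaussian"),
                 kappa = model$kappa, trace_sets = FALSE,
                 engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_penalised_args(series, model, beta)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .pelt_gauss(scaled_values(series, model), beta, kappa, trace_sets)
  } else {
    res <- r_pelt(series, model, beta, kappa, trace_sets)
  }
  new_penalised_fit("pelt", res$F, res$last_change, res$candidate_counts,
                    beta, if (trace_sets) res$sets else NULL, model, series$n)
}

#' FPOP: penalised segmentation with functional pruning
#'
#' Solves the same penalised problem as [optimal_partitioning()] by
#' maintaining, for every candidate last changepoint, its cost as a function
#' of the final-segment parameter, together with the interval set on which
#' that candidate is currently the pointwise minimum. A candidate whose set
#' becomes empty is pruned; functional pruning discards at least every
#' candidate that inequality-based pruning would (and typically many more),
#' while returning the exact optimum. Requires the pointwise-decomposable
#' C1 condition, satisfied by both built-in families.
#'
#' @inheritParams pelt
#' @return a `"penalised_fit"` (see [optimal_partitioning()]).
#' @examples
#' spec <- signal_spec(seed = 1)
#' y <- generate_signal(spec)
#' fit <- fpop(y, beta = penalty_value(length(y)))
#' fit$changepoints
#' @export
fpop <- function(series, beta, model = cost_model("gaussian"),
                 trace_sets = FALSE, engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_penalised_args(series, model, beta)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .fpop_gauss(scaled_values(series, model), beta, trace_sets)
  } else {
    res <- r_fpop(series, model, beta, trace_sets)
  }
  new_penalised_fit("fpop", res$F, res$last_change, res$candidate_counts,
                    beta, if (trace_sets) res$sets else NULL, model, series$n)
}

#' Recover the changepoint vector from backpointers
#'
#' Follows the recursion `cp(t) = (cp(tau*_t), tau*_t)` from `t = n` down to
#' 0, dropping the sentinel changepoint at 0.
#'
#' @param last_change integer vector; element `t` is the optimal position of
#'   the last changepoint when segmenting `y[1:t]` (0 = no changepoint).
#' @return strictly increasing integer vector of changepoints (possibly
#'   empty).
#' @export
backtrack_changepoints <- function(last_change) {
  n <- length(last_change)
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    tau <- last_change[t]
    if (is.na(tau) || tau >= t || tau < 0L)
      stop("corrupt backpointer at t = ", t, call. = FALSE)
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  as.integer(cps)
}

# ------------------------------------------------------------ pure-R engines

# Optimal Partitioning for any cost model (vectorised over tau).
r_op <- function(series, model, beta) {
  n <- series$n
  F <- numeric(n + 1); F[1] <- -beta
  lc <- integer(n); counts <- integer(n)
  for (t in seq_len(n)) {
    taus <- 0:(t - 1L)
    vals <- F[taus + 1L] + segment_cost_vec(model, series, taus, t) + beta
    i <- which.min(vals)
    F[t + 1L] <- vals[i]; lc[t] <- taus[i]; counts[t] <- t
  }
  list(F = F, last_change = lc, candidate_counts = counts)
}

# PELT for any C2 cost model.
r_pelt <- function(series, model, beta, kappa, trace_sets) {
  n <- series$n
  F <- numeric(n + 1); F[1] <- -beta
  lc <- integer(n); counts <- integer(n)
  sets <- if (trace_sets) vector("list", n) else NULL
  R <- 0L
  for (t in seq_len(n)) {
    counts[t] <- length(R)
    if (trace_sets) sets[[t]] <- R
    vals <- F[R + 1L] + segment_cost_vec(model, series, R, t) + beta
    i <- which.min(vals)
    F[t + 1L] <- vals[i]; lc[t] <- R[i]
    R <- c(R[vals - beta + kappa <= F[t + 1L]], t)
  }
  list(F = F, last_change = lc, candidate_counts = counts, sets = sets)
}

# FPOP for any C1 cost model, through the candidate-cost machinery.
r_fpop <- function(series, model, beta, trace_sets) {
  n <- series$n
  F <- numeric(n + 1); F[1] <- -beta
  lc <- integer(n); counts <- integer(n)
  sets <- if (trace_sets) vector("list", n) else NULL
  cands <- list(candidate_cost(model, 0L, init_value = 0))  # F(0) + beta
  for (t in seq_len(n)) {
    yt <- series$values[t]
    cands <- lapply(cands, add_observation, y = yt)
    counts[t] <- length(cands)
    if (trace_sets)
      sets[[t]] <- vapply(cands, function(cd) cd$tau, integer(1))
    mins <- vapply(cands, function(cd) candidate_minimum(cd)$value, numeric(1))
    i <- which.min(mins)
    F[t + 1L] <- mins[i]; lc[t] <- cands[[i]]$tau
    thr <- F[t + 1L] + beta
    Is <- lapply(cands, level_set, threshold = thr)
    keep <- logical(length(cands))
    for (j in seq_along(cands)) {
      cands[[j]]$set <- interval_intersect(cands[[j]]$set, Is[[j]])
      keep[j] <- !interval_is_empty(cands[[j]]$set)
    }
    cands <- cands[keep]
    if (t < n) {
      newset <- interval_complement_union(Is, model$domain)
      if (!interval_is_empty(newset)) {
        cands <- c(cands, list(
          candidate_cost(model, t, init_value = thr, set = newset)))
      }
    }
  }
  list(F = F, last_change = lc, candidate_counts = counts, sets = sets)
}
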