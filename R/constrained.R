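new_constrained_fit <- function(method, C, bp, counts, K, sets, model, n) {
  dimnames(C) <- list(k = 0:K, t = 0:n)
  segmentations <- lapply(seq_len(K), function(k) backtrack_constrained(bp, k))
  structure(list(
    method = method,
    C = C,
    backpointers = bp,
    segmentations = segmentations,
    candidate_counts = counts,
    K = K,
    sets = sets,
    family = model$family,
    n = n
  ), class = "constrained_fit")
}

#' @export
print.constrained_fit <- function(x, ...) {
  cat("<constrained_fit> method =", x$method, " family =", x$family,
      " n =", x$n, " K =", x$K, "\n")
  cat("  C(k, n):", paste(signif(x$C[, x$n + 1], 6), collapse = ", "), "\n")
  cat("  k =", x$K, "changepoints:",
      paste(utils::head(x$segmentations[[x$K]], 12L), collapse = ", "), "\n")
  invisible(x)
}

check_constrained_args <- function(series, model, K) {
  if (!inherits(model, "cost_model"))
    stop("'model' must be a cost_model", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("'K' must be a positive integer", call. = FALSE)
  if (K >= series$n)
    stop("'K' must be at most n - 1", call. = FALSE)
  if (model$family == "poisson" && any(series$values < 0))
    stop("Poisson loss requires non-negative data", call. = FALSE)
}

#' Segment Neighbourhood Search: exact constrained segmentation
#'
#' Computes the minimal total segment cost `C[k, t]` of segmenting
#' `y[1:t]` with exactly `k` changepoints, for all `k = 0..K` and all `t`,
#' by the O(K n^2) recursion
#' `C[k, t] = min_{k <= tau <= t-1} C[k-1, tau] + C(y[(tau+1):t])`.
#'
#' @param series numeric vector or [time_series()].
#' @param K maximum number of changepoints (`1 <= K <= n - 1`).
#' @param model a [cost_model()].
#' @param engine `"auto"` (C++ for Gaussian, R otherwise), `"cpp"` or `"r"`.
#' @return a `"constrained_fit"`: list with `C` (matrix, rows `k = 0..K`,
#'   columns `t = 0..n`, `NA` where `t < k`), `backpointers`,
#'   `segmentations` (for each `k`, the exact ordered changepoint vector),
#'   `candidate_counts` and `K`.
#' @examples
#' fit <- segment_neighbourhood(c(0, 0, 0, 10, 10, 10), K = 2)
#' fit$C[, 7]             # optimal cost for k = 0, 1, 2 changes
#' fit$segmentations[[1]] # 3
#' @export
segment_neighbourhood <- function(series, K, model = cost_model("gaussian"),
                                  engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_constrained_args(series, model, K)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .segneigh_gauss(scaled_values(series, model), as.integer(K))
  } else {
    res <- r_segneigh(series, model, K)
  }
  new_constrained_fit("segneigh", res$C, res$backpointers,
                      res$candidate_counts, K, NULL, model, series$n)
}

#' SNIP: constrained segmentation with inequality-based pruning
#'
#' Identical output to [segment_neighbourhood()]. For each number of changes
#' `k` a candidate set is maintained; a candidate `v` is discarded forever
#' once `C[k-1, v] + C(y[(v+1):t]) + kappa >= C[k-1, t]` (the freshly
#' admitted candidate `t` can then never lose to it). Requires condition C2.
#'
#' @inheritParams segment_neighbourhood
#' @param kappa the C2 constant (0 for both built-in families).
#' @param trace_sets keep per-(k, t) candidate sets (list of lists; memory
#'   grows as O(sum of set sizes), so reserve this for moderate `n`).
#' @return a `"constrained_fit"`.
#' @export
snip <- function(series, K, model = cost_model("gaussian"),
                 kappa = model$kappa, trace_sets = FALSE,
                 engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_constrained_args(series, model, K)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .snip_gauss(scaled_values(series, model), as.integer(K), kappa,
                       trace_sets)
  } else {
    res <- r_snip(series, model, K, kappa, trace_sets)
  }
  new_constrained_fit("snip", res$C, res$backpointers, res$candidate_counts,
                      K, if (trace_sets) res$sets else NULL, model, series$n)
}

#' pDPA: constrained segmentation with functional pruning
#'
#' Identical output to [segment_neighbourhood()]. For each `k` the cost of
#' every candidate last changepoint is carried as a function of the
#' final-segment parameter, and candidates are pruned as soon as they are
#' optimal for no parameter value. Requires condition C1.
#'
#' @inheritParams snip
#' @return a `"constrained_fit"`.
#' @export
pdpa <- function(series, K, model = cost_model("gaussian"),
                 trace_sets = FALSE, engine = c("auto", "cpp", "r")) {
  series <- time_series(series)
  engine <- match.arg(engine)
  check_constrained_args(series, model, K)
  use_cpp <- engine == "cpp" || (engine == "auto" && model$family == "gaussian")
  if (use_cpp) {
    if (model$family != "gaussian")
      stop("the compiled engine supports the Gaussian family only", call. = FALSE)
    res <- .pdpa_gauss(scaled_values(series, model), as.integer(K), trace_sets)
  } else {
    res <- r_pdpa(series, model, K, trace_sets)
  }
  new_constrained_fit("pdpa", res$C, res$backpointers, res$candidate_counts,
                      K, if (trace_sets) res$sets else NULL, model, series$n)
}

#' Recover the exact k-changepoint segmentation from backpointers
#'
#' Uses `tau_k = bp[k, n]` then `tau_l = bp[l, tau_{l+1}]` for
#' `l = k-1, ..., 1`.
#'
#' @param backpointers matrix as returned in a `"constrained_fit"` (rows
#'   `k = 0..K`, columns `t = 0..n`).
#' @param k number of changepoints, `1 <= k <= K`.
#' @return strictly increasing integer vector of length `k`.
#' @export
backtrack_constrained <- function(backpointers, k) {
  K <- nrow(backpointers) - 1L
  n <- ncol(backpointers) - 1L
  if (k < 1L || k > K) stop("'k' must be in 1..K", call. = FALSE)
  cps <- integer(k)
  t <- n
  for (l in k:1) {
    tau <- backpointers[l + 1L, t + 1L]
    if (is.na(tau) || tau >= t)
      stop("corrupt backpointer at (k = ", l, ", t = ", t, ")", call. = FALSE)
    cps[l] <- tau
    t <- tau
  }
  as.integer(cps)
}

# ------------------------------------------------------------ pure-R engines

empty_constrained <- function(series, K) {
  n <- series$n
  C <- matrix(NA_real_, K + 1L, n + 1L)
  bp <- matrix(NA_integer_, K + 1L, n + 1L)
  counts <- matrix(NA_integer_, K + 1L, n + 1L)
  list(C = C, bp = bp, counts = counts)
}

r_segneigh <- function(series, model, K) {
  n <- series$n
  st <- empty_constrained(series, K)
  C <- st$C; bp <- st$bp; counts <- st$counts
  C[1L, 1L] <- 0
  for (t in seq_len(n)) C[1L, t + 1L] <- segment_cost_vec(model, series, 0L, t)
  for (k in seq_len(K)) {
    C[k + 1L, k + 1L] <- 0
    for (t in (k + 1L):n) {
      taus <- k:(t - 1L)
      vals <- C[k, taus + 1L] + segment_cost_vec(model, series, taus, t)
      i <- which.min(vals)
      C[k + 1L, t + 1L] <- vals[i]
      bp[k + 1L, t + 1L] <- taus[i]
      counts[k + 1L, t + 1L] <- length(taus)
    }
  }
  list(C = C, backpointers = bp, candidate_counts = counts)
}

r_snip <- function(series, model, K, kappa, trace_sets) {
  n <- series$n
  st <- empty_constrained(series, K)
  C <- st$C; bp <- st$bp; counts <- st$counts
  C[1L, 1L] <- 0
  for (t in seq_len(n)) C[1L, t + 1L] <- segment_cost_vec(model, series, 0L, t)
  sets <- if (trace_sets) vector("list", K) else NULL
  for (k in seq_len(K)) {
    C[k + 1L, k + 1L] <- 0
    R <- k
    ksets <- if (trace_sets) vector("list", n - k) else NULL
    for (t in (k + 1L):n) {
      counts[k + 1L, t + 1L] <- length(R)
      if (trace_sets) ksets[[t - k]] <- R
      vals <- C[k, R + 1L] + segment_cost_vec(model, series, R, t)
      i <- which.min(vals)
      C[k + 1L, t + 1L] <- vals[i]
      bp[k + 1L, t + 1L] <- R[i]
      # strict inequality as in the constrained pruning rule; the new
      # candidate t is always admitted
      R <- c(R[vals + kappa < C[k, t + 1L]], t)
    }
    if (trace_sets) sets[[k]] <- ksets
  }
  list(C = C, backpointers = bp, candidate_counts = counts, sets = sets)
}

r_pdpa <- function(series, model, K, trace_sets) {
  n <- series$n
  st <- empty_constrained(series, K)
  C <- st$C; bp <- st$bp; counts <- st$counts
  C[1L, 1L] <- 0
  for (t in seq_len(n)) C[1L, t + 1L] <- segment_cost_vec(model, series, 0L, t)
  sets <- if (trace_sets) vector("list", K) else NULL
  for (k in seq_len(K)) {
    C[k + 1L, k + 1L] <- 0
    cands <- list(candidate_cost(model, k, init_value = C[k, k + 1L]))
    ksets <- if (trace_sets) vector("list", n - k) else NULL
    for (t in (k + 1L):n) {
      yt <- series$values[t]
      cands <- lapply(cands, add_observation, y = yt)
      counts[k + 1L, t + 1L] <- length(cands)
      if (trace_sets)
        ksets[[t - k]] <- vapply(cands, function(cd) cd$tau, integer(1))
      mins <- vapply(cands, function(cd) candidate_minimum(cd)$value, numeric(1))
      i <- which.min(mins)
      C[k + 1L, t + 1L] <- mins[i]
      bp[k + 1L, t + 1L] <- cands[[i]]$tau
      thr <- C[k, t + 1L]
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
    if (trace_sets) sets[[k]] <- ksets
  }
  list(C = C, backpointers = bp, candidate_counts = counts, sets = sets)
}
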