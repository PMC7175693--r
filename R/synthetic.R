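#' Specification of a piecewise-constant Gaussian test signal
#'
#' Describes a simulated signal: `n` points, mean changes at the given
#' indices (a changepoint at `t` means the mean shifts between `y[t]` and
#' `y[t+1]`), one mean per segment and i.i.d. Gaussian noise. The defaults
#' reproduce the design used throughout the package's diagnostics: `n =
#' 100` with changes at 20, 40, 60, 80 and segment means alternating
#' between 0 and 5 with unit noise, i.e. mean shifts of five noise s.d.
#'
#' @param n series length.
#' @param changepoints strictly increasing integer indices in `1..n-1`.
#' @param means one mean per segment (`length(changepoints) + 1`).
#' @param sigma noise standard deviation (`>= 0`; 0 gives the noiseless
#'   mean function).
#' @param seed integer seed making [generate_signal()] deterministic.
#' @return an object of class `"signal_spec"`.
#' @export
signal_spec <- function(n = 100, changepoints = c(20, 40, 60, 80),
                        means = rep(c(0, 5), length.out =
                                      length(changepoints) + 1),
                        sigma = 1, seed = 1) {
  changepoints <- as.integer(changepoints)
  if (length(changepoints) &&
      (any(diff(changepoints) <= 0) || any(changepoints < 1) ||
       any(changepoints > n - 1)))
    stop("'changepoints' must be strictly increasing indices in 1..n-1",
         call. = FALSE)
  if (length(means) != length(changepoints) + 1L)
    stop("need exactly one mean per segment: length(means) == ",
         "length(changepoints) + 1", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("'sigma' must be non-negative", call. = FALSE)
  structure(list(n = as.integer(n), changepoints = changepoints,
                 means = as.numeric(means), sigma = sigma,
                 seed = as.integer(seed)),
            class = "signal_spec")
}

#' @export
print.signal_spec <- function(x, ...) {
  cat("<signal_spec> n =", x$n, " sigma =", x$sigma, " seed =", x$seed, "\n")
  cat("  changepoints:", paste(x$changepoints, collapse = ", "), "\n")
  cat("  segment means:", paste(x$means, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a signal from a specification
#'
#' Draws `values[i] = segment mean + N(0, sigma^2)` using R's Mersenne
#' Twister generator seeded from `spec$seed`, so the same spec always
#' yields the same series. The caller's random-number state is left
#' untouched.
#'
#' @param spec a [signal_spec()].
#' @return numeric vector of length `spec$n`.
#' @export
generate_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  mean_fn <- rep(spec$means,
                 diff(c(0L, spec$changepoints, spec$n)))
  if (spec$sigma == 0) return(mean_fn)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  mean_fn + stats::rnorm(spec$n, sd = spec$sigma)
}

#' Exhaustive optimum of the penalised problem
#'
#' Enumerates every subset of `{1, ..., n-1}` as a candidate changepoint
#' set (2^(n-1) segmentations) and scores each as the summed segment costs
#' plus `beta` per changepoint. Serves as the ground-truth oracle for the
#' dynamic-programming solvers on small inputs.
#'
#' @param series numeric vector or [time_series()], `n <= 16`.
#' @param beta non-negative penalty per changepoint.
#' @param model a [cost_model()].
#' @return list with `F_n` (the optimal penalised cost) and `changepoints`
#'   (the optimal set; among exact ties the lexicographically smallest).
#' @export
brute_force_penalised <- function(series, beta, model = cost_model("gaussian")) {
  series <- time_series(series)
  n <- series$n
  if (n > 16L)
    stop("refusing exhaustive enumeration for n > 16", call. = FALSE)
  check_penalised_args(series, model, beta)
  costmat <- all_segment_costs(series, model)
  if (n == 1L)
    return(list(F_n = costmat[1L, 1L], changepoints = integer(0)))
  best <- Inf
  best_cps <- integer(0)
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cps <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2L))) != 0L)
    bounds <- c(0L, cps, n)
    val <- sum(costmat[cbind(bounds[-length(bounds)] + 1L,
                             bounds[-1L])]) + beta * length(cps)
    if (val < best - 1e-12 ||
        (abs(val - best) <= 1e-12 && lex_smaller(cps, best_cps))) {
      best <- val
      best_cps <- cps
    }
  }
  list(F_n = best, changepoints = as.integer(best_cps))
}

#' Exhaustive optimum of the constrained problem
#'
#' Enumerates all `choose(n-1, k)` placements of exactly `k` changepoints.
#'
#' @param series numeric vector or [time_series()], `n <= 16`.
#' @param k number of changepoints (`0 <= k <= min(n - 1, 4)`).
#' @param model a [cost_model()].
#' @return list with `C_kn` and `changepoints`.
#' @export
brute_force_constrained <- function(series, k, model = cost_model("gaussian")) {
  series <- time_series(series)
  n <- series$n
  if (n > 16L || k > 4L)
    stop("refusing enumeration beyond n = 16, k = 4", call. = FALSE)
  if (k < 0L || k > n - 1L) stop("'k' must be in 0..n-1", call. = FALSE)
  costmat <- all_segment_costs(series, model)
  if (k == 0L)
    return(list(C_kn = costmat[1L, n], changepoints = integer(0)))
  combos <- utils::combn(n - 1L, k)
  best <- Inf
  best_cps <- integer(0)
  for (j in seq_len(ncol(combos))) {
    cps <- combos[, j]
    bounds <- c(0L, cps, n)
    val <- sum(costmat[cbind(bounds[-length(bounds)] + 1L, bounds[-1L])])
    if (val < best - 1e-12 ||
        (abs(val - best) <= 1e-12 && lex_smaller(cps, best_cps))) {
      best <- val
      best_cps <- cps
    }
  }
  list(C_kn = best, changepoints = as.integer(best_cps))
}

# cost of every segment (s, t], rows indexed s + 1, columns t
all_segment_costs <- function(series, model) {
  n <- series$n
  m <- matrix(NA_real_, n, n)
  for (t in seq_len(n)) {
    s <- 0:(t - 1L)
    m[cbind(s + 1L, t)] <- segment_cost_vec(model, series, s, t)
  }
  m
}

# TRUE if integer vector a sorts lexicographically before b
lex_smaller <- function(a, b) {
  la <- length(a); lb <- length(b)
  for (i in seq_len(min(la, lb))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}
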