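#' Construct a time series with precomputed prefix sums
#'
#' Wraps an ordered numeric signal together with its cumulative sums and
#' cumulative sums of squares, so that the cost of any contiguous segment can
#' be evaluated in constant time by every solver in the package.
#'
#' Indexing is 1-based and segments follow the convention that
#' `y[(s+1):t]` is the segment "after a changepoint at s, up to t", with
#' `0 <= s < t <= n`.
#'
#' @param y numeric vector of ordered observations; must be finite.
#' @return an object of class `"time_series"`: a list with elements
#'   `values`, `n`, `prefix_sum` (length `n + 1`, starting at 0) and
#'   `prefix_sumsq` (length `n + 1`, starting at 0).
#' @examples
#' ts <- time_series(c(0, 0, 0, 10, 10, 10))
#' segment_cost(cost_model("gaussian"), ts, 0, 6)
#' @export
time_series <- function(y) {
  if (inherits(y, "time_series")) return(y)
  if (!is.numeric(y) || length(y) < 1L)
    stop("'y' must be a non-empty numeric vector", call. = FALSE)
  y <- as.numeric(y)
  if (any(!is.finite(y)))
    stop("'y' contains non-finite values (NA/NaN/Inf)", call. = FALSE)
  structure(list(
    values = y,
    n = length(y),
    prefix_sum = c(0, cumsum(y)),
    prefix_sumsq = c(0, cumsum(y^2))
  ), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat("<time_series> n =", x$n, "\n")
  cat("  values: ", paste(utils::head(signif(x$values, 4), 8L), collapse = ", "),
      if (x$n > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Define a segment loss family
#'
#' A cost model fixes the pointwise loss \eqn{\gamma(y, \mu)} whose minimised
#' sum over a segment gives the segment cost. Both supported families are
#' pointwise decomposable (condition C1: the segment cost is the minimum over
#' a shared scalar parameter of the summed pointwise losses), which implies
#' subadditivity across any split with constant \eqn{\kappa = 0} (condition
#' C2). C1 is what functional pruning (FPOP, pDPA) requires; C2 is what
#' inequality-based pruning (PELT, SNIP) requires.
#'
#' Families:
#' \describe{
#'   \item{`gaussian`}{change in mean with known noise s.d.:
#'     \eqn{\gamma(y,\mu) = (y-\mu)^2 / (2\sigma^2)}; parameter domain is the
#'     whole real line. The usual workflow standardises the signal first (see
#'     [mad_standardise()]) and keeps `sigma = 1`.}
#'   \item{`poisson`}{change in rate for non-negative data:
#'     \eqn{\gamma(y,\mu) = \mu - y \log\mu} (negative Poisson log-likelihood
#'     without its data-only term); domain is \eqn{(0, \infty)}. An all-zero
#'     segment has cost 0, attained in the limit \eqn{\mu \to 0^+}.}
#' }
#'
#' @param family `"gaussian"` or `"poisson"`.
#' @param sigma positive noise standard deviation (Gaussian only).
#' @return an object of class `"cost_model"` with fields `family`, `sigma`,
#'   `domain` (numeric length 2) and `kappa` (the C2 constant, 0).
#' @export
cost_model <- function(family = c("gaussian", "poisson"), sigma = 1) {
  family <- match.arg(family)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  domain <- if (family == "gaussian") c(-Inf, Inf) else c(0, Inf)
  structure(list(family = family, sigma = sigma, domain = domain, kappa = 0),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> family =", x$family,
      if (x$family == "gaussian") paste0("(sigma = ", x$sigma, ")") else "",
      "\n")
  invisible(x)
}

#' Pointwise loss gamma(y, mu)
#'
#' Evaluates the per-observation loss of a cost model at parameter `mu`.
#' Vectorised over `y` and `mu` (recycled).
#'
#' @param model a [cost_model()].
#' @param y observation(s).
#' @param mu segment parameter value(s); must lie in the model's domain
#'   (any real for Gaussian, strictly positive for Poisson).
#' @return numeric loss values.
#' @export
pointwise_cost <- function(model, y, mu) {
  stopifnot(inherits(model, "cost_model"))
  if (any(mu < model$domain[1] | mu > model$domain[2]) ||
      (model$family == "poisson" && any(mu <= 0)))
    stop("'mu' outside the parameter domain of the ", model$family,
         " cost model", call. = FALSE)
  switch(model$family,
    gaussian = (y - mu)^2 / (2 * model$sigma^2),
    poisson  = {
      if (any(y < 0)) stop("Poisson loss requires non-negative data", call. = FALSE)
      mu - y * log(mu)
    })
}

#' Closed-form minimal cost of one segment
#'
#' Computes \eqn{C(y_{(s+1):t}) = \min_\mu \sum_{i=s+1}^{t} \gamma(y_i,\mu)}
#' in O(1) from the prefix sums stored in the [time_series()] object. For the
#' Gaussian family this is the scaled within-segment sum of squares
#' \eqn{\frac{1}{2\sigma^2}\sum (y_i - \bar y)^2}; for Poisson it is
#' \eqn{S - S\log(S/m)} with segment sum \eqn{S} and length \eqn{m}
#' (0 when \eqn{S = 0}).
#'
#' @param model a [cost_model()].
#' @param series a [time_series()] (or numeric vector).
#' @param s,t segment boundaries, `0 <= s < t <= n`; the segment is
#'   `values[(s+1):t]`.
#' @return a single number. Gaussian costs are non-negative; Poisson costs
#'   can be negative because the data-only term of the log-likelihood has
#'   been dropped.
#' @export
segment_cost <- function(model, series, s, t) {
  series <- time_series(series)
  stopifnot(inherits(model, "cost_model"),
            length(s) == 1L, length(t) == 1L)
  if (s < 0 || t > series$n || s >= t)
    stop("invalid segment indices: need 0 <= s < t <= n", call. = FALSE)
  segment_cost_vec(model, series, s, t)
}

# Vectorised over s (same t): the O(1) kernel shared by the R solvers.
# No argument checking; internal.
segment_cost_vec <- function(model, series, s, t) {
  m <- t - s
  S <- series$prefix_sum[t + 1L] - series$prefix_sum[s + 1L]
  if (model$family == "gaussian") {
    SS <- series$prefix_sumsq[t + 1L] - series$prefix_sumsq[s + 1L]
    # clamp tiny negative rounding noise; the quantity is a sum of squares
    pmax(0, (SS - S^2 / m) / (2 * model$sigma^2))
  } else {
    if (any(series$values < 0))
      stop("Poisson loss requires non-negative data", call. = FALSE)
    ifelse(S <= 0, 0, S - S * log(S / m))
  }
}
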