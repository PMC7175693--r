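#' Candidate cost functions in the segment parameter
#'
#' Functional pruning maintains, for every candidate last changepoint
#' \eqn{\tau}, the cost of the data up to the current time conditional on the
#' final segment having parameter \eqn{\mu}. For the Gaussian family this is
#' a quadratic \eqn{a\mu^2 + b\mu + c}; for the Poisson family it has the
#' form \eqn{m\mu - s\log\mu + o} with \eqn{m} the number of absorbed points
#' and \eqn{s} their sum. A candidate also carries the interval set on which
#' it currently achieves the pointwise minimum over all live candidates; a
#' candidate whose set becomes empty can never be optimal again and is
#' pruned.
#'
#' @param model a [cost_model()].
#' @param tau integer index of the candidate last changepoint.
#' @param init_value value of the (initially flat) function: the optimal cost
#'   of the data up to `tau` plus, in the penalised problem, the penalty.
#' @param set an [interval_set()]; defaults to the whole parameter domain.
#' @return an object of class `"candidate_cost"`.
#' @examples
#' m <- cost_model("gaussian")
#' cand <- candidate_cost(m, tau = 0, init_value = 5)
#' cand <- add_observation(cand, 2)
#' candidate_minimum(cand)
#' @export
candidate_cost <- function(model, tau, init_value = 0,
                           set = interval_set(model$domain[1], model$domain[2])) {
  stopifnot(inherits(model, "cost_model"))
  coef <- if (model$family == "gaussian") {
    c(a = 0, b = 0, c = init_value)
  } else {
    c(m = 0, s = 0, o = init_value)
  }
  structure(list(tau = as.integer(tau), family = model$family,
                 sigma = model$sigma, domain = model$domain,
                 coef = coef, set = set, npts = 0L),
            class = "candidate_cost")
}

#' @export
print.candidate_cost <- function(x, ...) {
  cat("<candidate_cost> tau =", x$tau, "family =", x$family, "\n")
  cat("  coef:", paste(names(x$coef), "=", signif(x$coef, 6), collapse = ", "), "\n")
  print(x$set)
  invisible(x)
}

#' Absorb one observation into a candidate cost function
#'
#' Adds the pointwise loss \eqn{\gamma(y, \mu)} to the stored function, i.e.
#' updates its closed-form coefficients so that the candidate now accounts
#' for one more data point in its final segment.
#'
#' @param cand a [candidate_cost()].
#' @param y one observation.
#' @return the updated candidate.
#' @export
add_observation <- function(cand, y) {
  stopifnot(inherits(cand, "candidate_cost"), length(y) == 1L, is.finite(y))
  if (cand$family == "gaussian") {
    s2 <- cand$sigma^2
    cand$coef <- cand$coef + c(1 / (2 * s2), -y / s2, y^2 / (2 * s2))
  } else {
    if (y < 0) stop("Poisson loss requires non-negative data", call. = FALSE)
    cand$coef <- cand$coef + c(1, y, 0)
  }
  cand$npts <- cand$npts + 1L
  cand
}

#' Evaluate a candidate cost function
#'
#' @param cand a [candidate_cost()].
#' @param mu parameter value(s) inside the domain (vectorised).
#' @return numeric cost value(s).
#' @export
evaluate_candidate <- function(cand, mu) {
  cf <- cand$coef
  if (cand$family == "gaussian") {
    cf[1] * mu^2 + cf[2] * mu + cf[3]
  } else {
    cf[1] * mu - cf[2] * log(mu) + cf[3]
  }
}

#' Minimise a candidate cost function over the parameter
#'
#' Gives the unconstrained minimum of the stored function. For the Gaussian
#' quadratic this is the vertex; for Poisson the minimiser is the segment
#' mean. A flat candidate (no observation absorbed yet) returns its constant
#' value with minimiser 0 by convention.
#'
#' @param cand a [candidate_cost()].
#' @return list with `mu_hat` and `value`.
#' @export
candidate_minimum <- function(cand) {
  cf <- cand$coef
  if (cand$family == "gaussian") {
    if (cf[1] > 0) {
      mu <- -cf[2] / (2 * cf[1])
      list(mu_hat = unname(mu), value = unname(cf[3] - cf[2]^2 / (4 * cf[1])))
    } else {
      list(mu_hat = 0, value = unname(cf[3]))
    }
  } else {
    m <- cf[1]; s <- cf[2]; o <- cf[3]
    if (m == 0) return(list(mu_hat = 0, value = unname(o)))
    if (s == 0) return(list(mu_hat = 0, value = unname(o)))  # limit mu -> 0+
    mu <- s / m
    list(mu_hat = unname(mu), value = unname(s - s * log(mu) + o))
  }
}

#' Level set of a candidate cost function
#'
#' Returns the exact set \eqn{\{\mu \in D : Cost(\mu) \le threshold\}}. For
#' the Gaussian quadratic this is the interval between the two real roots
#' (empty if the minimum exceeds the threshold). The Poisson function has no
#' closed-form roots; it is convex in \eqn{\mu}, so each root is bracketed
#' and located by bisection to relative tolerance 1e-10.
#'
#' @param cand a [candidate_cost()].
#' @param threshold cost threshold.
#' @return an [interval_set()] clipped to the model domain.
#' @export
level_set <- function(cand, threshold) {
  stopifnot(inherits(cand, "candidate_cost"), is.finite(threshold))
  dom <- interval_set(cand$domain[1], cand$domain[2])
  cf <- cand$coef
  if (cand$family == "gaussian") {
    a <- cf[1]; b <- cf[2]; cc <- cf[3]
    if (a == 0)
      return(if (cc <= threshold) dom else interval_set())
    disc <- b^2 - 4 * a * (cc - threshold)
    if (disc < 0) return(interval_set())
    r <- sqrt(disc)
    interval_intersect(interval_set((-b - r) / (2 * a), (-b + r) / (2 * a)), dom)
  } else {
    m <- cf[1]; s <- cf[2]; o <- cf[3]
    if (m == 0 && s == 0)
      return(if (o <= threshold) dom else interval_set())
    if (s == 0) {
      # increasing linear m*mu + o on (0, Inf); value tends to o at 0+
      if (threshold < o) return(interval_set())
      return(interval_intersect(interval_set(0, (threshold - o) / m), dom))
    }
    f <- function(mu) m * mu - s * log(mu) + o
    mu_hat <- s / m
    fmin <- f(mu_hat)
    if (fmin > threshold) return(interval_set())
    # left root: f -> +Inf as mu -> 0+
    lo <- mu_hat
    while (f(lo) <= threshold && lo > .Machine$double.xmin) lo <- lo / 2
    left <- bisect_root(f, lo, mu_hat, threshold, decreasing = TRUE)
    # right root: f -> +Inf as mu -> Inf
    hi <- mu_hat
    while (f(hi) <= threshold && hi < .Machine$double.xmax / 4) hi <- hi * 2
    right <- bisect_root(f, mu_hat, hi, threshold, decreasing = FALSE)
    interval_intersect(interval_set(left, right), dom)
  }
}

# Bisection for f(mu) == threshold on a monotone stretch of a convex
# function. 'decreasing = TRUE' means f is decreasing on [lo, hi].
bisect_root <- function(f, lo, hi, threshold, decreasing, rel_tol = 1e-10) {
  if (lo == hi) return(lo)
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= rel_tol * (abs(mid) + rel_tol)) return(mid)
    if (mid <= lo || mid >= hi) return(mid)  # float fixed point
    above <- f(mid) > threshold
    if (decreasing) {
      if (above) lo <- mid else hi <- mid
    } else {
      if (above) hi <- mid else lo <- mid
    }
  }
}
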