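#' Unions of disjoint closed intervals
#'
#' Functional-pruning solvers track, for each candidate last changepoint, the
#' subset of the parameter domain on which that candidate currently achieves
#' the pointwise minimum of all candidate cost functions. These subsets are
#' finite unions of closed intervals, represented here as a two-column matrix
#' `cbind(lo, hi)` with rows sorted and pairwise disjoint; `-Inf`/`Inf` act
#' as open-ended sentinels. A zero-row matrix is the empty set.
#'
#' @param lo,hi numeric vectors of equal length with `lo <= hi`. Overlapping
#'   or touching input intervals are merged.
#' @return an object of class `"interval_set"`.
#' @examples
#' interval_set(c(-1, 2), c(1, 3))
#' interval_intersect(interval_set(-1, 1), interval_set(0, 2))
#' @export
interval_set <- function(lo = numeric(0), hi = numeric(0)) {
  if (length(lo) != length(hi))
    stop("'lo' and 'hi' must have equal length", call. = FALSE)
  if (any(lo > hi))
    stop("interval with lo > hi", call. = FALSE)
  m <- unname(cbind(as.numeric(lo), as.numeric(hi)))
  if (nrow(m) > 1L) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    out <- m[1L, , drop = FALSE]
    for (i in 2L:nrow(m)) {
      j <- nrow(out)
      if (m[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
    m <- out
  }
  structure(m, class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<interval_set> empty\n")
  } else {
    cat("<interval_set> ",
        paste(sprintf("[%g, %g]", x[, 1L], x[, 2L]), collapse = " U "), "\n")
  }
  invisible(x)
}

#' Test whether an interval set is empty
#' @param x an [interval_set()].
#' @return logical.
#' @export
interval_is_empty <- function(x) nrow(x) == 0L

#' Intersection of two interval sets
#'
#' Exact set intersection; the result is again sorted and disjoint.
#'
#' @param a,b [interval_set()] objects.
#' @return an [interval_set()].
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_set())
  lo <- numeric(0); hi <- numeric(0)
  for (i in seq_len(nrow(a))) {
    l <- pmax(a[i, 1L], b[, 1L])
    h <- pmin(a[i, 2L], b[, 2L])
    keep <- l <= h
    lo <- c(lo, l[keep]); hi <- c(hi, h[keep])
  }
  interval_set(lo, hi)
}

#' Complement of a union of interval sets within a domain
#'
#' Computes `domain \ union(sets)`. Used to initialise the optimality set of
#' a freshly added candidate changepoint: it is optimal exactly where no
#' existing candidate can still beat the current optimum. If the union
#' covers the domain the result is empty and the new candidate is pruned
#' immediately.
#'
#' @param sets a list of [interval_set()] objects (may be empty).
#' @param domain numeric length-2 vector `c(lo, hi)`; `-Inf`/`Inf` allowed.
#' @return an [interval_set()].
#' @export
interval_complement_union <- function(sets, domain = c(-Inf, Inf)) {
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  if (length(sets) == 0L) return(interval_set(domain[1], domain[2]))
  all_lo <- unlist(lapply(sets, function(s) s[, 1L]))
  all_hi <- unlist(lapply(sets, function(s) s[, 2L]))
  u <- interval_set(all_lo, all_hi)
  if (nrow(u) == 0L) return(interval_set(domain[1], domain[2]))
  # gaps of the union, clipped to the domain
  lo <- c(domain[1], u[, 2L])
  hi <- c(u[, 1L], domain[2])
  # keep non-degenerate gaps only: a width-0 gap endpoint belongs to the
  # union, and boundary ties go to the older candidate anyway
  keep <- lo < hi
  lo <- pmax(lo[keep], domain[1]); hi <- pmin(hi[keep], domain[2])
  keep2 <- lo < hi
  interval_set(lo[keep2], hi[keep2])
}
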