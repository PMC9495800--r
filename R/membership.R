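#' Trapezoidal membership function
#'
#' A fuzzy set over a one-dimensional universe (temperature in deg C or net
#' reproductive rate R0 in daughters/female), parameterised by four ordered
#' breakpoints `a <= b <= c <= d`.  Membership rises linearly from 0 at `a`
#' to 1 at `b`, is 1 on the plateau `[b, c]`, falls linearly to 0 at `d`,
#' and is 0 outside the open support `(a, d)`.  Degenerate `a == b` or
#' `c == d` give a vertical edge; the closed plateau wins at the shared
#' point, so `degree(b) == 1` always.
#'
#' @param name label of the set, unique within its partition.
#' @param a,b,c,d numeric breakpoints in universe units, `a <= b <= c <= d`.
#' @return an object of class `trapezoid_mf`.
#' @examples
#' opt <- trapezoid_mf("optimal", 18, 20, 25, 28)
#' membership_degree(opt, c(18, 19, 22, 28))
#' @export
trapezoid_mf <- function(name, a, b, c, d) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bp <- c(a = a, b = b, c = c, d = d)
  if (anyNA(bp) || any(!is.finite(bp)))
    stop("trapezoid breakpoints must be finite numbers")
  if (is.unsorted(bp))
    stop(sprintf("trapezoid '%s': breakpoints must satisfy a <= b <= c <= d (got %s)",
                 name, paste(signif(bp, 6), collapse = ", ")))
  structure(list(name = name, a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "trapezoid_mf")
}

#' Evaluate a membership function at crisp values
#'
#' @param mf a [trapezoid_mf()].
#' @param x numeric vector of crisp values (non-finite values are an error).
#' @return numeric vector of degrees in `[0, 1]`, same length as `x`.
#' @export
membership_degree <- function(mf, x) {
  stopifnot(inherits(mf, "trapezoid_mf"))
  if (any(!is.finite(x))) stop("membership_degree: x must be finite")
  deg <- numeric(length(x))
  on_plateau <- x >= mf$b & x <= mf$c
  deg[on_plateau] <- 1
  rising <- !on_plateau & x > mf$a & x < mf$b
  if (any(rising)) deg[rising] <- (x[rising] - mf$a) / (mf$b - mf$a)
  falling <- !on_plateau & x > mf$c & x < mf$d
  if (any(falling)) deg[falling] <- (mf$d - x[falling]) / (mf$d - mf$c)
  deg
}

#' @export
print.trapezoid_mf <- function(x, ...) {
  cat(sprintf("<trapezoid_mf '%s'> a=%g b=%g c=%g d=%g\n",
              x$name, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Fuzzy partition of a universe
#'
#' An ordered collection of named trapezoidal sets over a bounded universe.
#' Every point of the universe must be covered by at least one set with
#' positive degree, and set names must be unique.
#'
#' @param universe numeric length-2 `(lo, hi)`, `lo < hi`.
#' @param sets list of [trapezoid_mf()] objects.
#' @param units unit label, e.g. `"degC"` or `"R0"`.
#' @param check_coverage verify the coverage invariant on a dense sample of
#'   the universe (default `TRUE`).
#' @return an object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(universe, sets, units = "", check_coverage = TRUE) {
  stopifnot(is.numeric(universe), length(universe) == 2L,
            is.finite(universe), universe[1] < universe[2],
            is.list(sets), length(sets) >= 1L)
  ok <- vapply(sets, inherits, logical(1), what = "trapezoid_mf")
  if (!all(ok)) stop("all sets must be trapezoid_mf objects")
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("set names must be unique within a partition")
  names(sets) <- nm
  p <- structure(list(universe = as.numeric(universe), units = units,
                      sets = sets),
                 class = "fuzzy_partition")
  if (check_coverage) {
    n_uncov <- attr(partition_coverage_gap(p), "n_uncovered")
    if (n_uncov > 0)
      stop(sprintf("partition does not cover its universe [%g, %g]: %d sample point(s) have zero degree in every set",
                   universe[1], universe[2], n_uncov))
  }
  p
}

# Shortfall of max-set-degree below `floor`, sampled on a dense grid of the
# universe.  `n_uncovered` counts points with no positive degree at all (the
# coverage invariant proper); the summed shortfall against a small positive
# floor doubles as a smooth penalty during calibration, keeping fitted
# partitions covered with a margin so they re-validate on read.
partition_coverage_gap <- function(p, n = 201L, floor = 1e-3) {
  xs <- seq(p$universe[1], p$universe[2], length.out = n)
  degs <- vapply(p$sets, membership_degree, numeric(n), x = xs)
  mx <- if (is.matrix(degs)) apply(degs, 1L, max) else degs
  short <- pmax(0, floor - mx)
  structure(sum(short), n_uncovered = sum(mx <= 0))
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("<fuzzy_partition> universe [%g, %g] %s, %d sets: %s\n",
              x$universe[1], x$universe[2], x$units, length(x$sets),
              paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

#' Fuzzify a crisp value against a partition
#'
#' Returns the membership degree of `x` in every set of the partition.
#' Values outside the universe follow `policy`: `"zero"` (default) returns
#' all-zero degrees (no set activated), `"clamp"` evaluates at the nearest
#' universe bound.
#'
#' @param partition a [fuzzy_partition()].
#' @param x a single finite crisp value.
#' @param policy out-of-range policy, `"zero"` or `"clamp"`.
#' @return named numeric vector of degrees, one per set.
#' @export
fuzzify <- function(partition, x, policy = c("zero", "clamp")) {
  stopifnot(inherits(partition, "fuzzy_partition"), length(x) == 1L)
  if (!is.finite(x)) stop("fuzzify: x must be a finite number")
  policy <- match.arg(policy)
  lo <- partition$universe[1]; hi <- partition$universe[2]
  if (x < lo || x > hi) {
    if (policy == "zero")
      return(stats::setNames(numeric(length(partition$sets)),
                             names(partition$sets)))
    x <- min(max(x, lo), hi)
  }
  vapply(partition$sets, membership_degree, numeric(1), x = x)
}
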