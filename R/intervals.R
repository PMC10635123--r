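#' Ordered sets of disjoint half-open genomic intervals
#'
#' An `interval_set` is the inheritance annotation attached to a gARG edge:
#' an ordered list of disjoint half-open intervals `[left, right)` on the
#' genome. The canonical form is sorted by `left`, with abutting intervals
#' (`right[i] == left[i+1]`) merged, so equal sets of loci always have
#' identical representations and can be compared with `identical()`.
#'
#' @param left,right Numeric vectors of equal length; each pair is one
#'   half-open interval with `left < right`. Empty vectors give the empty set.
#' @return An object of class `interval_set`: a two-column numeric matrix
#'   with columns `left` and `right`, in canonical form.
#' @examples
#' interval_set(c(0, 5), c(3, 9))
#' interval_union(interval_set(0, 2), interval_set(2, 10))  # merges to [0,10)
#' @export
interval_set <- function(left = numeric(0), right = numeric(0)) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right)) {
    stop("left and right must have equal length")
  }
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    stop("interval endpoints must be finite")
  }
  if (any(left >= right)) {
    stop("each interval must satisfy left < right")
  }
  canonicalize_iset(cbind(left = left, right = right))
}

# Sort, merge overlapping and abutting intervals, set class.
canonicalize_iset <- function(m) {
  if (nrow(m) == 0) {
    return(empty_iset())
  }
  o <- order(m[, 1L], m[, 2L])
  l <- m[o, 1L]
  r <- m[o, 2L]
  out_l <- l[1L]
  out_r <- r[1L]
  k <- 1L
  if (length(l) > 1L) {
    for (i in 2L:length(l)) {
      if (l[i] <= out_r[k]) {
        # overlap or abutment: extend current interval
        if (r[i] > out_r[k]) out_r[k] <- r[i]
      } else {
        k <- k + 1L
        out_l[k] <- l[i]
        out_r[k] <- r[i]
      }
    }
  }
  structure(cbind(left = out_l, right = out_r), class = "interval_set")
}

empty_iset <- function() {
  structure(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("left", "right"))),
            class = "interval_set")
}

as_iset <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  if (is.matrix(x) && ncol(x) == 2L) return(canonicalize_iset(x))
  stop("cannot interpret object as an interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<empty interval set>\n")
  } else {
    cat("{", paste0("[", format(x[, 1L], trim = TRUE), ", ",
                    format(x[, 2L], trim = TRUE), ")", collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Total genomic span of an interval set
#'
#' @param x An `interval_set`.
#' @return The sum of interval lengths (0 for the empty set).
#' @export
interval_span <- function(x) {
  x <- as_iset(x)
  sum(x[, 2L] - x[, 1L])
}

#' Interval-set algebra
#'
#' Standard set operations on the loci covered by two interval sets. Results
#' are always in canonical form (sorted, disjoint, abutting intervals merged),
#' so two calls that cover the same loci return identical objects.
#'
#' @param a,b `interval_set` objects.
#' @return An `interval_set`.
#' @examples
#' interval_intersect(interval_set(2, 10), interval_set(0, 7))  # [2,7)
#' interval_subtract(interval_set(0, 10), interval_set(2, 7))   # [0,2), [7,10)
#' @export
interval_intersect <- function(a, b) {
  a <- as_iset(a)
  b <- as_iset(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_iset())
  out_l <- numeric(0)
  out_r <- numeric(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1L], b[j, 1L])
    hi <- min(a[i, 2L], b[j, 2L])
    if (lo < hi) {
      out_l <- c(out_l, lo)
      out_r <- c(out_r, hi)
    }
    # advance whichever interval ends first
    if (a[i, 2L] <= b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  if (length(out_l) == 0) return(empty_iset())
  canonicalize_iset(cbind(out_l, out_r))
}

#' @rdname interval_intersect
#' @export
interval_union <- function(a, b) {
  a <- as_iset(a)
  b <- as_iset(b)
  canonicalize_iset(rbind(unclass(a), unclass(b)))
}

#' @rdname interval_intersect
#' @export
interval_subtract <- function(a, b) {
  a <- as_iset(a)
  b <- as_iset(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out_l <- numeric(0)
  out_r <- numeric(0)
  j <- 1L
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1L]
    hi <- a[i, 2L]
    while (j <= nrow(b) && b[j, 2L] <= lo) j <- j + 1L
    jj <- j
    while (jj <= nrow(b) && b[jj, 1L] < hi) {
      if (b[jj, 1L] > lo) {
        out_l <- c(out_l, lo)
        out_r <- c(out_r, b[jj, 1L])
      }
      lo <- max(lo, b[jj, 2L])
      if (lo >= hi) break
      jj <- jj + 1L
    }
    if (lo < hi) {
      out_l <- c(out_l, lo)
      out_r <- c(out_r, hi)
    }
  }
  if (length(out_l) == 0) return(empty_iset())
  canonicalize_iset(cbind(out_l, out_r))
}

#' Does an interval set contain a position?
#'
#' @param x An `interval_set`.
#' @param pos A single genome position.
#' @return `TRUE` iff `pos` lies in one of the half-open intervals of `x`.
#' @export
interval_contains <- function(x, pos) {
  x <- as_iset(x)
  any(x[, 1L] <= pos & pos < x[, 2L])
}

# Union of a list of interval sets.
iset_union_all <- function(sets) {
  rows <- do.call(rbind, lapply(sets, unclass))
  if (is.null(rows) || nrow(rows) == 0) return(empty_iset())
  canonicalize_iset(rows)
}

# Loci covered by at least `k` of the given interval sets.
iset_covered_at_least <- function(sets, k) {
  rows <- do.call(rbind, lapply(sets, unclass))
  if (is.null(rows) || nrow(rows) == 0) return(empty_iset())
  pts <- sort(unique(c(rows[, 1L], rows[, 2L])))
  if (length(pts) < 2L) return(empty_iset())
  lo <- pts[-length(pts)]
  hi <- pts[-1L]
  cover <- vapply(seq_along(lo), function(i) {
    sum(rows[, 1L] <= lo[i] & rows[, 2L] >= hi[i])
  }, integer(1))
  keep <- cover >= k
  if (!any(keep)) return(empty_iset())
  canonicalize_iset(cbind(lo[keep], hi[keep]))
}

iset_equal <- function(a, b) {
  a <- as_iset(a)
  b <- as_iset(b)
  nrow(a) == nrow(b) && all(unclass(a) == unclass(b))
}
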