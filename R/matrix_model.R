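# Genus-resolved diagram expansion of the toy partition functions Z_n(a) and
# Z_n(a, N).  The Gaussian / Hermitian-matrix integrals behind these series
# are generating functions for chord-diagram counts; here the expansion is
# produced by exact exhaustive enumeration of partial matchings, each diagram
# weighted a^k N^(-2g) with k chords and genus g.  At N = 1 the genus grading
# collapses and the one-dimensional series is recovered.

#' Enumerate all partial chord matchings on n points
#'
#' Every way of drawing k = 0, 1, ... chords between \code{n} labeled
#' backbone points, each point used at most once.  The number of diagrams is
#' \eqn{\sum_k n! / (k! (n-2k)! 2^k)} (double-factorial growth), so the
#' point count is capped.  Enumeration order is deterministic: the smallest
#' free point is either left unpaired or paired with each larger free point
#' in ascending order.
#'
#' @param n number of backbone points.
#' @param perfect_only keep only perfect matchings (all points paired;
#'   requires even \code{n}); their count is \eqn{(n - 1)!!}.
#' @param cap refuse \code{n} above this bound (default 12).
#' @return list of \code{\link{chord_diagram}} objects.
#' @examples
#' length(enumerate_partial_matchings(4))                       # 10 diagrams
#' length(enumerate_partial_matchings(6, perfect_only = TRUE))  # 15 = 5!!
#' @export
enumerate_partial_matchings <- function(n, perfect_only = FALSE, cap = 12L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative", call. = FALSE)
  if (n > cap)
    stop("n = ", n, " exceeds the enumeration cap (", cap,
         "); raise `cap` explicitly to accept double-factorial growth",
         call. = FALSE)
  acc <- list()
  recurse <- function(free, arcs) {
    if (!length(free)) {
      acc[[length(acc) + 1L]] <<- arcs
      return(invisible())
    }
    p <- free[1L]
    if (!perfect_only) recurse(free[-1L], arcs)     # leave p unpaired
    for (q in free[-1L])
      recurse(setdiff(free, c(p, q)), rbind(arcs, c(p, q)))
    invisible()
  }
  recurse(seq_len(n), matrix(integer(0), ncol = 2L))
  lapply(acc, chord_diagram, n_points = n)
}

#' Genus-resolved expansion polynomial of Z_n(a, N)
#'
#' Tallies every partial matching of \code{n} points by (chord count k,
#' genus g).  The associated series is
#' \eqn{Z_n(a, N) = \sum_{k,g} c_{kg} \, a^k N^{-2g}}; for example
#' \eqn{Z_2 = 1 + a} and \eqn{Z_4 = 1 + 6a + 2a^2 + a^2/N^2}, whose planar
#' part survives the large-N limit while the genus-1 diagram is suppressed
#' by \eqn{1/N^2}.
#'
#' @inheritParams enumerate_partial_matchings
#' @return an object of class \code{expansion_poly}: a data frame with
#'   columns \code{k}, \code{g}, \code{count} (attribute \code{n} = point
#'   count).
#' @examples
#' expansion_polynomial(4)
#' @export
expansion_polynomial <- function(n, cap = 12L) {
  diags <- enumerate_partial_matchings(n, cap = cap)
  k <- vapply(diags, function(d) nrow(d$arcs), 1L)
  g <- vapply(diags, function(d) genus(d)$g, 1L)
  tab <- stats::aggregate(
    list(count = rep(1L, length(k))),
    by = list(k = k, g = g), FUN = sum)
  tab <- tab[order(tab$k, tab$g), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, n = as.integer(n),
            class = c("expansion_poly", "data.frame"))
}

#' Evaluate an expansion polynomial at (a, N)
#'
#' Computes \eqn{\sum_{k,g} c_{kg} a^k N^{-2g}}.  At \eqn{N = 1} this equals
#' the one-dimensional series \eqn{\sum_k (\sum_g c_{kg}) a^k}; as
#' \eqn{N \to \infty} only planar diagrams survive.
#'
#' @param poly an \code{\link{expansion_polynomial}} result.
#' @param a chord weight (propagator), positive real.
#' @param N matrix order, positive real; genus-g diagrams are weighted
#'   \eqn{N^{-2g}}.
#' @return numeric scalar.
#' @examples
#' evaluate_expansion(expansion_polynomial(4), a = 1, N = 1)  # 10 diagrams
#' @export
evaluate_expansion <- function(poly, a, N = 1) {
  stopifnot(inherits(poly, "expansion_poly"), a > 0, N > 0)
  sum(poly$count * a^poly$k * N^(-2 * poly$g))
}

#' @export
print.expansion_poly <- function(x, ...) {
  n <- attr(x, "n")
  terms <- ifelse(
    x$k == 0L, as.character(x$count),
    paste0(ifelse(x$count == 1L, "", x$count),
           "a", ifelse(x$k > 1L, paste0("^", x$k), ""),
           ifelse(x$g > 0L, paste0("/N^", 2L * x$g), "")))
  cat("Z_", n, "(a, N) = ", paste(terms, collapse = " + "), "\n", sep = "")
  cat("  (", sum(x$count), " partial matchings on ", n, " points)\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
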