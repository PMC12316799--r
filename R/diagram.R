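# Chord diagrams: backbone-ordered points with a partial matching of arcs,
# all arcs on one side of the backbone.  The combinatorial object whose genus
# is defined.

#' Construct a chord diagram
#'
#' @param arcs two-column integer matrix of arcs (a partial matching: each
#'   point in at most one arc), or \code{NULL} for an empty diagram.
#' @param n_points number of backbone points; defaults to the largest arc
#'   endpoint.
#' @return an object of class \code{chord_diagram}.
#' @examples
#' chord_diagram(rbind(c(1, 3), c(2, 4)))   # the crossing pair
#' @export
chord_diagram <- function(arcs = NULL, n_points = NULL) {
  arcs <- normalize_pairs(arcs)
  if (is.null(n_points)) n_points <- if (nrow(arcs)) max(arcs) else 0L
  n_points <- as.integer(n_points)
  if (nrow(arcs)) {
    if (max(arcs) > n_points || min(arcs) < 1L)
      stop("arc endpoint outside [1, n_points]", call. = FALSE)
    idx <- as.vector(arcs)
    if (anyDuplicated(idx))
      stop("arcs do not form a partial matching (shared endpoint)",
           call. = FALSE)
  }
  structure(list(n_points = n_points, arcs = arcs), class = "chord_diagram")
}

#' Convert a secondary structure to its chord diagram
#'
#' The backbone is stretched to a line (equivalently a circle) and each base
#' pair becomes an arc.  Unpaired vertices are isolated points that do not
#' affect the topology; by default they are dropped and paired positions are
#' relabeled \code{1..2m} preserving backbone order.  Keep them when absolute
#' positions matter (genus trace, fingerprint windows).
#'
#' @param s an \code{\link{rna_structure}} (or a chord diagram, returned
#'   unchanged).
#' @param keep_unpaired retain unpaired backbone points (default
#'   \code{FALSE}).
#' @return a \code{\link{chord_diagram}}.
#' @export
as_chord_diagram <- function(s, keep_unpaired = FALSE) {
  if (inherits(s, "chord_diagram")) return(s)
  stopifnot(inherits(s, "rna_structure"))
  p <- s$pairs
  if (keep_unpaired) return(chord_diagram(p, n_points = s$length))
  if (!nrow(p)) return(chord_diagram(NULL, n_points = 0L))
  kept <- sort(unique(as.vector(p)))
  relabel <- match(p, kept)
  chord_diagram(matrix(relabel, ncol = 2L), n_points = length(kept))
}

#' Arc crossings of a chord diagram
#'
#' Two arcs \eqn{(i, j)} and \eqn{(k, l)} cross when \eqn{i < k < j < l}:
#' they cannot be drawn on the same side of the backbone without
#' intersecting.  Crossing chords are the diagrammatic signature of a
#' pseudoknot.
#'
#' @param d a \code{\link{chord_diagram}} (or anything
#'   \code{\link{as_chord_diagram}} accepts).
#' @return integer matrix with columns \code{arc1}, \code{arc2} (row indices
#'   into \code{d$arcs}), one row per crossing pair.
#' @export
arc_crossings <- function(d) {
  d <- as_chord_diagram(d)
  a <- d$arcs
  m <- nrow(a)
  out <- list()
  if (m >= 2) {
    for (u in seq_len(m - 1L)) for (v in seq.int(u + 1L, m)) {
      i <- a[u, 1L]; j <- a[u, 2L]; k <- a[v, 1L]; l <- a[v, 2L]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
        out[[length(out) + 1L]] <- c(u, v)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else matrix(integer(0), ncol = 2L)
  dimnames(res) <- list(NULL, c("arc1", "arc2"))
  res
}

#' @rdname arc_crossings
#' @return \code{is_planar}: \code{TRUE} iff the diagram has no crossing
#'   (equivalently genus 0).
#' @export
is_planar <- function(d) nrow(arc_crossings(d)) == 0L

#' Collapse parallel arcs (stems) to single arcs
#'
#' A maximal run of parallel arcs \eqn{(i, j), (i+1, j-1), \ldots} — a helix
#' in RNA terms — is replaced by one arc, yielding the \emph{shadow} of the
#' diagram.  The operation preserves genus and is idempotent.
#'
#' @param d a \code{\link{chord_diagram}}.
#' @return the collapsed \code{\link{chord_diagram}} (points relabeled
#'   \code{1..2m'}).
#' @export
collapse_parallel <- function(d) {
  d <- as_chord_diagram(d)
  repeat {
    a <- d$arcs
    if (!nrow(a)) return(d)
    keep <- logical(nrow(a))
    has <- paste(a[, 1L], a[, 2L]) # membership of (i+1, j-1) tested by key
    for (r in seq_len(nrow(a))) {
      inner <- paste(a[r, 1L] + 1L, a[r, 2L] - 1L)
      keep[r] <- !(inner %in% has) # keep only the innermost arc of each run
    }
    d2 <- as_chord_diagram(rna_structure(a[keep, , drop = FALSE],
                                         length = d$n_points))
    # relabeling can bring formerly separated parallel arcs together;
    # iterate until the shadow is stable
    if (identical(d2$arcs, d$arcs)) return(d2)
    d <- d2
  }
}

#' Concatenate or nest two chord diagrams
#'
#' \code{concat_diagrams} places the points of \code{d2} after those of
#' \code{d1} on the backbone; \code{nest_diagrams} inserts \code{d2}'s points
#' strictly inside the first arc of \code{d1} (immediately after its left
#' endpoint).  In both cases the two arc sets cannot cross each other, so
#' genus is additive: \eqn{g(d_1 \circ d_2) = g(d_1) + g(d_2)}.
#'
#' @param d1,d2 \code{\link{chord_diagram}} objects.
#' @return a \code{\link{chord_diagram}} on \code{d1$n_points + d2$n_points}
#'   points.
#' @export
concat_diagrams <- function(d1, d2) {
  d1 <- as_chord_diagram(d1); d2 <- as_chord_diagram(d2)
  chord_diagram(rbind(d1$arcs, d2$arcs + d1$n_points),
                n_points = d1$n_points + d2$n_points)
}

#' @rdname concat_diagrams
#' @export
nest_diagrams <- function(d1, d2) {
  d1 <- as_chord_diagram(d1); d2 <- as_chord_diagram(d2)
  if (!nrow(d1$arcs))
    stop("cannot nest inside a diagram with no arcs", call. = FALSE)
  at <- d1$arcs[1L, 1L]               # insert just inside the first arc
  k <- d2$n_points
  shift <- function(x) ifelse(x > at, x + k, x)
  chord_diagram(rbind(matrix(shift(d1$arcs), ncol = 2L), d2$arcs + at),
                n_points = d1$n_points + k)
}

#' @export
print.chord_diagram <- function(x, ...) {
  cat("Chord diagram:", x$n_points, "points,", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs))
    cat("  arcs:", paste0("(", x$arcs[, 1L], ",", x$arcs[, 2L], ")",
                          collapse = " "), "\n")
  invisible(x)
}
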