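# Genus of a chord diagram via fat-graph boundary counting.
#
# Thicken the diagram in double-line notation: the backbone becomes the
# boundary of a disk, each arc a ribbon.  The number b of boundary components
# of the resulting surface is the number of cycles of the permutation
# sigma . alpha, where sigma is the backbone cycle (1 2 ... 2m) and alpha the
# product of the arc transpositions.  Filling each boundary with a disk gives
# a closed orientable surface of genus g = (m - b + 1) / 2.

#' Boundary components of the thickened (fat-graph) diagram
#'
#' Counts the cycles of \eqn{\sigma \circ \alpha} on the paired points
#' relabeled \code{1..2m}, where \eqn{\sigma} is the backbone cycle and
#' \eqn{\alpha} the arc involution.  The count is invariant under using the
#' consistent alternative composition \eqn{\alpha \circ \sigma}.
#'
#' @param d a \code{\link{chord_diagram}} (unpaired points are dropped
#'   first).
#' @return integer count; 1 for the empty diagram (the bare disk boundary).
#' @examples
#' boundary_components(chord_diagram(rbind(c(1, 2))))        # 2: a disk
#' boundary_components(chord_diagram(rbind(c(1, 3), c(2, 4)))) # 1: a torus
#' @export
boundary_components <- function(d) {
  d <- restrict_to_paired(d)
  m <- nrow(d$arcs)
  if (m == 0L) return(1L)
  n <- 2L * m
  alpha <- integer(n)
  alpha[d$arcs[, 1L]] <- d$arcs[, 2L]
  alpha[d$arcs[, 2L]] <- d$arcs[, 1L]
  sigma_after_alpha <- alpha %% n + 1L  # x -> sigma(alpha(x))
  count_cycles(sigma_after_alpha)
}

restrict_to_paired <- function(d) {
  d <- as_chord_diagram(d)
  if (!nrow(d$arcs)) return(chord_diagram(NULL, 0L))
  kept <- sort(unique(as.vector(d$arcs)))
  if (length(kept) == d$n_points) return(d)
  chord_diagram(matrix(match(d$arcs, kept), ncol = 2L),
                n_points = length(kept))
}

count_cycles <- function(perm) {
  seen <- logical(length(perm))
  cycles <- 0L
  for (start in seq_along(perm)) {
    if (seen[start]) next
    cycles <- cycles + 1L
    x <- start
    while (!seen[x]) { seen[x] <- TRUE; x <- perm[x] }
  }
  cycles
}

#' Topological genus of a structure or chord diagram
#'
#' The genus of a diagram is the genus of the orientable surface of lowest
#' genus on which it can be drawn without arc crossings: 0 for planar
#' (pseudoknot-free) structures, 1 for an H-type pseudoknot or a kissing
#' hairpin, and so on.  It is computed from the boundary-component count
#' \eqn{b} of the fat graph as \eqn{g = (m - b + 1)/2} with \eqn{m} arcs.
#' The Euler characteristic is reported under the one-puncture convention
#' \eqn{\chi = 2 - 2g - p} with \eqn{p = 1} (one closed backbone), hence
#' \eqn{\chi = 1 - 2g}; the kissing hairpin has \eqn{g = 1},
#' \eqn{\chi = -1}.
#'
#' @param x an \code{\link{rna_structure}}, a \code{\link{chord_diagram}}, or
#'   a two-column pair matrix.
#' @param ... unused.
#' @return an object of class \code{rna_genus}: list with \code{m} (arcs),
#'   \code{b} (boundary components), \code{g} (genus) and \code{chi}.
#' @examples
#' kh <- chord_diagram(rbind(c(1, 3), c(2, 5), c(4, 6)))  # kissing hairpin
#' genus(kh)
#' @export
genus <- function(x, ...) UseMethod("genus")

#' @export
genus.chord_diagram <- function(x, ...) {
  d <- restrict_to_paired(x)
  m <- nrow(d$arcs)
  b <- boundary_components(d)
  g <- (m - b + 1L) %/% 2L
  stopifnot((m - b + 1L) %% 2L == 0L, g >= 0L)
  structure(list(m = m, b = b, g = g, chi = 1L - 2L * g),
            class = "rna_genus")
}

#' @export
genus.rna_structure <- function(x, ...) genus(as_chord_diagram(x))

#' @export
genus.matrix <- function(x, ...) genus(chord_diagram(x))

#' @export
print.rna_genus <- function(x, ...) {
  cat("genus g =", x$g, " (m =", x$m, "arcs, b =", x$b,
      "boundary components, chi =", x$chi, ")\n")
  invisible(x)
}

#' Genus trace along the backbone
#'
#' The genus trace \eqn{g(i)} is the genus of the sub-structure restricted to
#' the first \eqn{i} residues (pairs with both endpoints \eqn{\le i}).  It is
#' non-decreasing in \eqn{i} and reaches the total genus at \eqn{i = L};
#' jumps localize where pseudoknotted domains close.
#'
#' @param s an \code{\link{rna_structure}}.
#' @return an integer vector of class \code{genus_trace}, one entry per
#'   backbone position.
#' @export
genus_trace <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  p <- s$pairs
  out <- integer(s$length)
  if (nrow(p)) {
    # recompute only where an arc closes; genus is constant in between
    g_cur <- 0L
    closings <- sort(unique(p[, 2L]))
    last <- 0L
    for (j in closings) {
      if (j > last + 1L && last >= 1L) out[(last + 1L):(j - 1L)] <- g_cur
      if (last == 0L && j > 1L) out[1:(j - 1L)] <- 0L
      sub <- p[p[, 2L] <= j, , drop = FALSE]
      g_cur <- genus(chord_diagram(sub, n_points = s$length))$g
      out[j] <- g_cur
      last <- j
    }
    if (last < s$length) out[(last + 1L):s$length] <- g_cur
  }
  structure(out, class = "genus_trace")
}

#' @export
print.genus_trace <- function(x, ...) {
  cat("Genus trace over", length(x), "positions; final genus",
      if (length(x)) x[length(x)] else 0L, "\n")
  print(unclass(x))
  invisible(x)
}

#' @export
plot.genus_trace <- function(x, ...) {
  graphics::plot(seq_along(x), as.integer(x), type = "s",
                 xlab = "position", ylab = "genus g(i)", ...)
  invisible(x)
}

#' Fingerprint matrix of windowed genus values
#'
#' The fingerprint matrix \eqn{G = (g_{ij})} holds the genus of every
#' sub-chain \eqn{[i..j]} (pairs with both endpoints inside the window),
#' defined for \eqn{i \le j}; entries below the diagonal are \code{NA}.  Row
#' 1 equals the genus trace.  Monotone under window inclusion:
#' \eqn{[i..j] \subseteq [i'..j'] \Rightarrow g_{ij} \le g_{i'j'}}.
#'
#' @param s an \code{\link{rna_structure}}.
#' @param cap maximum backbone length accepted (the computation costs
#'   \eqn{O(L^2)} genus evaluations); raise it explicitly for long chains.
#' @return an \code{L x L} integer matrix of class \code{genus_fingerprint}.
#' @export
genus_fingerprint <- function(s, cap = 500L) {
  stopifnot(inherits(s, "rna_structure"))
  L <- s$length
  if (L > cap)
    stop("backbone length ", L, " exceeds the fingerprint cap (", cap,
         "); pass a larger `cap` to accept the O(L^2) cost", call. = FALSE)
  G <- matrix(NA_integer_, L, L)
  p <- s$pairs
  for (i in seq_len(L)) {
    inside_i <- p[p[, 1L] >= i, , drop = FALSE]
    for (j in i:L) {
      sub <- inside_i[inside_i[, 2L] <= j, , drop = FALSE]
      G[i, j] <- if (nrow(sub)) genus(chord_diagram(sub, n_points = L))$g
                 else 0L
    }
  }
  structure(G, class = c("genus_fingerprint", "matrix"))
}

#' @export
print.genus_fingerprint <- function(x, ...) {
  cat("Fingerprint matrix (", nrow(x), "x", ncol(x), "), total genus",
      x[1L, ncol(x)], "\n")
  print(unclass(x))
  invisible(x)
}
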