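# Synthetic fixtures with known topology: pseudoknot geometries, random
# matchings, and controlled-genus structures built by concatenating and
# nesting genus-1 blocks.  Every generator's output is checked against the
# genus engine by the test suite, so fixtures never rely on downloads.

#' Kissing-hairpin fixture
#'
#' Two hairpins whose loops pair with each other: stems 1 and 2 close the
#' hairpins, stem 3 (the kissing interaction) joins the loops.  The shadow
#' (stems collapsed to single arcs) is \{(1,3),(2,5),(4,6)\}, the canonical
#' genus-1 diagram; the fixture has genus 1 for any stem lengths.
#'
#' @param stems lengths (pair counts) of hairpin-1, hairpin-2 and kissing
#'   stems.
#' @param loops unpaired spacer lengths: within loop 1 before/after the
#'   kissing block, the inter-hairpin linker, and within loop 2
#'   before/after its kissing block (5 values, recycled).
#' @param design_sequence attach a GC-rich designed sequence whose
#'   helipoints reproduce the three stems (kissing stem alternates A/U).
#' @return an \code{\link{rna_structure}} of genus 1.
#' @examples
#' genus(make_kissing_hairpin())$g   # 1
#' @export
make_kissing_hairpin <- function(stems = c(3L, 3L, 3L),
                                 loops = c(3L, 3L, 3L, 3L, 3L),
                                 design_sequence = FALSE) {
  stopifnot(length(stems) == 3L, all(stems >= 1L))
  loops <- rep_len(as.integer(loops), 5L)
  if (any(loops < 0L)) stop("loop lengths must be non-negative", call. = FALSE)
  s1 <- stems[1L]; s2 <- stems[2L]; s3 <- stems[3L]
  # segment layout: S1 l1 K1 l2 S1' l3 S2 l4 K2 l5 S2'
  seg_len <- c(s1, loops[1L], s3, loops[2L], s1, loops[3L],
               s2, loops[4L], s3, loops[5L], s2)
  start <- cumsum(c(1L, seg_len[-length(seg_len)]))
  span <- function(k) seq.int(start[k], length.out = seg_len[k])
  pairs <- rbind(
    cbind(span(1L), rev(span(5L))),   # hairpin 1 stem
    cbind(span(3L), rev(span(9L))),   # kissing stem
    cbind(span(7L), rev(span(11L))))  # hairpin 2 stem
  L <- sum(seg_len)
  seq <- ""
  if (design_sequence) {
    b <- rep("A", L)
    b[span(1L)] <- alternating(c("G", "C"), s1)
    b[span(5L)] <- complement(rev(b[span(1L)]))
    b[span(7L)] <- alternating(c("C", "G"), s2)
    b[span(11L)] <- complement(rev(b[span(7L)]))
    b[span(3L)] <- alternating(c("A", "U"), s3)
    b[span(9L)] <- complement(rev(b[span(3L)]))
    for (k in c(2L, 4L, 6L, 8L, 10L)) if (seg_len[k]) b[span(k)] <- "A"
    seq <- paste(b, collapse = "")
  }
  rna_structure(pairs, length = L, sequence = seq)
}

alternating <- function(chars, n) rep_len(chars, n)
complement <- function(b) c(A = "U", U = "A", G = "C", C = "G")[b]

#' H-type pseudoknot fixture
#'
#' A hairpin stem whose loop pairs downstream: shadow \{(1,3),(2,4)\}, the
#' minimal crossing diagram, genus 1.
#'
#' @param stems lengths of the two stems.
#' @param loops unpaired spacers between the four stem segments (3 values,
#'   recycled).
#' @param design_sequence attach a designed sequence (stem 1 GC, stem 2
#'   CG-alternating).
#' @return an \code{\link{rna_structure}} of genus 1.
#' @export
make_h_pseudoknot <- function(stems = c(3L, 3L), loops = c(3L, 3L, 3L),
                              design_sequence = FALSE) {
  stopifnot(length(stems) == 2L, all(stems >= 1L))
  loops <- rep_len(as.integer(loops), 3L)
  s1 <- stems[1L]; s2 <- stems[2L]
  seg_len <- c(s1, loops[1L], s2, loops[2L], s1, loops[3L], s2)
  start <- cumsum(c(1L, seg_len[-length(seg_len)]))
  span <- function(k) seq.int(start[k], length.out = seg_len[k])
  pairs <- rbind(cbind(span(1L), rev(span(5L))),
                 cbind(span(3L), rev(span(7L))))
  L <- sum(seg_len)
  seq <- ""
  if (design_sequence) {
    b <- rep("A", L)
    b[span(1L)] <- alternating(c("G", "C"), s1)
    b[span(5L)] <- complement(rev(b[span(1L)]))
    b[span(3L)] <- alternating(c("U", "A"), s2)
    b[span(7L)] <- complement(rev(b[span(3L)]))
    seq <- paste(b, collapse = "")
  }
  rna_structure(pairs, length = L, sequence = seq)
}

#' Simple hairpin fixture
#'
#' @param stem stem length (pairs); @param loop loop length (unpaired).
#' @param design_sequence attach a \code{G...A...C...} sequence.
#' @return a planar \code{\link{rna_structure}} (genus 0).
#' @export
make_hairpin <- function(stem = 3L, loop = 3L, design_sequence = FALSE) {
  stopifnot(stem >= 1L, loop >= 0L)
  L <- 2L * stem + loop
  pairs <- cbind(seq_len(stem), L + 1L - seq_len(stem))
  seq <- if (design_sequence)
    paste(c(rep("G", stem), rep("A", loop), rep("C", stem)), collapse = "")
  else ""
  rna_structure(pairs, length = L, sequence = seq)
}

#' Two-domain fixture: two genus-1 blocks in series
#'
#' Concatenates two kissing-hairpin blocks separated by an unpaired linker;
#' total genus 2, with the genus trace rising by one unit as each domain
#' closes.  Used to exercise plateau detection in trace summaries.
#'
#' @param linker unpaired spacer between the domains.
#' @param ... passed to \code{\link{make_kissing_hairpin}} for each domain.
#' @return an \code{\link{rna_structure}} of genus 2.
#' @export
make_two_domain <- function(linker = 5L, ...) {
  d <- make_kissing_hairpin(...)
  off <- d$length + as.integer(linker)
  rna_structure(rbind(d$pairs, d$pairs + off),
                length = d$length + off)
}

#' Uniform random partial matching
#'
#' Draws uniformly among all chord diagrams on \code{n_points} points with
#' exactly \code{n_chords} chords: the 2k matched points are a uniform
#' subset and the matching on them is uniform (smallest remaining point
#' paired with a uniform other).
#'
#' @param n_points backbone points.
#' @param n_chords chords to draw (\code{2 n_chords <= n_points}).
#' @param seed optional seed (RNG state is restored afterwards); when
#'   \code{NULL} the current RNG stream is used.
#' @return a \code{\link{chord_diagram}}.
#' @export
random_matching <- function(n_points, n_chords, seed = NULL) {
  n_points <- as.integer(n_points); n_chords <- as.integer(n_chords)
  if (2L * n_chords > n_points)
    stop("cannot place ", n_chords, " chords on ", n_points, " points",
         call. = FALSE)
  draw <- function() {
    pts <- sort(sample.int(n_points, 2L * n_chords))
    arcs <- matrix(integer(0), ncol = 2L)
    while (length(pts)) {
      p <- pts[1L]
      q <- if (length(pts) == 2L) pts[2L] else sample(pts[-1L], 1L)
      arcs <- rbind(arcs, c(p, q))
      pts <- setdiff(pts, c(p, q))
    }
    chord_diagram(arcs, n_points = n_points)
  }
  if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
}

#' Random structure with a prescribed genus
#'
#' Builds a structure of exact genus \code{target_g} by concatenating
#' \code{target_g} irreducible genus-1 blocks (a crossing pair or a
#' kissing-hairpin shadow, chosen at random) interleaved with planar filler
#' (nested stems and unpaired stretches).  Genus additivity under
#' concatenation guarantees the target is met exactly.
#'
#' @param target_g desired genus (non-negative integer).
#' @param filler number of planar filler blocks interleaved (default 2).
#' @param seed optional seed (RNG state restored).
#' @return an \code{\link{rna_structure}} with
#'   \code{genus(x)$g == target_g}.
#' @export
random_structure_with_genus <- function(target_g, filler = 2L, seed = NULL) {
  target_g <- as.integer(target_g)
  stopifnot(target_g >= 0L, filler >= 0L)
  build <- function() {
    blocks <- list()
    for (k in seq_len(target_g)) {
      blocks[[length(blocks) + 1L]] <-
        if (stats::runif(1) < 0.5) rbind(c(1L, 3L), c(2L, 4L))
        else rbind(c(1L, 3L), c(2L, 5L), c(4L, 6L))
    }
    for (k in seq_len(filler)) {
      depth <- sample.int(3L, 1L)  # nested stem of 1..3 arcs
      blocks[[length(blocks) + 1L]] <-
        cbind(seq_len(depth), 2L * depth + 1L - seq_len(depth))
    }
    if (length(blocks) > 1L) blocks <- blocks[sample.int(length(blocks))]
    pairs <- matrix(integer(0), ncol = 2L)
    off <- 0L
    for (bl in blocks) {
      gap <- sample.int(3L, 1L)   # unpaired spacer before each block
      off <- off + gap
      pairs <- rbind(pairs, bl + off)
      off <- off + max(bl)
    }
    rna_structure(pairs, length = off + sample.int(3L, 1L))
  }
  if (is.null(seed)) build() else with_preserved_rng(seed, build())
}
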