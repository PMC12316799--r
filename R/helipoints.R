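# Helipoint enumeration.  A helipoint is a stem-like block of base pairs:
# consecutive pairs (i, j), (i', j') step by (i' - i, j - j') in
# {(1,1) stack, (1,2)/(2,1) size-1 bulge, (2,2) 1x1 internal loop}.
# Helipoints are the elementary add/remove unit of the folding Monte Carlo.

#' Enumerate maximal helipoints of a sequence
#'
#' Finds every maximal stem — a run of base pairs allowing size-1 bulges and
#' 1x1 internal loops that cannot be extended at either end — with at least
#' \code{min_pairs} pairs and a negative free energy under \code{model}.
#' The free energy of a helipoint is the sum of stacking terms over its
#' (1,1) steps plus the bulge / internal-loop penalties.
#'
#' @param sequence RNA string over \code{A,C,G,U}.
#' @param model an \code{\link{energy_model}}.
#' @param min_pairs minimum number of pairs per helipoint (default 3).
#' @param allow_gu admit GU wobble pairs (default \code{FALSE}: canonical
#'   cWW AU/GC only).
#' @param min_loop minimum number of unpaired bases in a hairpin loop, i.e.
#'   every pair satisfies \eqn{j - i > } \code{min_loop} (default 3).
#' @param max_helipoints refuse to return more than this many (guards the
#'   worst-case combinatorial blowup of defect-containing stems).
#' @return list of helipoints; each has \code{pairs} (two-column matrix) and
#'   \code{dF} (kcal/mol).
#' @examples
#' h <- enumerate_helipoints("GGGAAACCC")
#' h[[1]]$pairs
#' @export
enumerate_helipoints <- function(sequence, model = energy_model(),
                                 min_pairs = 3L, allow_gu = FALSE,
                                 min_loop = 3L, max_helipoints = 10000L) {
  seq <- clean_sequence(sequence)
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  ok <- allowed_pair_types(allow_gu)
  # candidate pairs
  cand <- list()
  for (i in seq_len(max(0L, n - min_loop - 1L)))
    for (j in seq.int(i + min_loop + 1L, n))
      if (paste0(b[i], b[j]) %in% ok)
        cand[[length(cand) + 1L]] <- c(i, j)
  if (!length(cand)) return(list())
  cm <- do.call(rbind, cand)
  key <- function(i, j) paste(i, j)
  idx <- stats::setNames(seq_len(nrow(cm)), key(cm[, 1L], cm[, 2L]))
  steps <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  succ <- function(r) {
    i <- cm[r, 1L]; j <- cm[r, 2L]
    out <- integer(0)
    for (s in seq_len(4L)) {
      k <- idx[key(i + steps[s, 1L], j - steps[s, 2L])]
      if (!is.na(k)) out <- c(out, k)
    }
    out
  }
  succs <- lapply(seq_len(nrow(cm)), succ)
  has_pred <- logical(nrow(cm))
  has_pred[unlist(succs)] <- TRUE
  out <- list()
  walk <- function(path) {
    nxt <- succs[[path[length(path)]]]
    if (!length(nxt)) {
      if (length(path) >= min_pairs) {
        hp <- helipoint_from_rows(cm, path, b, model)
        if (hp$dF < 0) out[[length(out) + 1L]] <<- hp
        if (length(out) > max_helipoints)
          stop("more than ", max_helipoints, " helipoints; raise ",
               "`max_helipoints` or `min_pairs`", call. = FALSE)
      }
      return(invisible())
    }
    for (k in nxt) walk(c(path, k))
    invisible()
  }
  for (r in which(!has_pred)) walk(r)
  out
}

helipoint_from_rows <- function(cm, rows, bases, model) {
  pairs <- cm[rows, , drop = FALSE]
  dF <- 0
  n_b <- 0L; n_il <- 0L
  for (t in seq_len(nrow(pairs) - 1L)) {
    di <- pairs[t + 1L, 1L] - pairs[t, 1L]
    dj <- pairs[t, 2L] - pairs[t + 1L, 2L]
    if (di == 1L && dj == 1L) {
      p1 <- paste0(bases[pairs[t, 1L]], bases[pairs[t, 2L]])
      p2 <- paste0(bases[pairs[t + 1L, 1L]], bases[pairs[t + 1L, 2L]])
      dF <- dF + stack_energy(model, p1, p2)
    } else if (di == 2L && dj == 2L) {
      n_il <- n_il + 1L
      dF <- dF + model$internal11
    } else {
      n_b <- n_b + 1L
      dF <- dF + model$bulge1
    }
  }
  list(pairs = pairs, dF = dF, n_bulge = n_b, n_internal = n_il)
}

# positions used by a helipoint
helipoint_positions <- function(hp) as.vector(hp$pairs)

# TRUE iff no base is shared between the two helipoints
helipoints_compatible <- function(h1, h2)
  !any(helipoint_positions(h1) %in% helipoint_positions(h2))
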