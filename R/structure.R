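#' Construct a pseudoknotted RNA secondary structure
#'
#' The internal representation of a secondary structure is the sparse form of
#' the contact matrix: a set of base pairs \eqn{(i, j)} with \eqn{i < j},
#' 1-based along the backbone, where every position participates in at most
#' one pair.  The sequence is optional: topology-only structures (for example
#' those read from pairing annotations without sequence) carry an empty
#' sequence string.
#'
#' @param pairs a two-column integer matrix (or an empty/\code{NULL} value for
#'   an unpaired chain); each row is one base pair, in either column order.
#' @param length backbone length; must be at least the largest index used by
#'   \code{pairs}.  Defaults to the largest paired index (or 0 for no pairs)
#'   when the sequence is empty, otherwise to the sequence length.
#' @param sequence optional string over \code{A,C,G,U}; when non-empty its
#'   number of characters must equal \code{length}.
#' @return an object of class \code{rna_structure} with elements
#'   \code{sequence}, \code{pairs} (sorted two-column matrix, \code{i < j})
#'   and \code{length}.
#' @examples
#' s <- rna_structure(rbind(c(1, 6), c(2, 5)), length = 6)
#' genus(s)$g
#' @export
rna_structure <- function(pairs = NULL, length = NULL, sequence = "") {
  pairs <- normalize_pairs(pairs)
  sequence <- toupper(as.character(sequence %||% ""))
  if (is.na(sequence)) sequence <- ""
  if (is.null(length)) {
    length <- if (nzchar(sequence)) nchar(sequence)
              else if (nrow(pairs)) max(pairs) else 0L
  }
  length <- as.integer(length)
  x <- structure(
    list(sequence = sequence, pairs = pairs, length = length),
    class = "rna_structure"
  )
  validate_rna_structure(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0) ||
      (!is.matrix(pairs) && !length(pairs))) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2L)
  storage.mode(pairs) <- "integer"
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

validate_rna_structure <- function(x) {
  p <- x$pairs
  if (anyNA(p)) stop("pairs contain NA indices", call. = FALSE)
  if (nrow(p)) {
    if (any(p[, 1L] == p[, 2L]))
      stop("a base cannot pair with itself", call. = FALSE)
    if (min(p) < 1L || max(p) > x$length)
      stop("pair index outside [1, length]", call. = FALSE)
    idx <- as.vector(p)
    dup <- idx[duplicated(idx)]
    if (length(dup))
      stop("position(s) ", paste(sort(unique(dup)), collapse = ", "),
           " participate in more than one pair", call. = FALSE)
  }
  if (nzchar(x$sequence)) {
    if (nchar(x$sequence) != x$length)
      stop("sequence length (", nchar(x$sequence),
           ") does not match declared length (", x$length, ")", call. = FALSE)
    bad <- gsub("[ACGU]", "", x$sequence)
    if (nzchar(bad))
      stop("sequence contains non-ACGU character(s): ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""),
           "; see clean_sequence() for the replacement policy", call. = FALSE)
  }
  x
}

#' Sanitize an RNA sequence with the ribonucleotide replacement policy
#'
#' Databases annotate modified or ambiguous residues with extra letters.  The
#' replacement policy maps N (unknown), X (xanthosine), F (fluorouridine) and
#' M (adenosine or cytidine) to A, and V (adenosine, cytidine or guanosine)
#' to G; T is read as U.  The default is to reject anything outside
#' \code{A,C,G,U} so that silent substitutions never happen unnoticed.
#'
#' @param sequence character string.
#' @param replace apply the replacement policy (default \code{FALSE} =
#'   reject); when \code{TRUE} every substitution is reported via
#'   \code{message()}.
#' @return sanitized uppercase sequence over \code{A,C,G,U}.
#' @export
clean_sequence <- function(sequence, replace = FALSE) {
  s <- toupper(gsub("\\s", "", sequence))
  s <- gsub("T", "U", s)
  bad <- unique(strsplit(gsub("[ACGU]", "", s), "")[[1]])
  if (!length(bad)) return(s)
  if (!replace)
    stop("sequence contains non-ACGU character(s): ",
         paste(bad, collapse = ""),
         " (set replace = TRUE to apply the N,X,F,M->A / V->G policy)",
         call. = FALSE)
  map <- c(N = "A", X = "A", F = "A", M = "A", V = "G")
  unknown <- setdiff(bad, names(map))
  if (length(unknown))
    stop("no replacement rule for character(s): ",
         paste(unknown, collapse = ""), call. = FALSE)
  for (ch in intersect(bad, names(map))) {
    message("replacing ", sum(strsplit(s, "")[[1]] == ch), "x '", ch,
            "' with '", map[[ch]], "'")
    s <- gsub(ch, map[[ch]], s, fixed = TRUE)
  }
  s
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: length", x$length, "-", nrow(x$pairs),
      "base pairs\n")
  if (nzchar(x$sequence)) cat("  seq: ", abbreviate_seq(x$sequence), "\n",
                              sep = "")
  if (x$length && x$length <= 200) {
    db <- tryCatch(write_dotbracket(x), error = function(e) NULL)
    if (!is.null(db)) cat("  str: ", db, "\n", sep = "")
  }
  g <- genus(x)
  cat("  genus", g$g, "(", g$m, "arcs,", g$b, "boundary components )\n")
  invisible(x)
}

abbreviate_seq <- function(s, max = 60) {
  if (nchar(s) <= max) s else paste0(substr(s, 1, max - 3), "...")
}
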