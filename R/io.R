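# Readers/writers for extended dot-bracket, BPSEQ and CT.
# Coordinates are 1-based and inclusive throughout, the BPSEQ/CT convention.

# Bracket families, in the order deeper crossing layers are consumed:
# ( ), [ ], { }, < >, then Aa, Bb, ... Zz.
bracket_open  <- c("(", "[", "{", "<", LETTERS)
bracket_close <- c(")", "]", "}", ">", letters)

#' Parse an extended dot-bracket string
#'
#' Pseudoknotted structures need more than one bracket family: arcs that cross
#' are written with different families, each matched by an independent stack
#' discipline.  \code{.}, \code{-} and \code{:} denote unpaired positions.
#' Supported families, in layer order: \code{()}, \code{[]}, \code{\{\}},
#' \code{<>}, then \code{Aa}, \code{Bb}, ... for deeper crossing layers.
#'
#' @param text dot-bracket string.
#' @param sequence optional sequence of the same length.
#' @return an \code{\link{rna_structure}}.
#' @examples
#' read_dotbracket("((..))")$pairs
#' read_dotbracket("([)]")$pairs   # one crossing, two families
#' @export
read_dotbracket <- function(text, sequence = "") {
  chars <- strsplit(gsub("\\s", "", text), "")[[1]]
  stacks <- vector("list", length(bracket_open))
  pairs <- list()
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    if (ch %in% c(".", "-", ":")) next
    fam <- match(ch, bracket_open)
    if (!is.na(fam)) {
      stacks[[fam]] <- c(stacks[[fam]], pos)
      next
    }
    fam <- match(ch, bracket_close)
    if (is.na(fam))
      stop("unknown character '", ch, "' at position ", pos, call. = FALSE)
    st <- stacks[[fam]]
    if (!length(st))
      stop("unbalanced '", ch, "' at position ", pos, " (family ",
           bracket_open[fam], bracket_close[fam], ")", call. = FALSE)
    pairs[[length(pairs) + 1L]] <- c(st[length(st)], pos)
    stacks[[fam]] <- st[-length(st)]
  }
  open_left <- which(vapply(stacks, length, 1L) > 0)
  if (length(open_left))
    stop("unbalanced opening bracket(s) in family ",
         paste0(bracket_open[open_left], bracket_close[open_left],
                collapse = ", "),
         " at position(s) ",
         paste(unlist(stacks[open_left]), collapse = ", "), call. = FALSE)
  rna_structure(do.call(rbind, c(pairs, list(matrix(integer(0), ncol = 2)))),
                length = length(chars), sequence = sequence)
}

#' Write an extended dot-bracket string
#'
#' Bracket layers are assigned by greedy coloring of the arc-crossing conflict
#' graph: arcs are processed in order of left endpoint and each takes the
#' lowest layer not used by an already-colored arc it crosses.  This makes the
#' output deterministic (layer assignment is not canonical in the wild).
#'
#' @param s an \code{\link{rna_structure}}.
#' @return dot-bracket string of length \code{s$length}.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  p <- s$pairs
  out <- rep(".", s$length)
  if (!nrow(p)) return(paste(out, collapse = ""))
  layer <- integer(nrow(p))           # rows already sorted by left endpoint
  for (k in seq_len(nrow(p))) {
    if (k > 1) {
      prev <- seq_len(k - 1L)
      cross <- prev[p[prev, 1L] < p[k, 1L] & p[k, 1L] < p[prev, 2L] &
                    p[prev, 2L] < p[k, 2L]]
      used <- layer[cross]
    } else used <- integer(0)
    lay <- setdiff(seq_along(bracket_open), used)[1]
    if (is.na(lay))
      stop("structure needs more than ", length(bracket_open),
           " crossing layers; cannot be written in dot-bracket", call. = FALSE)
    layer[k] <- lay
    out[p[k, 1L]] <- bracket_open[lay]
    out[p[k, 2L]] <- bracket_close[lay]
  }
  paste(out, collapse = "")
}

#' Read a BPSEQ pairing file
#'
#' BPSEQ rows are \code{position base partner} with 1-based positions and
#' partner 0 for unpaired.  Partner symmetry is enforced: if row \eqn{i} names
#' partner \eqn{j}, row \eqn{j} must name partner \eqn{i}.
#'
#' @param con file path, connection, or character vector of lines.
#' @param replace apply the ribonucleotide replacement policy to the sequence
#'   column (see \code{\link{clean_sequence}}).
#' @return an \code{\link{rna_structure}}.
#' @export
read_bpseq <- function(con, replace = FALSE) {
  lines <- read_record_lines(con)
  fields <- strsplit(trimws(lines), "\\s+")
  n_f <- vapply(fields, length, 1L)
  if (any(n_f != 3L))
    stop("malformed BPSEQ line(s): ", paste(which(n_f != 3L), collapse = ", "),
         call. = FALSE)
  pos <- as.integer(vapply(fields, `[`, "", 1L))
  base <- vapply(fields, `[`, "", 2L)
  partner <- as.integer(vapply(fields, `[`, "", 3L))
  build_from_records(pos, base, partner, replace, "BPSEQ")
}

#' Read a CT (connectivity table) file
#'
#' Standard 6-column CT records: \code{index base prev next partner index},
#' preceded by a header line starting with the sequence length.
#'
#' @inheritParams read_bpseq
#' @return an \code{\link{rna_structure}}.
#' @export
read_ct <- function(con, replace = FALSE) {
  lines <- read_record_lines(con)
  if (!length(lines)) stop("empty CT input", call. = FALSE)
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1]))
  if (is.na(n)) stop("CT header does not start with a length", call. = FALSE)
  body <- lines[-1]
  if (length(body) != n)
    stop("CT header announces ", n, " rows but ", length(body), " found",
         call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  n_f <- vapply(fields, length, 1L)
  if (any(n_f < 6L))
    stop("malformed CT line(s): ",
         paste(1 + which(n_f < 6L), collapse = ", "), call. = FALSE)
  pos <- as.integer(vapply(fields, `[`, "", 1L))
  base <- vapply(fields, `[`, "", 2L)
  partner <- as.integer(vapply(fields, `[`, "", 5L))
  build_from_records(pos, base, partner, replace, "CT")
}

build_from_records <- function(pos, base, partner, replace, fmt) {
  n <- length(pos)
  if (anyNA(pos) || anyNA(partner))
    stop(fmt, ": non-numeric position or partner field", call. = FALSE)
  if (!identical(pos, seq_len(n)))
    stop(fmt, ": positions are not contiguous 1..", n, call. = FALSE)
  bad <- which(partner < 0L | partner > n)
  if (length(bad))
    stop(fmt, ": partner out of range at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  self <- which(partner == pos)
  if (length(self))
    stop(fmt, ": position paired to itself at ",
         paste(self, collapse = ", "), call. = FALSE)
  paired <- which(partner > 0L)
  asym <- paired[partner[partner[paired]] != paired]
  if (length(asym))
    stop(fmt, ": asymmetric pairing record(s) at position(s) ",
         paste(asym, collapse = ", "), call. = FALSE)
  up <- paired[pos[paired] < partner[paired]]
  pairs <- cbind(pos[up], partner[up])
  seq <- paste(base, collapse = "")
  if (grepl("[^ACGUacgu]", seq)) seq <- clean_sequence(seq, replace = replace)
  rna_structure(pairs, length = n, sequence = seq)
}

read_record_lines <- function(con) {
  if (is.character(con) && length(con) == 1L && file.exists(con))
    con <- readLines(con)
  lines <- as.character(con)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines
}

#' Write BPSEQ / CT records
#'
#' @param s an \code{\link{rna_structure}} with a non-empty sequence (BPSEQ
#'   and CT carry the base column; positions without sequence are written as
#'   \code{N}).
#' @param path optional output file; when missing, the lines are returned.
#' @return character vector of lines, invisibly when written to a file.
#' @export
write_bpseq <- function(s, path = NULL) {
  rec <- partner_vector(s)
  lines <- paste(seq_len(s$length), rec$base, rec$partner)
  emit_lines(lines, path)
}

#' @rdname write_bpseq
#' @export
write_ct <- function(s, path = NULL) {
  rec <- partner_vector(s)
  n <- s$length
  lines <- c(paste(n, "rnatopo"),
             paste(seq_len(n), rec$base, seq_len(n) - 1L,
                   c(seq_len(n)[-1L], 0L), rec$partner, seq_len(n)))
  emit_lines(lines, path)
}

partner_vector <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  partner <- integer(s$length)
  p <- s$pairs
  partner[p[, 1L]] <- p[, 2L]
  partner[p[, 2L]] <- p[, 1L]
  base <- if (nzchar(s$sequence)) strsplit(s$sequence, "")[[1]]
          else rep("N", s$length)
  list(base = base, partner = partner)
}

emit_lines <- function(lines, path) {
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read structures from an extended dot-bracket file
#'
#' One structure per record; a record is an optional FASTA-style \code{>}
#' header, an optional sequence line, and the dot-bracket line.
#'
#' @param con file path or character vector of lines.
#' @return list of \code{\link{rna_structure}} objects (named by header when
#'   present).
#' @export
read_dotbracket_file <- function(con) {
  if (is.character(con) && length(con) == 1L && file.exists(con))
    con <- readLines(con)
  lines <- trimws(as.character(con))
  lines <- lines[nzchar(lines)]
  out <- list()
  name <- NULL; seq <- ""
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      name <- sub("^>\\s*", "", ln); seq <- ""
    } else if (grepl("^[ACGUTNacgutn]+$", ln)) {
      seq <- clean_sequence(ln, replace = TRUE)
    } else {
      s <- read_dotbracket(ln, sequence = if (nchar(seq) == nchar(gsub(
        "\\s", "", ln))) seq else "")
      out[[length(out) + 1L]] <- s
      if (!is.null(name)) names(out)[length(out)] <- name
      name <- NULL; seq <- ""
    }
  }
  out
}
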