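# Simplified nearest-neighbour energy model for helipoints.
#
# The folding engine scores a helipoint as the sum of stacking free energies
# over consecutive (1,1) steps plus fixed penalties for size-1 bulges and
# 1x1 internal loops.  The shipped table is a simplified additive model with
# Turner-like magnitudes (GC stacks near -3 kcal/mol, AU near -1); it is NOT
# calibrated against McGenus or full Turner 2004 rules.  Any table can be
# loaded from a plain-text TSV with columns pair1, pair2, dG.

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct an energy model for helipoint scoring
#'
#' @param stack data frame with columns \code{pair1}, \code{pair2} (pair
#'   types as 5'-3' two-letter codes, e.g. \code{"GC"}) and \code{dG}
#'   (stacking free energy, kcal/mol, negative = stabilizing) for the stack
#'   of \code{pair2} on top of \code{pair1}; defaults to the shipped
#'   simplified table.
#' @param bulge1 penalty for a size-1 bulge inside a helipoint (kcal/mol).
#' @param internal11 penalty for a 1x1 internal loop (kcal/mol).
#' @param source short tag recording where the parameters came from.
#' @return object of class \code{energy_model}.
#' @export
energy_model <- function(stack = default_stack_table(), bulge1 = 3.8,
                         internal11 = 1.2, source = "rnatopo-simple") {
  stopifnot(is.data.frame(stack),
            all(c("pair1", "pair2", "dG") %in% names(stack)))
  bad <- setdiff(unique(c(stack$pair1, stack$pair2)), PAIR_TYPES)
  if (length(bad))
    stop("unknown pair type(s) in stack table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  lut <- stats::setNames(stack$dG, paste(stack$pair1, stack$pair2))
  structure(list(stack = stack, lut = lut, bulge1 = bulge1,
                 internal11 = internal11, source = source),
            class = "energy_model")
}

# Additive default: the stack of two pairs contributes the sum of per-pair
# strengths, reproducing the familiar ordering GC/GC < GC/AU < AU/AU.
default_stack_table <- function() {
  strength <- c(AU = -0.6, UA = -0.6, GC = -1.6, CG = -1.6,
                GU = -0.4, UG = -0.4)
  grid <- expand.grid(pair1 = PAIR_TYPES, pair2 = PAIR_TYPES,
                      stringsAsFactors = FALSE)
  grid$dG <- strength[grid$pair1] + strength[grid$pair2]
  grid
}

#' Read an energy model from a plain-text table
#'
#' TSV with a header \code{pair1 pair2 dG}; optional comment lines beginning
#' with \code{#} may set \code{bulge1} or \code{internal11} as
#' \code{# bulge1 = 3.8}.
#'
#' @param path file path.
#' @return an \code{\link{energy_model}}.
#' @export
read_energy_model <- function(path) {
  lines <- readLines(path)
  opts <- list(bulge1 = 3.8, internal11 = 1.2)
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("#\\s*(bulge1|internal11)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L) opts[[m[2]]] <- as.numeric(m[3])
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           stringsAsFactors = FALSE)
  energy_model(tab, bulge1 = opts$bulge1, internal11 = opts$internal11,
               source = basename(path))
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Energy model [", x$source, "]: ", nrow(x$stack),
      " stacking entries, bulge1 = ", x$bulge1, ", internal11 = ",
      x$internal11, " kcal/mol\n", sep = "")
  invisible(x)
}

# Allowed pair set under the pairing rules.  Canonical cWW (AU, GC) by
# default; GU wobble behind a flag.
allowed_pair_types <- function(allow_gu = FALSE) {
  if (allow_gu) PAIR_TYPES else c("AU", "UA", "GC", "CG")
}

stack_energy <- function(model, p1, p2) {
  v <- model$lut[paste(p1, p2)]
  if (anyNA(v)) stop("stack table does not cover ", p1, "/", p2,
                     call. = FALSE)
  unname(v)
}
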