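# Metropolis Monte-Carlo folding over helipoint sets.
#
# A fold state S is a subset of mutually compatible helipoints with free
# energy F_S = sum_i sigma_i^S dF(h_i) + mu * g(S): the sum of the selected
# helipoints' free energies plus a topological chemical potential mu per
# unit genus of the union pairing.  Positive mu penalizes pseudoknots;
# through the matrix-model correspondence mu = -2 kBT log(N), so N > 1
# rewards them.  The engine adds or removes helipoints one at a time under
# Metropolis acceptance and archives the lowest-energy distinct structures.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal / (mol K)

#' Topological chemical potential from the matrix order N
#'
#' \eqn{\mu = -2 k_B T \log(N)}: the matrix-model weight \eqn{N^{-2g}}
#' expressed as a free-energy term.  \code{N = 1} gives \eqn{\mu = 0};
#' \code{N > 1} gives negative \eqn{\mu} (genus rewarded).
#'
#' @param N matrix order, positive real.
#' @param temperature kelvin (default 310.15, i.e. 37 C).
#' @return mu in kcal/mol.
#' @export
mu_from_N <- function(N, temperature = 310.15) {
  if (!is.numeric(N) || N <= 0) stop("N must be positive", call. = FALSE)
  -2 * KB_KCAL * temperature * log(N)
}

#' Free energy of a helipoint selection
#'
#' \eqn{F_S = \sum_i \sigma_i^S \Delta F(h_i) + \mu \, g(S)} where
#' \eqn{g(S)} is the genus of the union of the selected helipoints' pairs.
#' The empty selection scores 0 (the open chain).
#'
#' @param helipoints list from \code{\link{enumerate_helipoints}}.
#' @param selected integer indices of the selected helipoints.
#' @param mu topological chemical potential, kcal/mol.
#' @return list with \code{energy}, \code{genus} and \code{pairs}.
#' @export
fold_energy <- function(helipoints, selected, mu = 0) {
  selected <- as.integer(selected)
  if (!length(selected))
    return(list(energy = 0, genus = 0L,
                pairs = matrix(integer(0), ncol = 2L)))
  pos <- unlist(lapply(helipoints[selected], helipoint_positions))
  if (anyDuplicated(pos))
    stop("selected helipoints are not pairwise compatible", call. = FALSE)
  pairs <- do.call(rbind, lapply(helipoints[selected], `[[`, "pairs"))
  g <- genus(chord_diagram(pairs))$g
  dF <- sum(vapply(helipoints[selected], `[[`, 0, "dF"))
  list(energy = dF + mu * g, genus = g, pairs = normalize_pairs(pairs))
}

#' Fold an RNA sequence by Metropolis Monte Carlo over helipoints
#'
#' Enumerates the sequence's helipoints, then runs a fixed-temperature
#' Metropolis chain: each step proposes adding a uniformly random compatible
#' helipoint or removing a uniformly random selected one, accepted with
#' probability \eqn{\min(1, e^{-\Delta F_S / k_B T})}.  Proposals that would
#' push the genus above \code{max_genus} are rejected outright.  A ranked
#' archive keeps the \code{n_suboptimal} lowest-energy distinct structures
#' (distinctness by exact pair-set identity); the run is deterministic given
#' \code{(sequence, config, seed)}.
#'
#' @param sequence RNA string (at most \code{max_length} bases).
#' @param mu topological chemical potential, kcal/mol; ignored when \code{N}
#'   is given.
#' @param N alternative to \code{mu}: matrix order, converted via
#'   \code{\link{mu_from_N}}.
#' @param temperature kelvin.
#' @param max_genus genus cap (default \code{Inf}: no topology restriction).
#' @param n_suboptimal number of suboptimal structures to report (default
#'   10).
#' @param steps Monte-Carlo iterations, in total across restarts.
#' @param restarts number of independent chains, each started from the open
#'   chain and sharing the suboptimal archive (default 5).  Restarts guard
#'   against deep local minima at strongly repulsive \code{mu}, where a
#'   single fixed-temperature chain can take arbitrarily long to dissolve a
#'   trapped helipoint.
#' @param seed RNG seed for the run.
#' @param model an \code{\link{energy_model}}.
#' @param min_pairs,allow_gu,min_loop passed to
#'   \code{\link{enumerate_helipoints}}.
#' @param max_length refuse longer sequences (default 1000).
#' @return an object of class \code{fold_ensemble}: list with
#'   \code{sequence}, \code{structures} (each with \code{pairs},
#'   \code{energy}, \code{genus}, \code{selected}), \code{helipoints}, and
#'   the run configuration.
#' @examples
#' f <- fold_mc("GGGAAACCC", steps = 200, seed = 1)
#' summary(f)
#' @export
fold_mc <- function(sequence, mu = 0, N = NULL, temperature = 310.15,
                    max_genus = Inf, n_suboptimal = 10L, steps = 2000L,
                    restarts = 5L, seed = 1L, model = energy_model(),
                    min_pairs = 3L, allow_gu = FALSE, min_loop = 3L,
                    max_length = 1000L) {
  seq <- clean_sequence(sequence)
  if (nchar(seq) > max_length)
    stop("sequence has ", nchar(seq), " bases, above the cap of ",
         max_length, call. = FALSE)
  if (!is.null(N)) mu <- mu_from_N(N, temperature)
  stopifnot(n_suboptimal >= 1L, steps >= 0L, restarts >= 1L)
  hp <- enumerate_helipoints(seq, model = model, min_pairs = min_pairs,
                             allow_gu = allow_gu, min_loop = min_loop)
  kBT <- KB_KCAL * temperature
  chain_steps <- diff(round(seq(0, steps, length.out = restarts + 1L)))
  run <- with_preserved_rng(seed, {
    archive <- new_archive(n_suboptimal)
    archive <- archive_offer(archive, integer(0), 0, 0L,
                             matrix(integer(0), ncol = 2L), hp)
    accepted <- 0L
    for (cs in chain_steps) {
      out <- mc_chain(hp, mu, kBT, max_genus, cs, nchar(seq), archive)
      archive <- out$archive
      accepted <- accepted + out$accepted
    }
    list(archive = archive_finalize(archive), accepted = accepted)
  })
  structure(
    list(sequence = seq, structures = run$archive, helipoints = hp,
         mu = mu, temperature = temperature, max_genus = max_genus,
         n_suboptimal = as.integer(n_suboptimal), steps = as.integer(steps),
         restarts = as.integer(restarts), seed = seed,
         accepted = run$accepted),
    class = "fold_ensemble")
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

mc_chain <- function(hp, mu, kBT, max_genus, steps, L, archive) {
  n_hp <- length(hp)
  occupied <- logical(L)           # base occupancy of the current state
  selected <- integer(0)
  sum_dF <- 0; cur_g <- 0L; cur_E <- 0
  hp_pos <- lapply(hp, helipoint_positions)
  accepted <- 0L
  for (step in seq_len(steps)) {
    if (n_hp == 0L) break
    do_add <- if (!length(selected)) TRUE else stats::runif(1) < 0.5
    if (do_add) {
      free <- which(!vapply(seq_len(n_hp), function(k)
        k %in% selected || any(occupied[hp_pos[[k]]]), TRUE))
      if (!length(free)) next
      k <- free[sample.int(length(free), 1L)]
      new_sel <- c(selected, k)
      new_dF <- sum_dF + hp[[k]]$dF
    } else {
      k <- selected[sample.int(length(selected), 1L)]
      new_sel <- setdiff(selected, k)
      new_dF <- sum_dF - hp[[k]]$dF
    }
    pairs <- union_pairs(hp, new_sel)
    new_g <- genus(chord_diagram(pairs))$g
    if (new_g > max_genus) next
    new_E <- new_dF + mu * new_g
    if (new_E <= cur_E || stats::runif(1) < exp(-(new_E - cur_E) / kBT)) {
      if (do_add) occupied[hp_pos[[k]]] <- TRUE
      else occupied[hp_pos[[k]]] <- FALSE
      selected <- new_sel; sum_dF <- new_dF
      cur_g <- new_g; cur_E <- new_E
      accepted <- accepted + 1L
      archive <- archive_offer(archive, selected, cur_E, cur_g, pairs, hp)
    }
  }
  list(archive = archive, accepted = accepted)
}

union_pairs <- function(hp, selected) {
  if (!length(selected)) return(matrix(integer(0), ncol = 2L))
  normalize_pairs(do.call(rbind, lapply(hp[selected], `[[`, "pairs")))
}

new_archive <- function(n_sub) list(n = n_sub, entries = list(), keys = character(0))

archive_offer <- function(arch, selected, energy, g, pairs, hp) {
  key <- paste(pairs[, 1L], pairs[, 2L], sep = ":", collapse = ",")
  if (key %in% arch$keys) return(arch)
  entry <- list(selected = sort(selected), energy = energy, genus = g,
                pairs = pairs)
  arch$entries[[length(arch$entries) + 1L]] <- entry
  arch$keys <- c(arch$keys, key)
  if (length(arch$entries) > arch$n) {
    worst <- which.max(vapply(arch$entries, `[[`, 0, "energy"))
    arch$entries <- arch$entries[-worst]
    arch$keys <- arch$keys[-worst]
  }
  arch
}

archive_finalize <- function(arch) {
  ord <- order(vapply(arch$entries, `[[`, 0, "energy"))
  arch$entries[ord]
}

#' Exhaustive ground-state search over helipoint subsets
#'
#' Enumerates every subset of pairwise-compatible helipoints and returns the
#' lowest-free-energy states exactly.  Feasible for small helipoint counts
#' only (cost \eqn{2^{n}}); serves as the exact reference the Monte-Carlo
#' engine is validated against.
#'
#' @inheritParams fold_mc
#' @param max_subsets refuse when \code{2^n_helipoints} exceeds this bound.
#' @return a \code{fold_ensemble} (with \code{steps = NA}).
#' @export
fold_exact <- function(sequence, mu = 0, N = NULL, temperature = 310.15,
                       max_genus = Inf, n_suboptimal = 10L,
                       model = energy_model(), min_pairs = 3L,
                       allow_gu = FALSE, min_loop = 3L,
                       max_subsets = 2^20) {
  seq <- clean_sequence(sequence)
  if (!is.null(N)) mu <- mu_from_N(N, temperature)
  hp <- enumerate_helipoints(seq, model = model, min_pairs = min_pairs,
                             allow_gu = allow_gu, min_loop = min_loop)
  n <- length(hp)
  if (2^n > max_subsets)
    stop(n, " helipoints: exhaustive search over 2^", n,
         " subsets exceeds max_subsets", call. = FALSE)
  compat <- if (n) outer(seq_len(n), seq_len(n), Vectorize(function(a, b)
    a == b || helipoints_compatible(hp[[a]], hp[[b]])))
  arch <- new_archive(n_suboptimal)
  arch <- archive_offer(arch, integer(0), 0, 0L,
                        matrix(integer(0), ncol = 2L), hp)
  if (n) {
    for (mask in seq_len(2^n - 1L)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      if (length(sel) > 1L && !all(compat[t(utils::combn(sel, 2L))])) next
      st <- fold_energy(hp, sel, mu)
      if (st$genus > max_genus) next
      arch <- archive_offer(arch, sel, st$energy, st$genus, st$pairs, hp)
    }
  }
  structure(
    list(sequence = seq, structures = archive_finalize(arch),
         helipoints = hp, mu = mu, temperature = temperature,
         max_genus = max_genus, n_suboptimal = as.integer(n_suboptimal),
         steps = NA_integer_, seed = NA_integer_, accepted = NA_integer_),
    class = "fold_ensemble")
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat("RNA fold ensemble:", nchar(x$sequence), "nt,",
      length(x$helipoints), "helipoints, mu =", format(x$mu, digits = 4),
      "kcal/mol\n")
  df <- as.data.frame(x)
  df$structure <- vapply(x$structures, function(st)
    write_dotbracket(rna_structure(st$pairs, length = nchar(x$sequence))),
    "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fold_ensemble <- function(x, ...) {
  data.frame(
    rank = seq_along(x$structures),
    energy = vapply(x$structures, `[[`, 0, "energy"),
    genus = vapply(x$structures, `[[`, 0L, "genus"),
    n_pairs = vapply(x$structures, function(st) nrow(st$pairs), 0L))
}

#' @export
summary.fold_ensemble <- function(object, ...) {
  g <- vapply(object$structures, `[[`, 0L, "genus")
  e <- vapply(object$structures, `[[`, 0, "energy")
  out <- list(n_structures = length(object$structures),
              best_energy = min(e), mean_genus = mean(g),
              genus_range = range(g), mu = object$mu)
  class(out) <- "summary.fold_ensemble"
  out
}

#' @export
print.summary.fold_ensemble <- function(x, ...) {
  cat("Ensemble of", x$n_structures, "structures\n")
  cat("  best free energy:", format(x$best_energy, digits = 6),
      "kcal/mol\n")
  cat("  mean genus:", format(x$mean_genus, digits = 4), " (range",
      x$genus_range[1], "-", x$genus_range[2], ")\n")
  cat("  mu:", format(x$mu, digits = 4), "kcal/mol\n")
  invisible(x)
}

#' Member structures of a fold ensemble
#'
#' @param x a \code{fold_ensemble}.
#' @return list of \code{\link{rna_structure}} objects.
#' @export
ensemble_structures <- function(x) {
  stopifnot(inherits(x, "fold_ensemble"))
  lapply(x$structures, function(st)
    rna_structure(st$pairs, length = nchar(x$sequence),
                  sequence = x$sequence))
}

#' @export
plot.fold_ensemble <- function(x, sigma = 1, ...) {
  ts <- ensemble_trace_summary(x, sigma = sigma)
  plot(ts, ...)
  invisible(x)
}
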