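# Independent oracles, deliberately using different formalisms than the
# package internals.

# Genus by polygon-edge gluing: a matching on 2m points is a gluing of the
# edges of a 2m-gon; identify the polygon corners with union-find and count
# surviving vertex classes V, then g = (m + 1 - V) / 2.  This never touches
# the sigma-alpha cycle machinery used by the package.
oracle_genus <- function(arcs) {
  arcs <- matrix(as.integer(arcs), ncol = 2L)
  if (!nrow(arcs)) return(0L)
  pts <- sort(unique(as.vector(arcs)))
  arcs <- matrix(match(arcs, pts), ncol = 2L)
  n <- 2L * nrow(arcs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
    invisible()
  }
  nxt <- function(k) k %% n + 1L
  for (r in seq_len(nrow(arcs))) {
    a <- arcs[r, 1L]; b <- arcs[r, 2L]
    unite(a, nxt(b))   # gluing edge a to edge b reversed identifies corners
    unite(nxt(a), b)
  }
  V <- length(unique(vapply(seq_len(n), find, 1L)))
  as.integer((nrow(arcs) + 1L - V) %/% 2L)
}

# Brute-force enumeration of matchings pairing the LARGEST free point first
# (the package pairs the smallest first), as lists of two-column matrices.
oracle_matchings <- function(n, perfect = FALSE) {
  acc <- list()
  recurse <- function(free, arcs) {
    if (!length(free)) { acc[[length(acc) + 1L]] <<- arcs; return(invisible()) }
    p <- free[length(free)]
    if (!perfect) recurse(free[-length(free)], arcs)
    for (q in free[-length(free)])
      recurse(setdiff(free, c(p, q)), rbind(arcs, c(q, p)))
    invisible()
  }
  recurse(seq_len(n), matrix(integer(0), ncol = 2L))
  acc
}

# Exhaustive minimum free energy over helipoint subsets, with genus from
# oracle_genus; independent of fold_exact / fold_mc internals.
oracle_best_energy <- function(hp, mu) {
  n <- length(hp)
  best <- 0
  pos <- lapply(hp, function(h) as.vector(h$pairs))
  dF <- vapply(hp, `[[`, 0, "dF")
  if (n) for (mask in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ps <- unlist(pos[sel])
    if (anyDuplicated(ps)) next
    pairs <- do.call(rbind, lapply(hp[sel], `[[`, "pairs"))
    e <- sum(dF[sel]) + mu * oracle_genus(pairs)
    if (e < best) best <- e
  }
  best
}

canon_pairs <- function(p) {
  p <- matrix(as.integer(p), ncol = 2L)
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# group a fixture's pairs into its constituent stems (runs of parallel pairs)
split_stems <- function(s) {
  p <- canon_pairs(s$pairs)
  groups <- list()
  cur <- p[1, , drop = FALSE]
  for (r in seq_len(nrow(p))[-1]) {
    prev <- cur[nrow(cur), ]
    if (p[r, 1] == prev[1] + 1L && p[r, 2] == prev[2] - 1L)
      cur <- rbind(cur, p[r, ])
    else { groups[[length(groups) + 1L]] <- cur; cur <- p[r, , drop = FALSE] }
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}
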