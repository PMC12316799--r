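test_that("boundary components follow the fat-graph cycle count", {
  expect_equal(boundary_components(chord_diagram(rbind(c(1, 2)))), 2L)
  expect_equal(boundary_components(chord_diagram(rbind(c(1, 3), c(2, 4)))),
               1L)   # hand-traced: one boundary cycle, the torus diagram
  expect_equal(boundary_components(chord_diagram(rbind(c(1, 4), c(2, 3)))),
               3L)   # hand-traced: nested pair keeps three boundaries
  expect_equal(boundary_components(chord_diagram(NULL, 0)), 1L)
})

test_that("cycle count is invariant under the alternative composition", {
  # alpha o sigma instead of sigma o alpha must give the same count
  alt_boundaries <- function(d) {
    m <- nrow(d$arcs)
    if (m == 0L) return(1L)
    n <- 2L * m
    alpha <- integer(n)
    alpha[d$arcs[, 1]] <- d$arcs[, 2]
    alpha[d$arcs[, 2]] <- d$arcs[, 1]
    perm <- alpha[seq_len(n) %% n + 1L]  # x -> alpha(sigma(x))
    seen <- logical(n); cycles <- 0L
    for (s in seq_len(n)) {
      if (seen[s]) next
      cycles <- cycles + 1L; x <- s
      while (!seen[x]) { seen[x] <- TRUE; x <- perm[x] }
    }
    cycles
  }
  for (d in enumerate_partial_matchings(8, perfect_only = TRUE))
    expect_equal(boundary_components(d), alt_boundaries(d))
})

test_that("kissing hairpin has genus 1 and chi = -1", {
  sh <- chord_diagram(rbind(c(1, 3), c(2, 5), c(4, 6)))
  g <- genus(sh)
  expect_equal(g$g, 1L)
  expect_equal(g$chi, -1L)
  expect_equal(g$m, 3L)
  expect_gt(nrow(arc_crossings(sh)), 0L)  # cannot embed crossing-free at g=0
  # any fleshed-out kissing hairpin keeps g = 1
  expect_equal(genus(make_kissing_hairpin(stems = c(4, 2, 5)))$g, 1L)
})

test_that("planar structures have genus 0 and chi = 1", {
  nested <- rna_structure(rbind(c(1, 8), c(2, 7), c(3, 6)), length = 8)
  expect_equal(genus(nested)$g, 0L)
  expect_equal(genus(nested)$chi, 1L)
  expect_equal(genus(rna_structure(length = 5))$g, 0L)
  expect_equal(genus(rna_structure(length = 5))$b, 1L)
})

test_that("genus agrees with the polygon-gluing oracle for all m <= 4", {
  for (n in c(2, 4, 6, 8)) {
    for (d in enumerate_partial_matchings(n, perfect_only = TRUE))
      expect_equal(genus(d)$g, oracle_genus(d$arcs))
  }
})

test_that("genus-resolved matching counts match brute-force enumeration", {
  # m = 3: 15 matchings split 5 planar (the Catalan number C_3) + 10 genus-1
  pm6 <- enumerate_partial_matchings(6, perfect_only = TRUE)
  expect_length(pm6, 15L)
  hist6 <- table(vapply(pm6, function(d) genus(d)$g, 1L))
  expect_equal(unname(c(hist6["0"], hist6["1"])), c(5L, 10L))
  # against the independent largest-point-first enumeration with the
  # polygon oracle (Harer-Zagier-type counts computed, not assumed)
  for (m in 1:4) {
    ours <- table(factor(vapply(
      enumerate_partial_matchings(2 * m, perfect_only = TRUE),
      function(d) genus(d)$g, 1L), levels = 0:2))
    theirs <- table(factor(vapply(
      oracle_matchings(2 * m, perfect = TRUE),
      function(a) oracle_genus(a), 1L), levels = 0:2))
    expect_equal(ours, theirs)
    # planar count is the Catalan number choose(2m, m)/(m + 1)
    expect_equal(unname(ours["0"]), as.integer(choose(2 * m, m) / (m + 1)))
  }
})

test_that("genus bounds and parity bookkeeping hold", {
  set.seed(5)
  for (rep in 1:40) {
    d <- random_matching(16, sample(0:8, 1))
    g <- genus(d)
    expect_true(g$g >= 0L && g$g <= g$m %/% 2L)
    expect_equal((g$m - g$b + 1L) %% 2L, 0L)
    expect_equal(g$chi, 1L - 2L * g$g)
  }
})

test_that("genus is invariant under unpaired-position insertion", {
  set.seed(9)
  for (rep in 1:10) {
    d <- random_matching(12, 5)
    # spread the same arcs over a longer backbone
    pos <- sort(sample.int(30, 12))
    s <- rna_structure(matrix(pos[d$arcs], ncol = 2), length = 30)
    expect_equal(genus(s)$g, genus(d)$g)
  }
})

test_that("genus trace is monotone and localizes pseudoknot closure", {
  kh <- chord_diagram(rbind(c(1, 3), c(2, 5), c(4, 6)))
  tr <- genus_trace(rna_structure(kh$arcs, length = 6))
  # the jump lands where the first crossing completes: arc (2,5) closes at 5
  # and crosses (1,3); prefix genus confirmed by the polygon oracle below
  expect_equal(as.integer(tr), c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(oracle_genus(rbind(c(1, 3), c(2, 5))), 1L)
  expect_true(all(diff(as.integer(tr)) >= 0L))
  expect_equal(as.integer(genus_trace(rna_structure(length = 7))),
               rep(0L, 7))
  # prefix brute force on random structures
  set.seed(31)
  for (rep in 1:10) {
    s <- random_structure_with_genus(sample(0:2, 1))
    tr <- as.integer(genus_trace(s))
    for (i in unique(c(1, s$length %/% 2, s$length))) {
      sub <- s$pairs[s$pairs[, 2] <= i, , drop = FALSE]
      expect_equal(tr[i], oracle_genus(sub))
    }
    expect_true(all(diff(tr) >= 0L))
    expect_equal(tr[s$length], genus(s)$g)
  }
})

test_that("concatenated genus-1 blocks give a two-jump trace", {
  td <- make_two_domain()
  tr <- as.integer(genus_trace(td))
  expect_equal(tr[length(tr)], 2L)
  expect_equal(sum(diff(tr) == 1L), 2L)
  expect_equal(genus(td)$g, 2L)
})

test_that("fingerprint matrix holds windowed genus values", {
  s <- rna_structure(length = 5)
  expect_true(all(genus_fingerprint(s)[upper.tri(diag(5), diag = TRUE)] == 0))
  kh <- rna_structure(rbind(c(1, 3), c(2, 5), c(4, 6)), length = 6)
  G <- genus_fingerprint(kh)
  expect_equal(G[1, 6], 1L)
  expect_equal(G[1, 3], 0L)   # window covering only the first stem
  expect_equal(G[4, 6], 0L)
  expect_true(all(diag(G) == 0L))
  # row 1 equals the genus trace; windows are monotone under inclusion
  set.seed(17)
  for (rep in 1:5) {
    s <- random_structure_with_genus(2)
    G <- genus_fingerprint(s)
    expect_equal(unname(G[1, ]), as.integer(genus_trace(s)))
    L <- s$length
    for (i in 2:L) expect_true(all(G[i, i:L] <= G[i - 1, i:L]))
    for (j in 1:(L - 1)) expect_true(all(G[1:j, j] <= G[1:j, j + 1]))
  }
  expect_error(genus_fingerprint(make_two_domain(), cap = 10), "cap")
})
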