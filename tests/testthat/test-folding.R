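test_that("helipoint enumeration finds maximal stems with negative dF", {
  h <- enumerate_helipoints("GGGAAACCC")
  expect_length(h, 1L)
  expect_equal(unname(h[[1]]$pairs), cbind(1:3, 9:7))
  expect_lt(h[[1]]$dF, 0)
  expect_length(enumerate_helipoints("AAAAAAAAAA"), 0L)
  # the designed kissing hairpin contains its three intended stems
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  hp <- enumerate_helipoints(kh$sequence)
  keys <- vapply(hp, function(h) paste(canon_pairs(h$pairs), collapse = ","),
                 "")
  for (stem in split_stems(kh))
    expect_true(paste(canon_pairs(stem), collapse = ",") %in% keys)
})

test_that("helipoints admit size-1 bulges and 1x1 internal loops", {
  # GGAGG AAAA CCCC: stem with a bulged A on the 5' side
  h <- enumerate_helipoints("GGAGGAAAACCCC", min_pairs = 4)
  pats <- lapply(h, function(x) unname(x$pairs))
  expect_true(any(vapply(pats, function(p)
    isTRUE(all.equal(p, cbind(c(1L, 2L, 4L, 5L), c(13L, 12L, 11L, 10L)))),
    TRUE)))
  bulged <- Filter(function(x) x$n_bulge == 1L, h)
  expect_gt(length(bulged), 0L)
  # GGAGG ... CCUCC: 1x1 internal loop (A opposite U)
  h2 <- enumerate_helipoints("GGAGGAAAACCUCC", min_pairs = 4)
  il <- Filter(function(x) x$n_internal == 1L, h2)
  expect_gt(length(il), 0L)
})

test_that("free energy combines helipoint terms with the genus penalty", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  hp <- enumerate_helipoints(kh$sequence)
  expect_equal(fold_energy(hp, integer(0), mu = 5)$energy, 0)
  one <- fold_energy(hp, 1L, mu = 100)
  expect_equal(one$genus, 0L)
  expect_equal(one$energy, hp[[1]]$dF)   # planar: mu does not enter
  # two crossing helipoints of dF = -5 each at mu = 3: -10 + 3*1 = -7
  model <- energy_model()
  fake <- list(list(pairs = cbind(1:3, 12:10), dF = -5),
               list(pairs = cbind(5:7, 18:16), dF = -5))
  expect_equal(fold_energy(fake, 1:2, mu = 3)$energy, -7)
  expect_equal(fold_energy(fake, 1:2, mu = 0)$genus, 1L)
  bad <- list(list(pairs = cbind(1:3, 12:10), dF = -5),
              list(pairs = cbind(3:5, 20:18), dF = -5))
  expect_error(fold_energy(bad, 1:2, 0), "compatible")
})

test_that("mu_from_N implements the matrix-model correspondence", {
  expect_equal(mu_from_N(1), 0)
  expect_equal(mu_from_N(exp(1), temperature = 0.5 / 0.0019872041), -1)
  expect_lt(mu_from_N(10), 0)
  expect_gt(mu_from_N(0.5), 0)
  expect_error(mu_from_N(-1), "positive")
})

test_that("metropolis runs are deterministic under a fixed seed", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  f1 <- fold_mc(kh$sequence, steps = 400, seed = 5)
  f2 <- fold_mc(kh$sequence, steps = 400, seed = 5)
  expect_identical(f1$structures, f2$structures)
  expect_error(fold_mc(strrep("A", 1200)), "cap of 1000")
})

test_that("zero steps reports only the open chain at energy 0", {
  f <- fold_mc("GGGAAACCC", steps = 0, seed = 1)
  expect_length(f$structures, 1L)
  expect_equal(f$structures[[1]]$energy, 0)
  expect_equal(nrow(f$structures[[1]]$pairs), 0L)
})

test_that("the MC optimum matches the exhaustive-subset oracle", {
  seqs <- list(
    hairpin = "GGGAAACCC",
    kissing = make_kissing_hairpin(design_sequence = TRUE)$sequence,
    hpk = make_h_pseudoknot(design_sequence = TRUE)$sequence)
  for (nm in names(seqs)) {
    hp <- enumerate_helipoints(seqs[[nm]])
    expect_lte(length(hp), 15L)
    for (mu in c(0, 20)) {
      best_oracle <- oracle_best_energy(hp, mu)
      mc <- fold_mc(seqs[[nm]], mu = mu, steps = 4000, seed = 11)
      expect_equal(mc$structures[[1]]$energy, best_oracle,
                   tolerance = 1e-9)
      ex <- fold_exact(seqs[[nm]], mu = mu)
      expect_equal(ex$structures[[1]]$energy, best_oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("positive mu drives the ground state planar on the kissing fixture", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  ex0 <- fold_exact(kh$sequence, mu = 0)
  expect_equal(ex0$structures[[1]]$genus, 1L)
  ex20 <- fold_exact(kh$sequence, mu = 20)
  expect_equal(ex20$structures[[1]]$genus, 0L)
})

test_that("mean ensemble genus is non-increasing in mu (multi-seed)", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  mus <- c(-2, 0, 2, 20)
  # enough restarts for the archive to converge on this small landscape
  mean_g <- sapply(mus, function(mu) {
    mean(sapply(1:5, function(sd) {
      f <- fold_mc(kh$sequence, mu = mu, steps = 2000, restarts = 40,
                   seed = sd, n_suboptimal = 10)
      summary(f)$mean_genus
    }))
  })
  expect_true(all(diff(mean_g) <= 1e-9))
})

test_that("max_genus caps the explored topologies", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  f <- fold_mc(kh$sequence, mu = -5, max_genus = 0, steps = 2000, seed = 3)
  expect_true(all(vapply(f$structures, `[[`, 0L, "genus") == 0L))
})

test_that("archived energies agree with from-scratch recomputation", {
  kh <- make_kissing_hairpin(design_sequence = TRUE)
  f <- fold_mc(kh$sequence, mu = 1.5, steps = 1000, seed = 9)
  for (st in f$structures) {
    again <- fold_energy(f$helipoints, st$selected, mu = f$mu)
    expect_equal(st$energy, again$energy, tolerance = 1e-9)
    expect_equal(st$genus, again$genus)
    expect_equal(st$genus, genus(rna_structure(st$pairs,
                                               length = nchar(kh$sequence)))$g)
  }
  es <- vapply(f$structures, `[[`, 0, "energy")
  expect_true(all(diff(es) >= 0))
  keys <- vapply(f$structures, function(st)
    paste(st$pairs, collapse = ","), "")
  expect_false(anyDuplicated(keys) > 0)
})
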