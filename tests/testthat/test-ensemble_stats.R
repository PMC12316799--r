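test_that("trace summary of identical members has zero spread", {
  kh <- make_kissing_hairpin()
  ts <- ensemble_trace_summary(list(kh, kh, kh), sigma = 0)
  tr <- as.integer(genus_trace(kh))
  expect_equal(ts$mean, tr)
  expect_equal(ts$mode, tr)
  expect_true(all(ts$sd == 0))
  expect_equal(ts$min, tr)
  expect_equal(ts$max, tr)
  # unsmoothed mean at the final position is the ensemble mean genus
  expect_equal(ts$mean[length(ts$mean)], genus(kh)$g)
})

test_that("mixed members average position-wise; mode ties go low", {
  flat <- rna_structure(length = 6)
  pk <- rna_structure(rbind(c(1, 3), c(2, 5), c(4, 6)), length = 6)
  ts <- ensemble_trace_summary(list(flat, pk), sigma = 0)
  expect_equal(ts$mean, c(0, 0, 0, 0, 0.5, 0.5))
  expect_equal(ts$mode, c(0L, 0L, 0L, 0L, 0L, 0L))  # tie 0/1 -> 0
  expect_equal(ts$min, c(0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(ts$max, c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_true(all(ts$min <= ts$mode & ts$mode <= ts$max))
  expect_error(ensemble_trace_summary(list(flat, make_kissing_hairpin())),
               "mixed")
  # order of members does not matter
  ts2 <- ensemble_trace_summary(list(pk, flat), sigma = 0)
  expect_equal(ts$mean, ts2$mean)
  expect_equal(ts$sd, ts2$sd)
})

test_that("Gaussian smoothing matches the frozen reference kernel", {
  v <- c(0, 0, 1, 1, 2, 2, 2, 1, 0, 0)
  # reference values from an independent 1-D Gaussian filter
  # (sigma 1, radius 4, reflection padding)
  expect_equal(gaussian_smooth(v, 1),
               c(0.06325634, 0.30522779, 0.75802855, 1.24183762,
                 1.69020652, 1.87818684, 1.63634922, 0.99986617,
                 0.35921892, 0.06782203),
               tolerance = 1e-7)
  expect_equal(gaussian_smooth(v, 0), v)
  # mass-preserving on constants, NA passthrough
  expect_equal(gaussian_smooth(rep(2, 8), 1.5), rep(2, 8))
  withNA <- gaussian_smooth(c(1, NA, 1, 1, 1), 1)
  expect_true(is.na(withNA[2]))
  expect_equal(withNA[-2], rep(1, 4))
})

test_that("smoothing keeps the two plateau domains in place", {
  td <- make_two_domain()
  ts <- ensemble_trace_summary(list(td, td), sigma = 1)
  tr <- as.integer(genus_trace(td))
  # plateau centers (genus 1 after domain 1, genus 2 after domain 2)
  p1 <- which(tr == 1L); p2 <- which(tr == 2L)
  mid1 <- p1[ceiling(length(p1) / 2)]; mid2 <- p2[ceiling(length(p2) / 2)]
  expect_equal(ts$smoothed_mean[mid1], 1, tolerance = 1e-6)
  expect_equal(ts$smoothed_mean[mid2], 2, tolerance = 1e-6)
})

test_that("NA positions are excluded and propagated", {
  m <- rbind(c(0, 0, 1, NA), c(0, 1, 1, 1))
  ts <- ensemble_trace_summary(m, sigma = 0)
  expect_equal(ts$mean, c(0, 0.5, 1, 1))
  expect_equal(ts$sd[4], 0)
  expect_equal(ts$mode[2], 0L)
})

test_that("regression on collinear data is exact", {
  d <- c(50, 120, 200, 340)
  fit <- fit_length_genus(d, 0.01 * d)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  two <- fit_length_genus(c(100, 200), c(1, 3))
  expect_equal(two$slope, 0.02)
  expect_equal(two$r_squared, 1)
  z <- fit_length_genus(d, 0.01 * d, zero_intercept = TRUE)
  expect_equal(z$slope, 0.01, tolerance = 1e-12)
  expect_equal(z$intercept, 0)
  expect_error(fit_length_genus(c(100, 100), c(1, 2)), "degenerate")
})

test_that("regression recovers simulated genus-length parameters", {
  set.seed(101)
  d <- round(runif(500, 50, 400))
  g <- 0.0134 * d - 0.3429 + rnorm(500, sd = 0.5)
  fit <- fit_length_genus(d, g)
  expect_lt(abs(fit$slope - 0.0134), 3 * fit$slope_se)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_equal(unname(coef(fit)["slope"]), fit$slope)
})
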