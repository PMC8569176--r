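test_that("Sobol' sequence matches the reference low-discrepancy points", {
  # first 8 points in 5 dimensions, generated independently with
  # scipy.stats.qmc.Sobol (unscrambled, zero point dropped)
  ref <- matrix(c(
    0.5,    0.5,    0.5,    0.5,    0.5,
    0.75,   0.25,   0.25,   0.25,   0.75,
    0.25,   0.75,   0.75,   0.75,   0.25,
    0.375,  0.375,  0.625,  0.875,  0.375,
    0.875,  0.875,  0.125,  0.375,  0.875,
    0.625,  0.125,  0.875,  0.625,  0.625,
    0.125,  0.625,  0.375,  0.125,  0.125,
    0.1875, 0.3125, 0.9375, 0.4375, 0.5625), 8, 5, byrow = TRUE)
  expect_equal(sobol_sequence(8, 5), ref, tolerance = 1e-12)
  # higher dimensions against the same oracle (points 2-4 of dims 9-12)
  ref2 <- matrix(c(
    0.75, 0.75, 0.75, 0.75,
    0.25, 0.25, 0.25, 0.25,
    0.875, 0.625, 0.875, 0.375), 3, 4, byrow = TRUE)
  expect_equal(sobol_sequence(3, 12, skip = 1)[, 9:12], ref2,
               tolerance = 1e-12)
})

test_that("sobol design respects ranges, structure and reproducibility", {
  rng <- default_sobol_ranges()
  des <- sobol_design(rng, n = 16, seed = 5)
  for (j in 1:5) {
    expect_true(all(des$M1[, j] >= rng[1, j] & des$M1[, j] <= rng[2, j]))
    expect_true(all(des$M2[, j] >= rng[1, j] & des$M2[, j] <= rng[2, j]))
  }
  expect_false(isTRUE(all.equal(des$M1, des$M2)))
  # mixed matrix j = M1 with column j from M2
  expect_equal(des$mixed[["D_w"]][, -2], des$M1[, -2])
  expect_equal(des$mixed[["D_w"]][, 2], des$M2[, 2])
  # total rows = n (k + 2)
  expect_equal(nrow(sobol_pooled_rows(des)), 16 * 7)
  expect_equal(nrow(sobol_pooled_rows(des, 100)), 100)
  # reproducible under a fixed seed, different under another
  expect_equal(sobol_design(rng, 16, seed = 5)$M1, des$M1)
  expect_false(isTRUE(all.equal(sobol_design(rng, 16, seed = 6)$M1, des$M1)))
  expect_error(sobol_design(rbind(c(1, 1), c(1, 2)), 16), "low < high")
})

test_that("total-effect estimator recovers analytic indices", {
  rng01 <- rbind(low = rep(0, 5), high = rep(1, 5))
  des <- sobol_design(rng01, n = 256, seed = 5)
  ev <- function(f) total_effect_indices(f(des$M1), f(des$M2),
                                         sapply(des$mixed, f))
  # single-input function: S = (1, 0, 0, 0, 0)
  s1 <- ev(function(m) 3 * m[, 1])
  expect_equal(unname(s1[1]), 1, tolerance = 0.05)
  expect_true(all(abs(s1[-1]) < 0.05))
  # additive equal-range function: S = (0.5, 0.5, 0, 0, 0)
  s2 <- ev(function(m) m[, 1] + m[, 2])
  expect_equal(unname(s2[1:2]), c(0.5, 0.5), tolerance = 0.07)
  expect_true(all(abs(s2[3:5]) < 0.07))
  # scale invariance
  s3 <- ev(function(m) 10 * (m[, 1] + m[, 2]))
  expect_equal(s3, s2, tolerance = 1e-10)
  # constant output raises
  expect_error(ev(function(m) rep(1, nrow(m))), "variance")
})

test_that("total effects match the Ishigami closed form", {
  rng <- rbind(low = rep(-pi, 3), high = rep(pi, 3))
  des <- sobol_design(rng, n = 4096, seed = 7)
  a <- 7; b <- 0.1
  ish <- function(m) sin(m[, 1]) + a * sin(m[, 2])^2 +
    b * m[, 3]^4 * sin(m[, 1])
  S <- total_effect_indices(ish(des$M1), ish(des$M2), sapply(des$mixed, ish))
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 1 / 2
  exact <- c((0.5 * (1 + b * pi^4 / 5)^2 + 8 * b^2 * pi^8 / 225) / V,
             (a^2 / 8) / V,
             (8 * b^2 * pi^8 / 225) / V)
  expect_equal(unname(S), exact, tolerance = 0.05)
})

test_that("Latin hypercube puts exactly one sample in every subinterval", {
  rng <- default_sobol_ranges()
  for (n in c(2L, 25L)) {
    X <- lhs_design(rng, n, seed = 3)
    for (j in 1:5) {
      cuts <- seq(rng[1, j], rng[2, j], length.out = n + 1)
      counts <- table(cut(X[, j], cuts, include.lowest = TRUE))
      expect_true(all(counts == 1))
    }
  }
  expect_equal(lhs_design(rng, 25, seed = 3), lhs_design(rng, 25, seed = 3))
  # empirical margins approach uniform (Kolmogorov-Smirnov oracle)
  Xl <- lhs_design(rbind(low = 0, high = 1), 400, seed = 9)
  ks <- suppressWarnings(stats::ks.test(Xl[, 1], "punif"))
  expect_gt(ks$p.value, 0.99)  # stratification beats iid sampling
})

test_that("partial correlation equals the precision-matrix oracle", {
  set.seed(2)
  X <- matrix(rnorm(125), 25, 5)
  y <- X[, 3] + rnorm(25, 0, 0.2)
  pc <- partial_correlation(X, y)
  P <- solve(stats::cov(cbind(X, y)))
  oracle <- -P[6, 1:5] / sqrt(P[6, 6] * diag(P)[1:5])
  expect_equal(pc$pcc, unname(oracle), tolerance = 1e-10)
  # exact dependence on x3: pcc = 1 there, near zero elsewhere
  pc2 <- partial_correlation(X, X[, 3])
  expect_equal(pc2$pcc[3], 1, tolerance = 1e-8)
  expect_true(all(abs(pc2$pcc[-3]) < 0.65))
  expect_true(pc2$p[3] < 1e-10)
  # independent output: mostly insignificant
  set.seed(4)
  pc3 <- partial_correlation(X, rnorm(25))
  expect_gt(min(pc3$p), 0.01)
  # zero-variance input flagged, collinear inputs raise
  Xz <- X; Xz[, 2] <- 1
  pcz <- partial_correlation(Xz, y)
  expect_true(pcz$degenerate[2])
  expect_true(is.na(pcz$pcc[2]))
  Xc <- X; Xc[, 2] <- 2 * X[, 1]
  expect_error(partial_correlation(Xc, y), "collinear")
})
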