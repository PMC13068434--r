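tongue_of <- function(v, nz = nrow(v), nr = ncol(v), kind = "synchrony") {
  arnold_tongue(v, seq(0.01, 1, length.out = nz),
                seq(1, 1.5, length.out = nr), kind = kind)
}

test_that("min-max normalization maps extremes to the unit interval", {
  t1 <- tongue_of(matrix(c(0.5, 0.75, 1, 0.75), 2, 2))
  n1 <- minmax_normalize(t1)
  expect_equal(sort(unique(as.vector(n1$values))), c(0, 0.5, 1))
  expect_true(n1$normalized)
  ## idempotent on a map already spanning [0, 1]
  expect_equal(minmax_normalize(n1)$values, n1$values)
  expect_error(minmax_normalize(tongue_of(matrix(0.4, 3, 3))), "constant")
})

test_that("Pearson similarity matches hand computations", {
  A <- tongue_of(matrix(1:4, 2, 2))
  expect_equal(pearson_similarity(A, A), 1)
  B <- tongue_of(matrix(5 - 2 * (1:4), 2, 2))
  expect_equal(pearson_similarity(A, B), -1)
  C <- tongue_of(matrix(c(1, 2, 4, 3), 2, 2))
  expect_equal(pearson_similarity(A, C), 0.8)  # hand: cov 4 / var 5
  expect_error(pearson_similarity(A, tongue_of(matrix(1, 2, 2))),
               "constant")
  expect_error(pearson_similarity(A, tongue_of(matrix(1:9, 3, 3))),
               "shapes")
})

test_that("weighted Jaccard is conservative and exact on hand cases", {
  A <- tongue_of(matrix(c(0.2, 0.8, 0.5, 0.1), 2, 2))
  expect_equal(weighted_jaccard(A, A), 1)
  B <- tongue_of(matrix(c(0.4, 0.4, 0.5, 0.3), 2, 2))
  expect_equal(weighted_jaccard(tongue_of(matrix(c(0.2, 0.8), 1, 2,
                                                 byrow = TRUE), 1, 2),
                                tongue_of(matrix(c(0.4, 0.4), 1, 2), 1, 2)),
               0.5)  # (0.2 + 0.4) / (0.4 + 0.8)
  disjoint_a <- tongue_of(matrix(c(1, 0, 1, 0), 2, 2))
  disjoint_b <- tongue_of(matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(weighted_jaccard(disjoint_a, disjoint_b), 0)
  expect_equal(weighted_jaccard(tongue_of(matrix(0, 2, 2)),
                                tongue_of(matrix(0, 2, 2))), 1)
  ## more conservative than Pearson under a constant shift
  Ashift <- tongue_of(A$values + 0.2)
  expect_equal(pearson_similarity(A, Ashift), 1)
  expect_lt(weighted_jaccard(A, Ashift), 1)
  expect_error(weighted_jaccard(A, tongue_of(matrix(-0.1, 2, 2))),
               "nonnegative")
})

test_that("Simpson tongue volume is exact where Simpson is exact", {
  ## constant surface over the native domain
  expect_equal(tongue_size(tongue_of(matrix(1, 5, 5))), 0.99 * 0.5,
               tolerance = 1e-12)
  ## separable cubic x quadratic surface: Simpson integrates exactly
  zx <- seq(0.01, 1, length.out = 5)
  rx <- seq(1, 1.5, length.out = 5)
  vals <- outer(zx^3, rx^2)
  fz <- (1^4 - 0.01^4) / 4
  fr <- (1.5^3 - 1^3) / 3
  expect_equal(tongue_size(tongue_of(vals)), fz * fr, tolerance = 1e-12)
  ## linearity under scaling
  expect_equal(tongue_size(tongue_of(2 * vals)),
               2 * tongue_size(tongue_of(vals)), tolerance = 1e-12)
  ## even point counts (trapezoid closing panel) stay exact for linear maps
  vals4 <- outer(seq(0.01, 1, length.out = 4),
                 seq(1, 1.5, length.out = 4), function(a, b) 2 * a + b)
  fz4 <- 1^2 - 0.01^2  # integral of 2z over [0.01, 1]
  fr4 <- 1.25 * 0.5    # integral of r over [1, 1.5]: mean times width
  expect_equal(tongue_size(tongue_of(vals4, 4, 4)),
               0.99 * fr4 + 0.5 * fz4, tolerance = 1e-12)
  expect_error(tongue_size(tongue_of(matrix(1, 2, 2))), "3 points")
})

test_that("coarse and fine grids agree for a smooth tongue", {
  surf <- function(z, r) plogis(3 - 6 * z - 2 * (r - 1) - 2 * z * (r - 1))
  coarse <- tongue_of(outer(seq(0.01, 1, length.out = 5),
                        seq(1, 1.5, length.out = 5), surf))
  fine <- tongue_of(outer(seq(0.01, 1, length.out = 31),
                         seq(1, 1.5, length.out = 31), surf))
  expect_equal(tongue_size(coarse), tongue_size(fine), tolerance = 0.05)
})

test_that("metrics are invariant to transposing both maps", {
  set.seed(51)
  A <- matrix(runif(25), 5, 5)
  B <- matrix(runif(25), 5, 5)
  ta <- tongue_of(A)
  tb <- tongue_of(B)
  ## transpose both: similarity unchanged (axes swap consistently)
  expect_equal(pearson_similarity(t(A), t(B)), pearson_similarity(ta, tb))
  expect_equal(weighted_jaccard(t(A), t(B)), weighted_jaccard(ta, tb))
})

test_that("the 2D psychometric surface fit recovers known parameters", {
  set.seed(52)
  beta <- c(4, -8, -1.5, 1)  # strong heterogeneity effect, mild coarseness
  zx <- seq(0.01, 1, length.out = 5)
  rx <- seq(1, 1.5, length.out = 5)
  eta <- outer(zx, rx, function(z, r) beta[1] + beta[2] * z + beta[3] * r +
                 beta[4] * z * r)
  p <- 0.5 + 0.5 * plogis(eta)
  n <- 1000
  acc <- matrix(rbinom(25, n, p) / n, 5, 5)
  fit <- fit_tongue_surface(tongue_of(acc, kind = "accuracy"), n)
  expect_true(fit$converged)
  for (i in 1:4)
    expect_lt(abs(fit$beta[i] - beta[i]), 3 * fit$se[i])
  ## the 75% contour trades heterogeneity against coarseness
  expect_gt(nrow(fit$contour75), 0)
  expect_true(all(diff(fit$contour75$rho) < 0))
  ## saturated accuracy: no contour inside the domain
  fit1 <- fit_tongue_surface(tongue_of(matrix(0.999, 5, 5),
                                       kind = "accuracy"), n)
  expect_equal(nrow(fit1$contour75), 0)
})

test_that("noise ceilings summarize fold-to-leftout similarity", {
  t0 <- tongue_of(matrix(c(0.9, 0.6, 0.4, 0.7, 0.5, 0.3, 0.5, 0.4, 0.2),
                         3, 3))
  ## identical participants: degenerate band at similarity 1
  nc <- noise_ceiling(list(t0, t0, t0), list(t0, t0, t0))
  expect_equal(as.numeric(nc), c(1, 1))
  expect_lte(nc[["lower"]], nc[["upper"]])
  ## band reflects between-subject noise: wider with noisier cohorts
  band_width <- sapply(c(0.02, 0.3), function(s) {
    set.seed(53)
    outs <- lapply(1:8, function(i)
      tongue_of(pmin(pmax(t0$values + matrix(rnorm(9, 0, s), 3, 3), 0), 1)))
    folds <- lapply(1:8, function(i) mean_tongue(outs[-i]))
    vals <- attr(noise_ceiling(folds, outs), "values")
    1 - mean(vals)  # distance from perfect similarity
  })
  expect_lt(band_width[1], band_width[2])
  expect_error(noise_ceiling(list(t0), list(t0)), "2 folds")
})
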