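# Standard ellipse geometry and the conjugate bivariate posterior.

test_that("standard ellipse areas match closed forms", {
  expect_equal(standard_ellipse_area(diag(2)), pi)
  expect_equal(standard_ellipse_area(diag(c(4, 1))), 2 * pi)
  expect_equal(standard_ellipse_area(matrix(c(2, 1, 1, 2), 2)), pi * sqrt(3))
  expect_error(standard_ellipse_area(matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("area is rotation-invariant and scales quadratically", {
  set.seed(1)
  S <- crossprod(matrix(rnorm(4), 2)) + diag(2) * 0.1
  a0 <- standard_ellipse_area(S)
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_lt(abs(standard_ellipse_area(R %*% S %*% t(R)) - a0), 1e-10)
  }
  for (cc in c(0.5, 2, 7)) {
    expect_equal(standard_ellipse_area(cc^2 * S), cc^2 * a0,
                 tolerance = 1e-12)
  }
})

test_that("small-sample correction follows (n-1)/(n-2)", {
  expect_equal(sea_c(diag(2), 3), 2 * pi)
  expect_equal(sea_c(diag(2), 12), 1.1 * pi)
  expect_lt(abs(sea_c(diag(2), 1e6) - pi) / pi, 1e-5)
  expect_error(sea_c(diag(2), 2), ">= 3")
})

test_that("conjugate posterior is consistent and reproducible", {
  set.seed(7)
  mu0 <- c(-15, 16)
  S0 <- matrix(c(1.5, 0.4, 0.4, 0.8), 2)
  xy <- isopart:::.rmvn2(2000, mu0, S0)
  np <- fit_niche(xy, ndraw = 2000, seed = 3)
  expect_lt(max(abs(colMeans(np$mu) - mu0)), 0.05)

  np2 <- fit_niche(xy, ndraw = 2000, seed = 3)
  expect_identical(np$mu, np2$mu)
  expect_identical(np$Sigma, np2$Sigma)

  coll <- cbind(1:3, 2 * (1:3))
  expect_error(fit_niche(coll), "rank 1")
})

test_that("SEA_B brackets the plug-in area", {
  set.seed(8)
  S0 <- matrix(c(2, -0.6, -0.6, 1.2), 2)
  xy <- isopart:::.rmvn2(1000, c(0, 0), S0)
  ar <- sea_b(fit_niche(xy, ndraw = 2000, seed = 1))
  expect_lt(abs(ar$mean - standard_ellipse_area(S0)) /
              standard_ellipse_area(S0), 0.08)

  # coverage of the plug-in area across replicates
  hits <- 0L
  for (r in 1:10) {
    xy <- isopart:::.rmvn2(300, c(0, 0), S0)
    plug <- pi * sqrt(det(cov(xy)))
    a <- sea_b(fit_niche(xy, ndraw = 1000, seed = r))
    hits <- hits + (plug >= a$hdi[1] && plug <= a$hdi[2])
  }
  expect_gte(hits, 9L)

  # constant-Sigma draws give constant areas
  npc <- niche_posterior(c(0, 0), diag(c(4, 1)), ndraw = 100)
  expect_equal(unique(sea_b(npc)$draws), 2 * pi)
})

test_that("area comparisons report direction and magnitude", {
  set.seed(9)
  a <- rnorm(2000, 10, 0.5)
  cmp_same <- compare_areas(a, a + rnorm(2000, 0, 0.5) * 0)
  expect_equal(cmp_same$p_greater, 0.5, tolerance = 0.02)

  xs <- isopart:::.rmvn2(500, c(0, 0), diag(2))      # area pi
  big <- sea_b(fit_niche(isopart:::.rmvn2(500, c(0, 0), diag(2) * 4),
                         ndraw = 1000, seed = 2))    # area 4*pi
  small <- sea_b(fit_niche(xs, ndraw = 1000, seed = 3))
  cmp <- compare_areas(big, small)
  expect_gt(cmp$p_greater, 0.99)
  expect_gt(cmp$mean_diff, 0)
})
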