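# Posterior summary machinery: HDI, convergence diagnostics, directional
# probabilities.

test_that("hdi finds the shortest mass-covering interval", {
  expect_equal(as.numeric(hdi(rep(4.2, 100))), c(4.2, 4.2))

  set.seed(11)
  h <- hdi(rnorm(1e5), 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)

  g <- hdi(seq(0, 1, length.out = 1000), 0.95)
  expect_lt(abs((g[["upper"]] - g[["lower"]]) - 0.95), 0.005)

  expect_error(hdi(rnorm(10)), "at least 50")
  expect_error(hdi(rnorm(100), mass = 1.2), "in \\(0, 1\\)")
})

test_that("hdi is equivariant under monotone affine maps", {
  set.seed(12)
  x <- rexp(500)
  h0 <- hdi(x, 0.9)
  for (ab in list(c(2, 1), c(0.5, -3), c(10, 0))) {
    h1 <- hdi(ab[1] * x + ab[2], 0.9)
    expect_equal(as.numeric(h1), as.numeric(ab[1] * h0 + ab[2]),
                 tolerance = 1e-12)
  }
  # a decreasing map swaps the endpoints
  h2 <- hdi(-x, 0.9)
  expect_equal(as.numeric(h2), rev(-as.numeric(h0)), tolerance = 1e-12)
})

test_that("rhat distinguishes stationary from non-mixing chains", {
  set.seed(21)
  expect_lt(rhat(matrix(rnorm(30000), ncol = 3)), 1.01)
  expect_gte(rhat(matrix(rnorm(30000), ncol = 3)), 1.0)

  sep <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(rhat(sep), 1.5)

  expect_identical(rhat(matrix(7, 100, 3)), 1)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  # invariant to common affine rescaling of all chains
  m <- matrix(rnorm(4000), ncol = 4)
  expect_equal(rhat(m), rhat(5 * m - 2), tolerance = 1e-10)
})

test_that("ess matches iid and AR(1) references", {
  set.seed(31)
  m <- matrix(rnorm(30000), ncol = 3)
  expect_lt(abs(ess(m) - 30000) / 30000, 0.2)

  ar <- sapply(1:3, function(k) as.numeric(arima.sim(list(ar = 0.9), 10000)))
  nominal <- 30000 * (1 - 0.9) / (1 + 0.9)
  expect_lt(abs(ess(ar) - nominal) / nominal, 0.25)

  expect_identical(ess(matrix(1, 100, 2)), 0)

  # independent oracle: coda's spectral-density estimate on the same chains
  coda_est <- sum(coda::effectiveSize(coda::mcmc.list(
    lapply(seq_len(ncol(ar)), function(j) coda::mcmc(ar[, j]))
  )))
  expect_lt(abs(ess(ar) - coda_est) / coda_est, 0.5)
})

test_that("prob_greater follows the tie convention and complementarity", {
  expect_identical(prob_greater(rep(1, 10), 0), 1)
  x <- rnorm(100)
  expect_identical(prob_greater(x, x), 0.5)

  set.seed(41)
  a <- rnorm(1e5)
  b <- rnorm(1e5)
  expect_lt(abs(prob_greater(a, b) - 0.5), 0.01)

  # complementarity holds exactly, including with ties, in both modes
  a2 <- sample(1:5, 50, replace = TRUE)
  b2 <- sample(1:5, 50, replace = TRUE)
  expect_equal(prob_greater(a2, b2) + prob_greater(b2, a2), 1)
  expect_equal(prob_greater(a2, b2, "independent") +
                 prob_greater(b2, a2, "independent"), 1)

  expect_error(prob_greater(numeric(0), 1), "nonempty")
})

test_that("independent comparison equals the brute-force cross product", {
  set.seed(42)
  a <- sample(seq(0, 2, 0.25), 150, replace = TRUE)
  b <- sample(seq(0, 2, 0.25), 80, replace = TRUE)
  brute <- mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
  expect_equal(prob_greater(a, b, "independent"), brute, tolerance = 1e-12)
})
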