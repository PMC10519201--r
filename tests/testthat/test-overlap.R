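# Directional niche overlap: region membership and Monte-Carlo overlap.

test_that("niche-region membership follows the chi-square boundary", {
  expect_true(in_niche_region(c(0, 0), c(0, 0), diag(2), 0.5))
  # chi-square(2) 0.95 quantile is 5.9915: 2.44^2 inside, 2.46^2 outside
  expect_true(in_niche_region(c(2.44, 0), c(0, 0), diag(2), 0.95))
  expect_false(in_niche_region(c(2.46, 0), c(0, 0), diag(2), 0.95))
  # as conf -> 1 a fixed point ends up inside
  expect_true(in_niche_region(c(4, 0), c(0, 0), diag(2), 0.99995))
  # vectorised input
  got <- in_niche_region(rbind(c(0, 0), c(5, 5)), c(0, 0), diag(2), 0.95)
  expect_equal(got, c(TRUE, FALSE))
  expect_error(in_niche_region(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("self-overlap of a point-mass niche approximates conf", {
  np <- niche_posterior(c(-15, 16), diag(2), ndraw = 60)
  ov <- directional_overlap(np, np, conf = 0.95, nmc = 2e4, seed = 1)
  expect_lt(abs(ov$mean_pct / 100 - 0.95), 0.02)
  expect_true(all(ov$draws >= 0 & ov$draws <= 1))
})

test_that("separated niches do not overlap", {
  a <- niche_posterior(c(0, 0), diag(2), ndraw = 60)
  b <- niche_posterior(c(50, 0), diag(2), ndraw = 60)
  ov <- directional_overlap(a, b, nmc = 2000, seed = 1)
  expect_lt(ov$mean_pct, 0.1)
})

test_that("overlap is directional: broad niches swallow narrow ones", {
  broad <- niche_posterior(c(0, 0), diag(2) * 9, ndraw = 80)
  narrow <- niche_posterior(c(1, 0), diag(2) * 0.25, ndraw = 80)
  into_broad <- directional_overlap(narrow, broad, nmc = 4000, seed = 2)
  into_narrow <- directional_overlap(broad, narrow, nmc = 4000, seed = 2)
  expect_gt(into_broad$mean_pct, 90)
  expect_lt(into_narrow$mean_pct, 30)
})

test_that("overlap_matrix has the right shape and is reproducible", {
  d <- simulate_isotopes(tiny_iso_spec(n = 30L), seed = 3)
  nps <- fit_niche_by_group(d, ndraw = 200, seed = 1)
  m1 <- overlap_matrix(nps, nmc = 1000, seed = 9)
  m2 <- overlap_matrix(nps, nmc = 1000, seed = 9)
  expect_equal(dim(m1), c(3L, 3L))
  expect_true(all(is.na(diag(m1))))
  expect_true(all(m1[!is.na(m1)] >= 0 & m1[!is.na(m1)] <= 100))
  expect_identical(unclass(m1)[1:3, 1:3], unclass(m2)[1:3, 1:3])
  expect_error(overlap_matrix(nps[1]), "at least 2")
})

test_that("Monte-Carlo error shrinks like 1/sqrt(nmc)", {
  np <- niche_posterior(c(0, 0), diag(2), ndraw = 1)
  est <- function(nmc, reps) {
    vapply(seq_len(reps), function(r) {
      directional_overlap(np, np, conf = 0.8, nmc = nmc, seed = 100 + r)$draws
    }, numeric(1L))
  }
  sd_small <- sd(est(1000, 30))
  sd_large <- sd(est(16000, 30))
  # fourfold nmc increase should cut the sd roughly by 4
  expect_gt(sd_small / sd_large, 2.4)
  expect_lt(sd_small / sd_large, 6.8)
})
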