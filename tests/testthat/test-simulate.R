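# Synthetic-data generators: reproducibility, calibration and validation.

test_that("isotope generator is reproducible and validates its spec", {
  spec <- default_isotope_spec()
  expect_identical(simulate_isotopes(spec, seed = 5),
                   simulate_isotopes(spec, seed = 5))
  expect_false(identical(simulate_isotopes(spec, seed = 5),
                         simulate_isotopes(spec, seed = 6)))

  expect_error(isotope_sim_spec("a", 10, c(-15, 16), diag(2), nu = 2),
               "nu")
  expect_error(isotope_sim_spec("a", 10, c(-15, 16),
                                matrix(c(1, 2, 2, 1), 2), nu = 8),
               "cov")
  expect_error(isotope_sim_spec("a", -3, c(-15, 16), diag(2)), "n")
})

test_that("categorical levels come from the controlled vocabularies", {
  d <- simulate_isotopes(default_isotope_spec(), seed = 2)
  expect_true(all(d$sex %in% c("female", "male")))
  expect_true(all(d$stage %in% c("adult", "juvenile")))
  expect_true(all(d$season %in% c("cold", "warm")))
  # exact group sizes from the spec
  expect_equal(unname(table(d$species)[c("H_dipterurus", "N_entemedor",
                                         "R_steindachneri")]),
               c(81L, 69L, 74L), ignore_attr = TRUE)
  expect_equal(sum(d$species == "H_dipterurus" & d$season == "cold"), 18L)
})

test_that("large-n sample mean matches the spec mean", {
  spec <- isotope_sim_spec("H_dipterurus", 50000L, c(-15, 16), diag(2), nu = 8)
  d <- simulate_isotopes(spec, seed = 3)
  expect_lt(abs(mean(d$d13C) + 15), 0.05)
  expect_lt(abs(mean(d$d15N) - 16), 0.05)
})

test_that("raw t scatter has the nu/(nu-2) covariance scale factor", {
  set.seed(9)
  nu <- 5
  scatter <- matrix(c(2, 0.5, 0.5, 1), 2)
  y <- isopart:::.rmvt_scatter(2e5, c(0, 0), scatter, nu)
  expect_equal(cov(y), nu / (nu - 2) * scatter, tolerance = 0.05)
})

test_that("default spec reproduces the calibrated niche areas (plug-in)", {
  spec <- default_isotope_spec()
  target <- c(H_dipterurus = 9.66, N_entemedor = 2.15, R_steindachneri = 1.68)
  spec$n <- rep(5000L, 3)
  spec$factor_counts <- lapply(spec$factor_counts, function(fc) {
    lapply(fc, function(cnt) {
      out <- round(cnt / sum(cnt) * 5000)
      out[1L] <- 5000L - out[2L]
      out
    })
  })
  d <- simulate_isotopes(spec, seed = 4)
  for (sp in names(target)) {
    xy <- d[d$species == sp, c("d13C", "d15N")]
    plug <- pi * sqrt(det(cov(xy)))
    expect_lt(abs(plug - target[[sp]]) / target[[sp]], 0.10)
  }
})

test_that("diet generator is reproducible with valid zero structure", {
  spec <- default_diet_spec()
  expect_identical(simulate_diet(spec, seed = 5), simulate_diet(spec, seed = 5))

  d <- simulate_diet(spec, seed = 1)
  w <- as.matrix(d[, prey_categories()])
  expect_true(all(w >= 0))
  expect_true(all(rowSums(w) > 0)) # empty stomachs are redrawn
  expect_equal(sum(d$species == "H_dipterurus"), 205L)
  expect_equal(sum(d$species == "N_entemedor"), 187L)

  # occurrence probability zero forces an all-zero column
  sp0 <- sipunculid_split_spec()
  sp0$occurrence[, "fishes"] <- 0
  d0 <- simulate_diet(sp0, seed = 2)
  expect_true(all(d0$fishes == 0))

  expect_error(diet_sim_spec(default_diet_spec()$classes,
                             occurrence = matrix(1.4, 16, 10),
                             meanlog = matrix(0, 16, 10)),
               "occurrence")
  expect_error(diet_sim_spec(default_diet_spec()$classes,
                             occurrence = matrix(0.5, 16, 10),
                             meanlog = matrix(0, 16, 10), sdlog = -1),
               "sdlog")
})
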