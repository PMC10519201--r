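# Hierarchical bivariate Student-t model: recovery, conventions, policies.
# Sampler budgets here are deliberately lean; the model's statistical
# calibration is exercised more deeply in the acceptance suite.

test_that("the model recovers separated species means and contrasts", {
  spec <- tiny_iso_spec(n = 60L,
                        means = rbind(c(-16, 16), c(-13, 18), c(-14, 16.2)))
  d <- simulate_isotopes(spec, seed = 21)
  fit <- fit_isotope_hier(d, quick_hier_config(), seed = 1)

  sm <- species_means(fit, force = TRUE)
  truth <- c(H_dipterurus = -16, N_entemedor = -13, R_steindachneri = -14)
  got <- sm[sm$isotope == "d13C", ]
  expect_lt(max(abs(got$mean - truth[got$species])), 0.35)
  # Table-style ordering: descending mean within isotope
  expect_false(is.unsorted(rev(got$mean)))

  ct <- species_contrasts(fit, force = TRUE)
  hd_ne_c <- ct[ct$pair == "H_dipterurus - N_entemedor" & ct$isotope == "d13C", ]
  expect_gt(hd_ne_c$p_less, 0.99) # 3 per-mil separation
  expect_equal(ct$p_less + ct$p_greater, rep(1, nrow(ct)))

  # summaries are deterministic given the fit
  expect_identical(species_means(fit, force = TRUE),
                   species_means(fit, force = TRUE))
  expect_identical(factor_effects(fit, force = TRUE),
                   factor_effects(fit, force = TRUE))
})

test_that("single-species fits recover the generative mean", {
  spec <- isotope_sim_spec("H_dipterurus", 80L, c(-15, 16), diag(0.8, 2),
                           nu = 8)
  d <- simulate_isotopes(spec, seed = 22)
  fit <- fit_isotope_hier(d, quick_hier_config(), seed = 2,
                          allow_single_species = TRUE)
  sm <- species_means(fit, force = TRUE)
  expect_lt(abs(sm$mean[sm$isotope == "d13C"] + 15), 0.3)
  expect_lt(abs(sm$mean[sm$isotope == "d15N"] - 16), 0.3)
  expect_error(species_contrasts(fit, force = TRUE), ">= 2 species")
  expect_error(fit_isotope_hier(d, quick_hier_config(), seed = 2),
               "allow_single_species")
})

test_that("flipping a factor coding flips the slope sign", {
  spec <- isotope_sim_spec("H_dipterurus", 90L, c(-15, 16), diag(0.8, 2),
                           nu = 30,
                           shifts = list(rbind(season = c(1.2, 0),
                                               sex = c(0, 0),
                                               stage = c(0, 0))))
  d <- simulate_isotopes(spec, seed = 23)
  fit <- fit_isotope_hier(d, quick_hier_config(), seed = 3,
                          allow_single_species = TRUE)
  d_flip <- d
  d_flip$season <- ifelse(d$season == "cold", "warm", "cold")
  fit_flip <- fit_isotope_hier(d_flip, quick_hier_config(), seed = 3,
                               allow_single_species = TRUE)
  ef <- factor_effects(fit, force = TRUE)
  ef_flip <- factor_effects(fit_flip, force = TRUE)
  b <- ef[ef$factor == "season" & ef$isotope == "d13C", "mean"]
  b_flip <- ef_flip[ef_flip$factor == "season" & ef_flip$isotope == "d13C",
                    "mean"]
  expect_gt(b, 0.5)       # cold-coded shift of +1.2 recovered
  expect_lt(b_flip, -0.5) # relabelled data flips the sign
  expect_lt(abs(b + b_flip), 0.4)
})

test_that("the convergence policy flags and guards summaries", {
  d <- simulate_isotopes(tiny_iso_spec(n = 25L), seed = 24)
  cfg <- hier_config(chains = 2L, adapt = 150L, warmup = 50L, draws = 150L,
                     target_ess = 1e6, max_retries = 0L)
  fit <- fit_isotope_hier(d, cfg, seed = 4)
  expect_false(fit$converged)
  expect_error(species_means(fit), "non-converged")
  expect_s3_class(species_means(fit, force = TRUE), "data.frame")
  expect_identical(fit$divergences, 0L)
})

test_that("Student-t fits on near-normal data agree with large-nu truth", {
  # with nu fixed large in the generator the model's posterior predictive
  # machinery and point predictions behave like the normal model
  spec <- isotope_sim_spec("N_entemedor", 80L, c(-13, 18), diag(0.5, 2),
                           nu = 1000)
  d <- simulate_isotopes(spec, seed = 25)
  fit <- fit_isotope_hier(d, quick_hier_config(), seed = 5,
                          allow_single_species = TRUE)
  pr <- predict(fit)
  expect_equal(dim(pr), c(80L, 2L))
  expect_lt(abs(mean(pr[, "d13C"]) + 13), 0.3)
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.3)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_lt(abs(mean(sims[[1]]$d13C) + 13), 0.6)
})

test_that("Laplace shrinkage pulls null slopes towards zero", {
  # same data, shrinkage prior vs an essentially flat slope prior
  shrunk <- numeric(0)
  loose <- numeric(0)
  for (s in 1:3) {
    d <- simulate_isotopes(tiny_iso_spec(n = 40L), seed = 30 + s)
    f1 <- fit_isotope_hier(d, quick_hier_config(laplace_hyper_sd = 1),
                           seed = s)
    f2 <- fit_isotope_hier(d, quick_hier_config(laplace_hyper_sd = 50),
                           seed = s)
    shrunk <- c(shrunk, abs(factor_effects(f1, force = TRUE)$mean))
    loose <- c(loose, abs(factor_effects(f2, force = TRUE)$mean))
  }
  expect_lt(mean(shrunk), mean(loose))
})
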