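# Shared fixtures: lean sampler budgets and reduced tuning grids keep the
# unit tests fast while exercising the same code paths as the defaults.

quick_hier_config <- function(...) {
  hier_config(chains = 2L, adapt = 200L, warmup = 100L, draws = 400L,
              target_ess = 50, rhat_max = 1.2, max_retries = 0L, ...)
}

small_rf_grid <- function() {
  expand.grid(num_trees = c(50L, 100L), max_depth = c(2L, 0L),
              mtry = c(2L, 5L))
}

# A minimal three-species isotope spec with controllable shifts.
tiny_iso_spec <- function(n = 60L, shifts = NULL, means = NULL, nu = 8,
                          area = 3) {
  isotope_sim_spec(
    species = c("H_dipterurus", "N_entemedor", "R_steindachneri"),
    n = n,
    mean = means %||% rbind(c(-16, 16), c(-13, 18), c(-14, 16.2)),
    cov = diag(area / pi, 2L),
    nu = nu,
    shifts = shifts
  )
}

# Two-class diet spec separated only in sipunculid occurrence.
sipunculid_split_spec <- function(n = 100L, p_high = 0.9, p_low = 0.05) {
  base_p <- rep(0.4, 10)
  occ <- rbind(replace(base_p, 8L, p_high), replace(base_p, 8L, p_low))
  diet_sim_spec(
    classes = data.frame(species = c("H_dipterurus", "N_entemedor"),
                         sex = "female", stage = "adult", season = "warm",
                         n = n),
    occurrence = occ,
    meanlog = matrix(0.8, 2L, 10L),
    sdlog = 0.6
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
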