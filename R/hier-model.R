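# Hierarchical bivariate robust Bayesian model of (d13C, d15N): a
# multivariate Student-t likelihood whose mean is, for individual i of
# species s,
#   mu_i = alpha_s + sum_f beta_{s,f} * x_{f,i}
# with binary codings cold = 1 / warm = 0, male = 1 / female = 0,
# juvenile = 1 / adult = 0. Intercepts are partially pooled across species
# through community-level location/scale hyperpriors; slopes carry a
# Laplace ("Bayesian lasso") prior centered at 0 whose scale is learned per
# factor and isotope axis and shared across species (pooling the shrinkage
# strength). Each species has its own scale matrix via a separation
# strategy (half-normal axis scales, LKJ(2)-equivalent correlation prior),
# and a single heavy-tail parameter nu is shared.

FACTOR_NAMES <- c("season", "sex", "stage")
FACTOR_CODED <- c(season = "cold", sex = "male", stage = "juvenile")

#' Configuration for the hierarchical isotope model
#'
#' Sampler settings and prior scales for [fit_isotope_hier()]. The defaults
#' run three chains until the convergence policy is met: rank-normalized
#' split R-hat below `rhat_max` (1.01) and bulk ESS above `target_ess`
#' (2000) for every monitored parameter, retrying with doubled draws up to
#' `max_retries` times.
#'
#' @param chains Number of MCMC chains (>= 2).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Kept iterations per chain in the first attempt.
#' @param target_ess Minimum bulk ESS per parameter.
#' @param rhat_max Maximum R-hat per parameter.
#' @param hdi_mass Probability mass for posterior intervals.
#' @param max_retries Automatic retries with doubled draws on
#'   non-convergence.
#' @param alpha_hyper_sd Hyper-prior sd (per-mil) for the community
#'   intercept location and scale.
#' @param laplace_hyper_sd Half-normal sd of the Laplace slope scale.
#' @param cov_scale Half-normal sd (per-mil) of the per-axis residual
#'   scales.
#' @return List of class `hier_config`.
#' @export
hier_config <- function(chains = 3L, adapt = 1000L, warmup = 1000L,
                        draws = 2000L, target_ess = 2000, rhat_max = 1.01,
                        hdi_mass = 0.95, max_retries = 2L,
                        alpha_hyper_sd = 5, laplace_hyper_sd = 1,
                        cov_scale = 2.5) {
  if (chains < 2L) stop("'chains' must be >= 2", call. = FALSE)
  stopifnot(adapt > 0, warmup >= 0, draws > 0, target_ess > 0, rhat_max > 1,
            hdi_mass > 0, hdi_mass < 1, max_retries >= 0,
            alpha_hyper_sd > 0, laplace_hyper_sd > 0, cov_scale > 0)
  structure(as.list(environment()), class = "hier_config")
}

#' Fit the hierarchical bivariate Student-t isotope model
#'
#' Fits the package's core model: both isotope ratios regressed jointly on
#' season, sex and maturity stage with all effects nested within species,
#' a shared heavy-tailed Student-t likelihood, Laplace-shrunk slopes and
#' partially pooled intercepts (see the package vignette for the full
#' model statement). Sampling uses Gibbs/slice MCMC through JAGS with the
#' Student-t expressed as its exact gamma scale-mixture; convergence is
#' declared only when every monitored parameter passes the R-hat and ESS
#' thresholds of `config`, otherwise sampling is retried with doubled
#' draws and finally flagged.
#'
#' @param data Validated isotope table (see [validate_isotope_table()]).
#' @param config A [hier_config()].
#' @param seed Integer seed (chains use derived RNG streams).
#' @param allow_single_species Permit fitting with one species (hierarchy
#'   collapses to that species' parameters).
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `hier_fit` with elements `draws` (iterations x
#'   chains x parameters array), `diagnostics` (per-parameter R-hat and
#'   ESS), `converged`, `divergences` (always 0: the Gibbs/slice sampler
#'   family has no divergence diagnostic), `species`, `composition` (the
#'   observed factor composition per species used by [species_means()]),
#'   `data`, `config`, `seed`.
#' @seealso [species_means()], [species_contrasts()], [factor_effects()]
#' @export
fit_isotope_hier <- function(data, config = hier_config(), seed = 1L,
                             allow_single_species = FALSE, quiet = TRUE) {
  data <- validate_isotope_table(data)
  species <- sort(unique(data$species))
  if (length(species) < 2L && !allow_single_species) {
    stop("need >= 2 species (or set allow_single_species = TRUE)", call. = FALSE)
  }
  sp <- match(data$species, species)
  x <- cbind(season = as.numeric(data$season == FACTOR_CODED["season"]),
             sex = as.numeric(data$sex == FACTOR_CODED["sex"]),
             stage = as.numeric(data$stage == FACTOR_CODED["stage"]))
  y <- as.matrix(data[, c("d13C", "d15N")])
  jags_data <- list(
    N = nrow(y), S = length(species), F = ncol(x), y = y, sp = sp, x = x,
    gm = colMeans(y), alpha_hyper_sd = config$alpha_hyper_sd,
    laplace_hyper_sd = config$laplace_hyper_sd, cov_scale = config$cov_scale
  )
  model_file <- system.file("jags", "mvst_hier.jags", package = "isopart")
  if (model_file == "") { # during development without installation
    model_file <- file.path("inst", "jags", "mvst_hier.jags")
  }
  inits <- lapply(seq_len(config$chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = .stage_seed(seed, k))
  })
  monitor <- c("alpha", "beta", "sig", "rho", "nu", "b", "mu_alpha", "sd_alpha")
  run <- function(n_iter) {
    jm <- rjags::jags.model(model_file, data = jags_data,
                            n.chains = config$chains, n.adapt = config$adapt,
                            inits = inits, quiet = quiet)
    if (config$warmup > 0) {
      stats::update(jm, config$warmup, progress.bar = "none")
    }
    rjags::coda.samples(jm, monitor, n.iter = n_iter, progress.bar = "none")
  }
  attempt <- 0L
  n_iter <- config$draws
  repeat {
    samples <- run(n_iter)
    diag <- .hier_diagnostics(samples)
    converged <- all(diag$rhat < config$rhat_max) &&
      all(diag$ess > config$target_ess)
    if (converged || attempt >= config$max_retries) break
    attempt <- attempt + 1L
    n_iter <- n_iter * 2L
  }
  arr <- .mcmc_list_to_array(samples)
  comp <- do.call(rbind, lapply(seq_along(species), function(s) {
    colMeans(x[sp == s, , drop = FALSE])
  }))
  rownames(comp) <- species
  structure(list(
    draws = arr, diagnostics = diag, converged = converged,
    divergences = 0L,
    divergence_note = "Gibbs/slice sampler: divergence diagnostics not applicable",
    species = species, factors = FACTOR_NAMES, codings = FACTOR_CODED,
    composition = comp, data = data, config = config, seed = seed,
    attempts = attempt + 1L, kept_iter = n_iter
  ), class = "hier_fit")
}

# mcmc.list -> iterations x chains x parameters array.
.mcmc_list_to_array <- function(samples) {
  pn <- colnames(samples[[1L]])
  arr <- array(NA_real_,
               dim = c(nrow(samples[[1L]]), length(samples), length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (ch in seq_along(samples)) arr[, ch, ] <- as.matrix(samples[[ch]])
  arr
}

.hier_diagnostics <- function(samples) {
  pn <- colnames(samples[[1L]])
  m <- lapply(samples, as.matrix)
  rh <- vapply(pn, function(p) rhat(sapply(m, function(ch) ch[, p])), numeric(1L))
  es <- vapply(pn, function(p) {
    d <- sapply(m, function(ch) ch[, p])
    if (stats::var(as.vector(d)) < .Machine$double.eps) Inf else ess(d)
  }, numeric(1L))
  data.frame(parameter = pn, rhat = rh, ess = es, row.names = NULL)
}

# Flattened draws (iterations*chains) of one scalar parameter.
.par_draws <- function(fit, name) {
  as.vector(fit$draws[, , name])
}

.check_converged <- function(fit, force) {
  if (!fit$converged && !force) {
    stop("posterior is flagged non-converged; pass force = TRUE to summarise anyway",
         call. = FALSE)
  }
}

#' Posterior species-level isotope means
#'
#' Posterior distribution of each species' mean d13C and d15N: the species
#' intercept plus its slopes weighted by the observed factor composition of
#' that species' sample, approximating the sample-centered species mean.
#' Summarised by posterior mean and HDI, sorted within isotope in
#' descending order of the mean.
#'
#' @param fit A [fit_isotope_hier()] result.
#' @param composition Optional k x 3 matrix of factor weights (proportion
#'   coded cold/male/juvenile per species) replacing the observed
#'   composition.
#' @param force Summarise even if the fit is flagged non-converged.
#' @return Data frame (species, isotope, mean, hdi_lower, hdi_upper) with
#'   attribute `draws` (list of draw matrices per isotope).
#' @export
species_means <- function(fit, composition = NULL, force = FALSE) {
  stopifnot(inherits(fit, "hier_fit"))
  .check_converged(fit, force)
  comp <- composition %||% fit$composition
  k <- length(fit$species)
  mass <- fit$config$hdi_mass
  out <- list()
  draws_by_iso <- list()
  for (j in 1:2) {
    iso <- c("d13C", "d15N")[j]
    dm <- sapply(seq_len(k), function(s) {
      d <- .par_draws(fit, sprintf("alpha[%d,%d]", s, j))
      for (f in 1:3) {
        d <- d + comp[s, f] * .par_draws(fit, sprintf("beta[%d,%d,%d]", s, f, j))
      }
      d
    })
    colnames(dm) <- fit$species
    draws_by_iso[[iso]] <- dm
    sm <- data.frame(
      species = fit$species, isotope = iso, mean = colMeans(dm),
      hdi_lower = apply(dm, 2L, function(v) hdi(v, mass)[1L]),
      hdi_upper = apply(dm, 2L, function(v) hdi(v, mass)[2L])
    )
    out[[iso]] <- sm[order(-sm$mean), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- draws_by_iso
  res
}

#' Pairwise species contrasts of posterior means
#'
#' Draw-wise differences of the species-level isotope means for every
#' species pair: mean difference M, its HDI, and the directional
#' probabilities P(diff < 0) and P(diff > 0) (paired comparison, same
#' model).
#'
#' @inheritParams species_means
#' @return Data frame (pair, isotope, mean_diff, hdi_lower, hdi_upper,
#'   p_less, p_greater).
#' @export
species_contrasts <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "hier_fit"))
  .check_converged(fit, force)
  if (length(fit$species) < 2L) stop("need >= 2 species", call. = FALSE)
  sm <- species_means(fit, force = force)
  draws <- attr(sm, "draws")
  mass <- fit$config$hdi_mass
  pairs <- utils::combn(fit$species, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    do.call(rbind, lapply(c("d13C", "d15N"), function(iso) {
      dd <- draws[[iso]][, a] - draws[[iso]][, b]
      h <- hdi(dd, mass)
      data.frame(pair = paste(a, "-", b), isotope = iso,
                 mean_diff = mean(dd), hdi_lower = h[1L], hdi_upper = h[2L],
                 p_less = prob_greater(0, dd), p_greater = prob_greater(dd, 0))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Posterior summaries of the factor slopes
#'
#' One row per species x factor x isotope axis: the posterior mean of the
#' slope (the coded-level minus reference-level difference in per-mil), its
#' HDI and the directional probabilities P(beta > 0) / P(beta < 0).
#' Deterministic given the fit.
#'
#' @inheritParams species_means
#' @return Data frame (species, factor, isotope, mean, hdi_lower,
#'   hdi_upper, p_greater, p_less).
#' @export
factor_effects <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "hier_fit"))
  .check_converged(fit, force)
  mass <- fit$config$hdi_mass
  grid <- expand.grid(s = seq_along(fit$species), f = 1:3, j = 1:2)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    s <- grid$s[r]; f <- grid$f[r]; j <- grid$j[r]
    d <- .par_draws(fit, sprintf("beta[%d,%d,%d]", s, f, j))
    h <- hdi(d, mass)
    data.frame(species = fit$species[s], factor = fit$factors[f],
               isotope = c("d13C", "d15N")[j], mean = mean(d),
               hdi_lower = h[1L], hdi_upper = h[2L],
               p_greater = prob_greater(d, 0), p_less = prob_greater(0, d))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("Hierarchical bivariate Student-t isotope model (Laplace-shrunk slopes)\n")
  cat(sprintf("  %d observations, %d species; %d chains x %d kept iterations\n",
              nrow(x$data), length(x$species), x$config$chains, x$kept_iter))
  cat(sprintf("  convergence: %s (max R-hat %.4f, min ESS %.0f, attempts %d)\n",
              if (x$converged) "PASSED" else "FLAGGED NON-CONVERGED",
              max(x$diagnostics$rhat), min(x$diagnostics$ess), x$attempts))
  cat(sprintf("  divergences: %d (%s)\n", x$divergences, x$divergence_note))
  invisible(x)
}

#' @export
summary.hier_fit <- function(object, force = FALSE, ...) {
  out <- list(
    species_means = species_means(object, force = force),
    effects = factor_effects(object, force = force),
    nu = c(mean = mean(.par_draws(object, "nu")),
           hdi(.par_draws(object, "nu"), object$config$hdi_mass)),
    diagnostics = object$diagnostics,
    converged = object$converged
  )
  class(out) <- "summary.hier_fit"
  out
}

#' @export
print.summary.hier_fit <- function(x, ...) {
  cat("Species-level posterior means (sorted within isotope):\n")
  print(x$species_means, digits = 4L, row.names = FALSE)
  cat(sprintf("\nStudent-t df nu: mean %.1f, HDI (%.1f, %.1f)\n",
              x$nu[1L], x$nu[2L], x$nu[3L]))
  cat("\nFactor slopes (coded minus reference level):\n")
  print(x$effects, digits = 3L, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hier_fit <- function(object, ...) {
  k <- length(object$species)
  alpha <- matrix(NA_real_, k, 2L,
                  dimnames = list(object$species, c("d13C", "d15N")))
  for (s in seq_len(k)) for (j in 1:2) {
    alpha[s, j] <- mean(.par_draws(object, sprintf("alpha[%d,%d]", s, j)))
  }
  beta <- array(NA_real_, dim = c(k, 3L, 2L),
                dimnames = list(object$species, object$factors,
                                c("d13C", "d15N")))
  for (s in seq_len(k)) for (f in 1:3) for (j in 1:2) {
    beta[s, f, j] <- mean(.par_draws(object, sprintf("beta[%d,%d,%d]", s, f, j)))
  }
  list(alpha = alpha, beta = beta)
}

# Posterior-mean fitted value for each row of newdata.
#' @export
predict.hier_fit <- function(object, newdata = NULL, ...) {
  d <- validate_isotope_table(newdata %||% object$data)
  cf <- coef(object)
  s <- match(d$species, object$species)
  if (anyNA(s)) stop("newdata contains species not in the fit", call. = FALSE)
  x <- cbind(as.numeric(d$season == "cold"), as.numeric(d$sex == "male"),
             as.numeric(d$stage == "juvenile"))
  out <- matrix(NA_real_, nrow(d), 2L, dimnames = list(NULL, c("d13C", "d15N")))
  for (j in 1:2) {
    out[, j] <- cf$alpha[s, j] +
      x[, 1L] * cf$beta[cbind(s, 1L, j)] +
      x[, 2L] * cf$beta[cbind(s, 2L, j)] +
      x[, 3L] * cf$beta[cbind(s, 3L, j)]
  }
  out
}

#' @export
residuals.hier_fit <- function(object, ...) {
  as.matrix(object$data[, c("d13C", "d15N")]) - predict(object)
}

#' @export
simulate.hier_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  # posterior predictive: one dataset per sim, drawing a posterior draw and
  # then new Student-t observations at the observed design
  .with_seed(seed %||% object$seed + 7L, {
    n_iter <- dim(object$draws)[1L]
    n_ch <- dim(object$draws)[2L]
    d <- object$data
    s <- match(d$species, object$species)
    x <- cbind(as.numeric(d$season == "cold"), as.numeric(d$sex == "male"),
               as.numeric(d$stage == "juvenile"))
    lapply(seq_len(nsim), function(k) {
      it <- sample.int(n_iter, 1L); ch <- sample.int(n_ch, 1L)
      g <- function(nm) {
        # JAGS drops the index on length-one vectors (e.g. "rho" when S = 1)
        if (!nm %in% dimnames(object$draws)[[3L]]) nm <- sub("\\[.*", "", nm)
        object$draws[it, ch, nm]
      }
      nu <- g("nu")
      y <- matrix(NA_real_, nrow(d), 2L, dimnames = list(NULL, c("d13C", "d15N")))
      for (sp_i in seq_along(object$species)) {
        rows <- which(s == sp_i)
        if (!length(rows)) next
        sig1 <- g(sprintf("sig[%d,1]", sp_i)); sig2 <- g(sprintf("sig[%d,2]", sp_i))
        rho <- g(sprintf("rho[%d]", sp_i))
        Sig <- matrix(c(sig1^2, rho * sig1 * sig2, rho * sig1 * sig2, sig2^2), 2L)
        mu <- sapply(1:2, function(j) {
          g(sprintf("alpha[%d,%d]", sp_i, j)) +
            x[rows, , drop = FALSE] %*% vapply(1:3, function(f)
              g(sprintf("beta[%d,%d,%d]", sp_i, f, j)), numeric(1L))
        })
        y[rows, ] <- matrix(mu, length(rows), 2L) +
          .rmvt_scatter(length(rows), c(0, 0), Sig, nu)
      }
      out <- d
      out$d13C <- y[, 1L]; out$d15N <- y[, 2L]
      out
    })
  })
}

#' Forest plot of the factor slopes
#'
#' Base-graphics forest plot of every species x factor x isotope slope
#' posterior (mean and HDI) with the zero line, mirroring the standard
#' presentation of nested effects.
#'
#' @param x A `hier_fit`.
#' @param force Plot even if flagged non-converged.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hier_fit <- function(x, force = FALSE, ...) {
  ef <- factor_effects(x, force = force)
  ef$label <- sprintf("%s %s %s", ef$species, ef$factor, ef$isotope)
  n <- nrow(ef)
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(ef$mean, seq_len(n), xlim = range(ef$hdi_lower, ef$hdi_upper),
                 yaxt = "n", xlab = "slope (per-mil)", ylab = "", pch = 16,
                 main = "Factor slopes (posterior mean and HDI)", ...)
  graphics::segments(ef$hdi_lower, seq_len(n), ef$hdi_upper, seq_len(n))
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = ef$label, las = 1, cex.axis = 0.7)
  invisible(ef)
}
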