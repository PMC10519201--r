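# Directional probabilistic niche overlap: the probability that a random
# individual of species A falls inside the alpha-level probability region of
# species B's bivariate niche, propagated over posterior uncertainty in both
# niches. Asymmetric by construction.

#' Membership in an elliptical niche region
#'
#' Tests whether points lie inside the `conf`-level probability region of a
#' bivariate normal niche: the Mahalanobis distance of `x` from `mu` under
#' `Sigma` is compared with the chi-square(2) quantile at `conf`.
#'
#' @param x A 2-vector or an n x 2 matrix of points (per-mil).
#' @param mu Niche mean 2-vector.
#' @param Sigma 2x2 symmetric positive-definite covariance.
#' @param conf Region probability level in (0, 1).
#' @return Logical vector.
#' @export
#' @examples
#' in_niche_region(c(2.44, 0), c(0, 0), diag(2), 0.95) # TRUE
#' in_niche_region(c(2.46, 0), c(0, 0), diag(2), 0.95) # FALSE
in_niche_region <- function(x, mu, Sigma, conf = 0.95) {
  if (!is.numeric(conf) || length(conf) != 1L || conf <= 0 || conf >= 1) {
    stop("'conf' must be a single number in (0, 1)", call. = FALSE)
  }
  if (!.is_spd(Sigma)) {
    stop("'Sigma' must be a symmetric positive-definite 2x2 matrix", call. = FALSE)
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  d2 <- stats::mahalanobis(x, center = mu, cov = Sigma)
  unname(d2 <= stats::qchisq(conf, df = 2L))
}

#' Directional niche overlap between two posteriors
#'
#' For each paired posterior draw d, the overlap of A onto B is
#' P(X in N_conf(B_d)) with X ~ Normal(mu_A_d, Sigma_A_d), estimated with
#' `nmc` Monte-Carlo points; the result is the posterior distribution of
#' that probability. The measure is asymmetric: a narrow niche nested inside
#' a broad one overlaps it almost fully while the converse overlap is small.
#'
#' @param postA,postB `niche_posterior` objects (A is the row species whose
#'   individuals are tested against B's region).
#' @param conf Probability level of B's niche region (default 0.95).
#' @param nmc Monte-Carlo points per posterior draw (>= 1000).
#' @param seed Integer seed.
#' @param mass HDI mass for the summary.
#' @return Object of class `overlap_result`: list with `draws` (overlap
#'   proportions in \[0, 1\]), `mean_pct` (mean x 100), `hdi_pct`, `conf`,
#'   `from`, `onto`.
#' @export
directional_overlap <- function(postA, postB, conf = 0.95, nmc = 1e4L,
                                seed = 1L, mass = 0.95) {
  stopifnot(inherits(postA, "niche_posterior"), inherits(postB, "niche_posterior"))
  if (!is.numeric(nmc) || nmc < 1e3) {
    stop("'nmc' must be at least 1000 Monte-Carlo points", call. = FALSE)
  }
  nmc <- as.integer(nmc)
  ndraw <- min(nrow(postA$mu), nrow(postB$mu))
  q <- stats::qchisq(conf, df = 2L)
  .with_seed(seed, {
    draws <- vapply(seq_len(ndraw), function(d) {
      X <- .rmvn2(nmc, postA$mu[d, ], postA$Sigma[, , d])
      mean(stats::mahalanobis(X, postB$mu[d, ], postB$Sigma[, , d]) <= q)
    }, numeric(1L))
    structure(list(
      draws = draws,
      mean_pct = 100 * mean(draws),
      hdi_pct = if (length(draws) >= 50L) 100 * hdi(draws, mass) else
        100 * range(draws),
      conf = conf, from = postA$group, onto = postB$group
    ), class = "overlap_result")
  })
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Directional overlap P(%s in %d%% region of %s): mean %.1f%% (%.1f, %.1f)\n",
              x$from, round(100 * x$conf), x$onto, x$mean_pct,
              x$hdi_pct[1L], x$hdi_pct[2L]))
  invisible(x)
}

#' Pairwise directional overlap matrix
#'
#' Mean directional overlaps (%) for every ordered pair of groups: entry
#' (row A, column B) is the mean probability that an individual of A lies
#' within the `conf`-level niche region of B. The diagonal is empty.
#'
#' @param posteriors Named list of `niche_posterior` objects (>= 2).
#' @inheritParams directional_overlap
#' @return k x k numeric matrix of mean overlaps in percent, `NA` diagonal,
#'   with attribute `draws` holding the full `overlap_result` objects.
#' @export
overlap_matrix <- function(posteriors, conf = 0.95, nmc = 1e4L, seed = 1L) {
  k <- length(posteriors)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  labs <- names(posteriors)
  if (is.null(labs)) {
    labs <- vapply(posteriors, function(p) p$group, character(1L))
  }
  m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  results <- list()
  idx <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      idx <- idx + 1L
      res <- directional_overlap(posteriors[[i]], posteriors[[j]],
                                 conf = conf, nmc = nmc,
                                 seed = .stage_seed(seed, idx))
      res$from <- labs[i]
      res$onto <- labs[j]
      m[i, j] <- res$mean_pct
      results[[paste(labs[i], labs[j], sep = " in ")]] <- res
    }
  }
  attr(m, "draws") <- results
  attr(m, "conf") <- conf
  m
}
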