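# Standard-ellipse isotopic niche geometry and its Bayesian posterior.
# The standard ellipse of a bivariate distribution (the 1-sd contour,
# containing ~40% of the mass for a normal) has area pi * sqrt(det(Sigma));
# its posterior distribution under a vague conjugate prior is the Bayesian
# standard ellipse area, SEA_B.

#' Standard ellipse area
#'
#' Area of the standard ellipse of a bivariate covariance matrix:
#' `pi * sqrt(lambda1 * lambda2) = pi * sqrt(det(Sigma))` where lambda are
#' the eigenvalues of Sigma. Rotation-invariant; scales with the square of a
#' common data scaling.
#'
#' @param Sigma 2x2 symmetric positive-definite covariance (per-mil squared).
#' @return Area in per-mil squared.
#' @export
#' @examples
#' standard_ellipse_area(diag(2)) # pi
#' standard_ellipse_area(diag(c(4, 1))) # 2 * pi
standard_ellipse_area <- function(Sigma) {
  if (!.is_spd(Sigma)) {
    stop("'Sigma' must be a symmetric positive-definite 2x2 matrix", call. = FALSE)
  }
  pi * sqrt(det(Sigma))
}

#' Small-sample corrected standard ellipse area (SEA_c)
#'
#' Multiplies the standard ellipse area by `(n - 1) / (n - 2)`, the standard
#' correction that removes the small-sample bias of the plug-in area.
#'
#' @inheritParams standard_ellipse_area
#' @param n Number of observations (>= 3).
#' @return Corrected area in per-mil squared.
#' @export
#' @examples
#' sea_c(diag(2), n = 12) # 1.1 * pi
sea_c <- function(Sigma, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3) {
    stop("'n' must be a single count >= 3", call. = FALSE)
  }
  standard_ellipse_area(Sigma) * (n - 1) / (n - 2)
}

#' Bayesian posterior of a bivariate isotopic niche
#'
#' Draws from the joint posterior of the mean vector and covariance matrix
#' of a group's (d13C, d15N) values under a weakly informative conjugate
#' normal-inverse-Wishart scheme (prior mean at the sample mean with
#' near-zero prior weight `kappa0`, inverse-Wishart with `nu0` degrees of
#' freedom and a near-zero scale matrix), mirroring the vague-prior
#' behaviour of standard Bayesian ellipse estimators. The posterior is the
#' basis for SEA_B areas ([sea_b()]) and directional overlaps
#' ([directional_overlap()]).
#'
#' @param xy Two-column matrix or data frame of (d13C, d15N) values; n >= 3
#'   non-collinear points.
#' @param ndraw Number of posterior draws.
#' @param seed Integer seed (identical data and seed give identical draws).
#' @param prior List with `kappa0`, `nu0`, `psi0` (2x2 scale matrix).
#' @param group Optional group label carried into summaries.
#' @return Object of class `niche_posterior`: list with `mu` (ndraw x 2),
#'   `Sigma` (2 x 2 x ndraw), `n`, `group`.
#' @export
#' @examples
#' xy <- cbind(rnorm(50, -15), rnorm(50, 16))
#' np <- fit_niche(xy, ndraw = 500, seed = 1)
#' mean(sea_b(np)$draws)
fit_niche <- function(xy, ndraw = 4000L, seed = 1L,
                      prior = list(kappa0 = 1e-3, nu0 = 3, psi0 = diag(2) * 1e-3),
                      group = NULL) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("'xy' must have two columns", call. = FALSE)
  storage.mode(xy) <- "double"
  if (anyNA(xy)) stop("'xy' must not contain missing values", call. = FALSE)
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  ctr <- scale(xy, scale = FALSE)
  r <- qr(ctr)$rank
  if (r < 2L) {
    stop(sprintf("degenerate data: centered observations have rank %d < 2 (collinear or constant)", r),
         call. = FALSE)
  }
  xbar <- colMeans(xy)
  S <- crossprod(ctr)
  kappa0 <- prior$kappa0
  nu0 <- prior$nu0
  # prior mean at the sample mean: the mean-deviation term vanishes
  kappa_n <- kappa0 + n
  nu_n <- nu0 + n
  psi_n <- prior$psi0 + S
  .with_seed(seed, {
    W <- stats::rWishart(ndraw, df = nu_n, Sigma = solve(psi_n))
    Sigma <- array(apply(W, 3L, solve), dim = c(2L, 2L, ndraw))
    z <- matrix(stats::rnorm(2L * ndraw), ndraw, 2L)
    mu <- t(vapply(seq_len(ndraw), function(i) {
      xbar + drop(z[i, ] %*% chol(Sigma[, , i] / kappa_n))
    }, numeric(2L)))
    structure(list(mu = mu, Sigma = Sigma, n = n,
                   group = if (is.null(group)) NA_character_ else as.character(group)),
              class = "niche_posterior")
  })
}

#' Construct a niche posterior from explicit draws
#'
#' Wraps externally produced (or degenerate point-mass) draws of the mean
#' vector and covariance matrix as a `niche_posterior`, e.g. for analytical
#' checks or for propagating posteriors from another model.
#'
#' @param mu ndraw x 2 matrix of mean draws (a single vector is recycled).
#' @param Sigma 2 x 2 x ndraw array of covariance draws (a single matrix is
#'   recycled).
#' @param n Number of observations behind the posterior.
#' @param group Optional label.
#' @param ndraw Number of draws when recycling point masses.
#' @return Object of class `niche_posterior`.
#' @export
niche_posterior <- function(mu, Sigma, n = NA_integer_, group = NULL,
                            ndraw = NULL) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = ndraw %||% 1L, ncol = 2L,
                                     byrow = TRUE)
  if (length(dim(Sigma)) == 2L) {
    nd <- ndraw %||% nrow(mu)
    Sigma <- array(rep(Sigma, nd), dim = c(2L, 2L, nd))
  }
  if (!is.null(ndraw) && nrow(mu) == 1L && ndraw > 1L) {
    mu <- mu[rep(1L, ndraw), , drop = FALSE]
  }
  if (nrow(mu) != dim(Sigma)[3L]) {
    stop("'mu' and 'Sigma' must have the same number of draws", call. = FALSE)
  }
  for (i in seq_len(dim(Sigma)[3L])) {
    if (!.is_spd(Sigma[, , i])) {
      stop(sprintf("Sigma draw %d is not symmetric positive-definite", i),
           call. = FALSE)
    }
  }
  structure(list(mu = mu, Sigma = Sigma, n = n,
                 group = if (is.null(group)) NA_character_ else as.character(group)),
            class = "niche_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.niche_posterior <- function(x, ...) {
  cat(sprintf("Bivariate niche posterior%s: %d draws, n = %s\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$mu), x$n))
  cat(sprintf("  posterior mean mu = (%.2f, %.2f)\n",
              mean(x$mu[, 1L]), mean(x$mu[, 2L])))
  a <- sea_b(x)
  cat(sprintf("  SEA_B mean %.2f, HDI95 (%.2f, %.2f)\n",
              a$mean, a$hdi[1L], a$hdi[2L]))
  invisible(x)
}

#' Bayesian standard ellipse area (SEA_B)
#'
#' Applies [standard_ellipse_area()] to each posterior covariance draw of a
#' [fit_niche()] posterior, giving the posterior distribution of the
#' isotopic niche area.
#'
#' @param post A `niche_posterior`.
#' @param mass HDI mass for the summary.
#' @return Object of class `sea_b`: list with `draws` (numeric vector),
#'   `mean`, `hdi`, `group`.
#' @export
sea_b <- function(post, mass = 0.95) {
  stopifnot(inherits(post, "niche_posterior"))
  draws <- pi * sqrt(apply(post$Sigma, 3L, det))
  structure(list(draws = draws, mean = mean(draws),
                 hdi = if (length(draws) >= 50L) hdi(draws, mass) else
                   range(draws),
                 group = post$group),
            class = "sea_b")
}

#' @export
print.sea_b <- function(x, ...) {
  cat(sprintf("SEA_B%s: mean %.2f, interval (%.2f, %.2f) [%d draws]\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              x$mean, x$hdi[1L], x$hdi[2L], length(x$draws)))
  invisible(x)
}

#' Compare two posterior area distributions
#'
#' Posterior difference of two independently fitted niche areas: mean
#' difference, HDI of the difference, and the probability that the first
#' area exceeds the second (independent cross-draw comparison, since the
#' two posteriors come from distinct models).
#'
#' @param a,b `sea_b` objects or numeric vectors of area draws.
#' @param mass HDI mass.
#' @return List with `mean_diff`, `hdi`, `p_greater` (P(a > b)).
#' @export
compare_areas <- function(a, b, mass = 0.95) {
  da <- if (inherits(a, "sea_b")) a$draws else as.numeric(a)
  db <- if (inherits(b, "sea_b")) b$draws else as.numeric(b)
  if (!length(da) || !length(db)) stop("empty area draws", call. = FALSE)
  m <- min(length(da), length(db))
  diff_draws <- da[seq_len(m)] - db[seq_len(m)]
  list(
    mean_diff = mean(da) - mean(db),
    hdi = if (m >= 50L) hdi(diff_draws, mass) else range(diff_draws),
    p_greater = prob_greater(da, db, method = "independent")
  )
}

#' Fit niche posteriors for every group of an isotope table
#'
#' Convenience wrapper: splits a validated isotope table by one or more
#' grouping factors and fits [fit_niche()] to each cell's (d13C, d15N)
#' values on the raw data.
#'
#' @param data Validated isotope table.
#' @param group_by Character vector of grouping columns (default "species").
#' @param min_n Cells with fewer observations are skipped with a message.
#' @inheritParams fit_niche
#' @return Named list of `niche_posterior` objects.
#' @export
fit_niche_by_group <- function(data, group_by = "species", ndraw = 4000L,
                               seed = 1L, min_n = 3L,
                               prior = list(kappa0 = 1e-3, nu0 = 3,
                                            psi0 = diag(2) * 1e-3)) {
  stopifnot(all(group_by %in% names(data)))
  key <- interaction(data[group_by], drop = TRUE, sep = ":")
  out <- list()
  for (g in levels(key)) {
    rows <- key == g
    if (sum(rows) < min_n) {
      message(sprintf("skipping group %s: only %d observation(s)", g, sum(rows)))
      next
    }
    out[[g]] <- fit_niche(as.matrix(data[rows, c("d13C", "d15N")]),
                          ndraw = ndraw,
                          seed = .stage_seed(seed, match(g, levels(key))),
                          prior = prior, group = g)
  }
  out
}
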