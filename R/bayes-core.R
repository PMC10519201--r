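# Posterior-summary machinery shared by all Bayesian stages: highest density
# intervals, convergence diagnostics and directional probabilities.

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing a given probability mass of the
#' empirical distribution: with n sorted draws it is the narrowest window
#' spanning `ceiling(mass * n)` consecutive order statistics (ties broken by
#' the lowest starting index). Used to summarise every posterior in the
#' package as the 95% HDI.
#'
#' @param x Numeric vector of draws (a `DrawsMatrix` is flattened).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @param min_n Minimum number of draws required (default 50).
#' @return Named numeric vector `c(lower, upper)` with attribute `mass`.
#' @export
#' @examples
#' hdi(rnorm(1e4))
hdi <- function(x, mass = 0.95, min_n = 50L) {
  x <- as.vector(x)
  x <- x[!is.na(x)]
  if (length(x) < min_n) {
    stop(sprintf("hdi() needs at least %d samples, got %d", min_n, length(x)),
         call. = FALSE)
  }
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("'mass' must be a single number in (0, 1)", call. = FALSE)
  }
  s <- sort(x)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) {
    out <- c(lower = s[1L], upper = s[n])
  } else {
    widths <- s[k:n] - s[seq_len(n - k + 1L)]
    i <- which.min(widths) # which.min returns the first (lowest) index on ties
    out <- c(lower = s[i], upper = s[i + k - 1L])
  }
  attr(out, "mass") <- mass
  out
}

# Coerce chain input to an iterations x chains matrix.
.draws_matrix <- function(d) {
  if (inherits(d, "mcmc.list")) {
    d <- sapply(d, as.numeric)
  }
  if (is.list(d) && !is.data.frame(d)) {
    len <- unique(lengths(d))
    if (length(len) != 1L) {
      stop("all chains must have the same number of draws", call. = FALSE)
    }
    d <- do.call(cbind, lapply(d, as.numeric))
  }
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  d
}

# Split each chain in half (dropping one draw if odd length).
.split_chains <- function(m) {
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}

# Rank-normalize all draws jointly (average ranks for ties, Blom offsets).
.rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

# Classic split-Rhat on an already prepared matrix.
.rhat_basic <- function(m) {
  n <- nrow(m)
  ch_mean <- colMeans(m)
  ch_var <- apply(m, 2L, stats::var)
  w <- mean(ch_var)
  b <- n * stats::var(ch_mean)
  if (w < .Machine$double.eps) {
    return(1)
  }
  sqrt((n - 1) / n + b / (w * n))
}

#' Rank-normalized split R-hat convergence diagnostic
#'
#' Potential scale reduction factor comparing between- and within-chain
#' variance after splitting each chain in half and rank-normalizing the
#' draws. Values near 1 indicate mixing; the package's convergence policy
#' requires R-hat < 1.01 for every monitored parameter. Chains with zero
#' variance (all draws identical) return 1 by convention.
#'
#' @param d Chains as an iterations x chains matrix, list of equal-length
#'   numeric vectors, or `coda::mcmc.list` of a scalar parameter.
#' @return Scalar R-hat (>= 1 up to floating point).
#' @export
#' @examples
#' rhat(matrix(rnorm(3000), ncol = 3))
rhat <- function(d) {
  m <- .draws_matrix(d)
  if (ncol(m) < 2L) stop("rhat() needs at least 2 chains", call. = FALSE)
  if (nrow(m) < 4L) stop("rhat() needs at least 4 draws per chain", call. = FALSE)
  m <- .split_chains(m)
  if (stats::var(as.vector(m)) < .Machine$double.eps) return(1)
  # the (n-1)/n split-half term can push the estimate a hair under 1 for
  # perfectly mixed chains; clamp to the >= 1 convention
  max(.rhat_basic(.rank_normalize(m)), 1)
}

# Autocovariance function of one chain via FFT (biased, as used for ESS).
.autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, nfft - n)))
  # biased estimator (divide by n); the ESS formula corrects at lag 0
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (n * nfft)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws in a set of autocorrelated MCMC
#' chains, computed on rank-normalized split chains with cross-chain
#' autocorrelation combination and Geyer's initial-monotone-sequence
#' truncation. The package's sampling policy targets ESS > 2000 for every
#' parameter. Constant (zero-variance) chains return 0 and are considered
#' degenerate.
#'
#' @inheritParams rhat
#' @return Scalar effective sample size.
#' @export
#' @examples
#' ess(matrix(rnorm(3000), ncol = 3))
ess <- function(d) {
  m <- .draws_matrix(d)
  if (ncol(m) < 2L) stop("ess() needs at least 2 chains", call. = FALSE)
  if (nrow(m) < 4L) stop("ess() needs at least 4 draws per chain", call. = FALSE)
  m <- .split_chains(m)
  if (stats::var(as.vector(m)) < .Machine$double.eps) return(0)
  m <- .rank_normalize(m)
  nch <- ncol(m)
  n <- nrow(m)
  acov <- apply(m, 2L, .autocov)
  ch_var <- acov[1L, ]
  mean_var <- mean(ch_var) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + stats::var(colMeans(m))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer initial monotone sequence: accumulate consecutive lag pairs
  # (rho_2t + rho_2t+1) while positive, then enforce monotone decrease.
  pair_sums <- numeric(0)
  t <- 0L
  while (t + 2L <= n) {
    p <- rho[t + 1L] + rho[t + 2L]
    if (p <= 0) break
    pair_sums <- c(pair_sums, p)
    t <- t + 2L
  }
  if (length(pair_sums) > 1L) pair_sums <- cummin(pair_sums)
  tau <- -1 + 2 * sum(pair_sums)
  tau <- max(tau, 1 / log10(nch * n + 10)) # guard against antithetic chains
  nch * n / tau
}

#' Directional posterior probability P(a > b)
#'
#' Fraction of comparisons in which `a` exceeds `b`; exact ties count 1/2 so
#' that `prob_greater(a, b) + prob_greater(b, a) = 1` exactly. Used for the
#' "probability of the difference being greater/smaller than 0" summaries on
#' species contrasts, factor slopes and niche-area comparisons.
#'
#' @param a Numeric vector of draws.
#' @param b Numeric vector of draws or a scalar (default 0).
#' @param method `"paired"` compares draw-wise (same MCMC provenance; vectors
#'   must have equal length), `"independent"` compares all cross pairs
#'   (distinct models).
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' prob_greater(rnorm(1000, 1), 0)
prob_greater <- function(a, b = 0, method = c("paired", "independent")) {
  method <- match.arg(method)
  a <- as.vector(a)
  if (length(a) == 0L) stop("'a' must be nonempty", call. = FALSE)
  b <- as.vector(b)
  if (length(b) == 0L) stop("'b' must be nonempty", call. = FALSE)
  if (length(b) == 1L || length(a) == 1L) { # scalar broadcasts on either side
    return(mean((a > b) + 0.5 * (a == b)))
  }
  if (method == "paired") {
    if (length(a) != length(b)) {
      stop("paired comparison needs equal-length vectors", call. = FALSE)
    }
    return(mean((a > b) + 0.5 * (a == b)))
  }
  # Independent: P(A > B) + 0.5 P(A = B) over the full cross product,
  # computed in O(n log n) through the rank decomposition of the
  # Mann-Whitney U statistic.
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u / (na * nb)
}
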