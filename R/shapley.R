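# Shapley prey-importance attributions for the diet classifiers. Both the
# sampling estimator and the exact enumerator use the same interventional
# value function: v(S) is the mean model output when the features in S take
# the explained row's values and the remaining features take a background
# row's values. Attributions are on the positive-class probability scale.

# Resolve the model output function: diet_rf -> positive-class probability.
.shap_predict_fun <- function(model, predict_fun = NULL) {
  if (!is.null(predict_fun)) return(predict_fun)
  if (inherits(model, "diet_rf")) {
    return(function(X) {
      stats::predict(model$model, X)$predictions[, model$positive]
    })
  }
  stop("supply 'predict_fun' for models other than diet_rf", call. = FALSE)
}

#' Sampling-based Shapley feature attributions
#'
#' Estimates, for each explained row and each prey category, the Shapley
#' value of that feature for the model's positive-class probability, by the
#' permutation-sampling estimator: for each of `n_samples` random feature
#' orderings (each paired with one random background row), features are
#' switched one at a time from the background value to the explained row's
#' value and the successive output differences are accumulated. Summing a
#' row's attributions recovers exactly the difference between the model
#' output at that row and the mean output over that row's sampled
#' background rows (local accuracy).
#'
#' @param model A [rf_classify()] fit (or any model with `predict_fun`).
#' @param d Rows to explain (diet table with the ten prey columns).
#' @param background Background diet table supplying reference feature
#'   values; defaults to the model's training data.
#' @param n_samples Number of sampled permutations per explained row; must
#'   be at least twice the number of features.
#' @param seed Integer seed.
#' @param predict_fun Optional function(X matrix) -> numeric output.
#' @param features Optional character vector of feature columns (default:
#'   the prey categories present in `d`, else all columns of `d`).
#' @return Object of class `shap_table`: list with `values` (n x p matrix of
#'   signed attributions), `baseline` (per-row mean background output),
#'   `prediction` (per-row output), `ranking` (prey sorted by global mean
#'   absolute attribution), `importance` (the mean |value| per prey).
#' @export
shapley_importance <- function(model, d = NULL, background = NULL,
                               n_samples = 200L, seed = 1L,
                               predict_fun = NULL, features = NULL) {
  f <- .shap_predict_fun(model, predict_fun)
  if (is.null(d)) d <- model$train_data
  if (is.null(background)) {
    background <- if (inherits(model, "diet_rf")) model$train_data else d
  }
  d <- as.data.frame(d)
  if (is.null(features)) {
    features <- intersect(names(d), PREY_CATEGORIES)
    if (!length(features)) features <- names(d)
  }
  X <- as.matrix(d[, features, drop = FALSE])
  B <- as.matrix(as.data.frame(background)[, features, drop = FALSE])
  p <- ncol(X)
  if (n_samples < 2L * p) {
    stop(sprintf("'n_samples' must be at least 2 * %d features = %d", p, 2L * p),
         call. = FALSE)
  }
  n <- nrow(X)
  .with_seed(seed, {
    values <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
    baseline <- numeric(n)
    prediction <- f(X)
    for (i in seq_len(n)) {
      # build all intermediate coalition rows for all permutations, then
      # evaluate the model once on the whole block
      block <- matrix(0, n_samples * (p + 1L), p)
      perms <- replicate(n_samples, sample.int(p), simplify = FALSE)
      bg_rows <- sample.int(nrow(B), n_samples, replace = TRUE)
      r <- 0L
      for (s in seq_len(n_samples)) {
        cur <- B[bg_rows[s], ]
        block[r + 1L, ] <- cur
        for (step in seq_len(p)) {
          j <- perms[[s]][step]
          cur[j] <- X[i, j]
          block[r + 1L + step, ] <- cur
        }
        r <- r + p + 1L
      }
      colnames(block) <- colnames(X)
      out <- f(block)
      r <- 0L
      for (s in seq_len(n_samples)) {
        diffs <- out[r + 1L + seq_len(p)] - out[r + seq_len(p)]
        values[i, perms[[s]]] <- values[i, perms[[s]]] + diffs
        baseline[i] <- baseline[i] + out[r + 1L]
        r <- r + p + 1L
      }
      values[i, ] <- values[i, ] / n_samples
      baseline[i] <- baseline[i] / n_samples
    }
    imp <- colMeans(abs(values))
    structure(list(values = values, baseline = baseline,
                   prediction = prediction,
                   importance = imp, ranking = names(sort(imp, decreasing = TRUE)),
                   n_samples = n_samples, seed = seed),
              class = "shap_table")
  })
}

#' @export
print.shap_table <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d rows x %d features (%d permutations/row)\n",
              nrow(x$values), ncol(x$values), x$n_samples))
  cat("Global importance (mean |value|):\n")
  imp <- sort(x$importance, decreasing = TRUE)
  for (nm in names(imp)) cat(sprintf("  %-18s %.4f\n", nm, imp[nm]))
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' Brute-force oracle: enumerates all 2^p feature coalitions and applies
#' the Shapley weighting, with the same background-conditional
#' (interventional) value function as [shapley_importance()]. Intended for
#' testing the sampling estimator on small feature sets; refuses p > 12.
#'
#' @param model A [rf_classify()] fit or any model with `predict_fun`.
#' @param x A single row to explain (named numeric vector or 1-row data
#'   frame of feature values).
#' @param background Background rows (matrix or data frame of the same
#'   features).
#' @param features Optional character vector naming the feature columns
#'   (default: the prey categories present in `x`).
#' @param predict_fun Optional function(X matrix) -> numeric output.
#' @return Named numeric vector of exact Shapley values; attribute
#'   `baseline` is the mean background output, and
#'   `sum(values) + baseline == f(x)` exactly.
#' @export
exact_shapley <- function(model, x, background, features = NULL,
                          predict_fun = NULL) {
  f <- .shap_predict_fun(model, predict_fun)
  if (is.null(features)) {
    features <- intersect(names(x), PREY_CATEGORIES)
    if (!length(features)) features <- names(x)
  }
  if (is.data.frame(x)) {
    x <- vapply(x[1L, features, drop = FALSE], as.numeric, numeric(1L))
  } else {
    x <- x[features]
  }
  p <- length(features)
  if (p > 12L) {
    stop(sprintf("exact enumeration refused for p = %d > 12 features", p),
         call. = FALSE)
  }
  B <- as.matrix(as.data.frame(background)[, features, drop = FALSE])
  nb <- nrow(B)
  # v(S) for every subset S, coded as bitmask 0 .. 2^p - 1
  nsub <- 2L^p
  v <- numeric(nsub)
  for (s in seq_len(nsub) - 1L) {
    in_s <- as.logical(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)))
    Xs <- B
    if (any(in_s)) Xs[, in_s] <- matrix(x[in_s], nb, sum(in_s), byrow = TRUE)
    colnames(Xs) <- features
    v[s + 1L] <- mean(f(Xs))
  }
  sizes <- vapply(seq_len(nsub) - 1L, function(s) sum(
    as.logical(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)))), integer(1L))
  w <- ifelse(sizes < p,
              factorial(sizes) * factorial(pmax(p - sizes - 1L, 0L)) / factorial(p),
              0) # the full set never appears as S in the marginal sum
  phi <- stats::setNames(numeric(p), features)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    no_j <- which(bitwAnd(seq_len(nsub) - 1L, bit) == 0L)
    phi[j] <- sum(w[no_j] * (v[no_j + bit] - v[no_j]))
  }
  attr(phi, "baseline") <- v[1L]
  phi
}
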