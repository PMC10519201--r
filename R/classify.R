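# Stomach-content stage: balanced random-forest classification of
# individuals from their prey-weight profiles, evaluated by ROC AUC.

#' Balance a two-class diet dataset (undersampling + SMOTE)
#'
#' Randomly undersamples the majority class down to `n_target` rows and
#' upsamples the minority class to `n_target` with SMOTE: each synthetic
#' minority row is a convex combination `x + u * (neighbour - x)`,
#' `u ~ U(0, 1)`, of a real minority row and one of its `k_neighbors`
#' nearest minority neighbours in prey-weight space (Euclidean distance on
#' the raw gram weights). Non-feature columns of synthetic rows are copied
#' from the seed row; synthetic ids are suffixed `_syn`.
#'
#' @param d Validated diet table.
#' @param target Name of the binary grouping column.
#' @param n_target Rows per class after balancing (default 100).
#' @param k_neighbors Neighbourhood size for SMOTE (minority class must
#'   have at least `k_neighbors + 1` rows).
#' @param seed Integer seed.
#' @return A balanced diet table with `n_target` rows per class.
#' @export
#' @examples
#' d <- simulate_diet(default_diet_spec(), seed = 1)
#' hd <- d[d$species == "H_dipterurus", ]
#' table(balance_classes(hd, "stage", seed = 1)$stage)
balance_classes <- function(d, target, n_target = 100L, k_neighbors = 5L,
                            seed = 1L) {
  d <- as.data.frame(d)
  if (!target %in% names(d)) stop(sprintf("no column '%s'", target), call. = FALSE)
  y <- as.character(d[[target]])
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop(sprintf("'%s' must have exactly 2 classes, found %d", target, length(lev)),
         call. = FALSE)
  }
  counts <- table(factor(y, lev))
  minority <- names(which.min(counts))
  .with_seed(seed, {
    pieces <- lapply(lev, function(cl) {
      rows <- d[y == cl, , drop = FALSE]
      n <- nrow(rows)
      if (n >= n_target) {
        return(rows[sample.int(n, n_target), , drop = FALSE])
      }
      if (n < k_neighbors + 1L) {
        stop(sprintf(
          "minority class '%s' has %d rows; SMOTE needs at least k_neighbors + 1 = %d (use a smaller k_neighbors)",
          cl, n, k_neighbors + 1L), call. = FALSE)
      }
      X <- as.matrix(rows[, PREY_CATEGORIES])
      dist2 <- as.matrix(stats::dist(X))^2
      diag(dist2) <- Inf
      nn <- apply(dist2, 1L, function(r) order(r)[seq_len(k_neighbors)])
      n_syn <- n_target - n
      base_idx <- sample.int(n, n_syn, replace = TRUE)
      syn <- rows[base_idx, , drop = FALSE]
      for (s in seq_len(n_syn)) {
        i <- base_idx[s]
        j <- nn[sample.int(k_neighbors, 1L), i]
        u <- stats::runif(1L)
        syn[s, PREY_CATEGORIES] <- X[i, ] + u * (X[j, ] - X[i, ])
      }
      if ("id" %in% names(syn)) {
        syn$id <- sprintf("%s_syn%03d", syn$id, seq_len(n_syn))
      }
      rbind(rows, syn)
    })
    out <- do.call(rbind, pieces)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Default random-forest tuning grid
#'
#' Grid spanning the ensemble sizes, depths and feature subsets used by the
#' tuned classifiers in this problem: trees in \{50, 100, 200\}, maximum
#' depth in \{1, 2, 4, 5, 7, 28, unlimited\} (0 = unlimited), and maximum
#' features per split 1..p.
#'
#' @param p Number of features (default 10 prey categories).
#' @return Data frame with columns `num_trees`, `max_depth`, `mtry`.
#' @export
default_rf_grid <- function(p = length(PREY_CATEGORIES)) {
  expand.grid(num_trees = c(50L, 100L, 200L),
              max_depth = c(1L, 2L, 4L, 5L, 7L, 28L, 0L),
              mtry = seq_len(p))
}

# Stratified index split: returns logical vector, TRUE = train.
.stratified_split <- function(y, frac) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- round(frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

# Stratified fold assignment 1..k.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.auc <- function(y_true, score, positive) {
  suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = factor(y_true == positive, c(FALSE, TRUE)),
              predictor = score, quiet = TRUE, direction = "<")
  )))
}

#' Tune and evaluate a random-forest diet classifier
#'
#' Classifies individuals into the two levels of `target` from the raw gram
#' weights of the ten prey categories (no transformation). The training
#' portion of a stratified 75-25 split is optionally balanced
#' (undersampling + SMOTE, applied before model selection so the held-out
#' test rows are never touched); hyperparameters are selected by stratified
#' 5-fold cross-validated ROC AUC over `grid`; the selected model is refit
#' on the full training portion and its held-out test AUC reported.
#'
#' @param d Validated diet table (>= 20 rows; subset it first for
#'   within-species tasks).
#' @param target Binary grouping column: `"species"`, `"sex"`, `"stage"` or
#'   `"season"`.
#' @param grid Hyperparameter grid as from [default_rf_grid()].
#' @param seed Integer seed controlling the split, folds, balancing and
#'   forests.
#' @param balance `"auto"` balances when the class ratio exceeds
#'   `balance_ratio`, `"off"` never, `"force"` always.
#' @param n_target Per-class size after balancing.
#' @param balance_ratio Majority/minority ratio above which `"auto"`
#'   balances (default 2).
#' @param split Training fraction (default 0.75).
#' @param folds Cross-validation folds (default 5).
#' @param label Task label carried into the report.
#' @return Object of class `diet_rf`: the fitted ranger model plus the
#'   chosen hyperparameters, cross-validation AUC, held-out test AUC, class
#'   counts before/after balancing, positive class and seed.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_diet(default_diet_spec(), seed = 1)
#' fit <- rf_classify(d, "species", grid = default_rf_grid()[c(10, 40), ],
#'                    seed = 1)
#' fit$test_auc
#' }
rf_classify <- function(d, target, grid = default_rf_grid(), seed = 1L,
                        balance = c("auto", "off", "force"), n_target = 100L,
                        balance_ratio = 2, split = 0.75, folds = 5L,
                        label = NULL) {
  balance <- match.arg(balance)
  d <- as.data.frame(d)
  if (nrow(d) < 20L) stop("need at least 20 rows", call. = FALSE)
  if (!target %in% names(d)) stop(sprintf("no column '%s'", target), call. = FALSE)
  y <- as.character(d[[target]])
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop(sprintf("'%s' must have exactly 2 classes in the supplied rows", target),
         call. = FALSE)
  }
  positive <- lev[2L]
  counts_before <- table(factor(y, lev))
  .with_seed(seed, {
    train <- .stratified_split(y, split)
    if (length(unique(y[train])) < 2L || length(unique(y[!train])) < 2L) {
      stop("degenerate split: a class is absent from train or test", call. = FALSE)
    }
    d_train <- d[train, , drop = FALSE]
    d_test <- d[!train, , drop = FALSE]
    ratio <- max(counts_before) / min(counts_before)
    do_balance <- balance == "force" || (balance == "auto" && ratio > balance_ratio)
    if (do_balance) {
      d_train <- balance_classes(d_train, target, n_target = n_target,
                                 seed = sample.int(.Machine$integer.max, 1L))
    }
    counts_after <- table(factor(as.character(d_train[[target]]), lev))
    X_train <- d_train[, PREY_CATEGORIES, drop = FALSE]
    y_train <- factor(as.character(d_train[[target]]), lev)
    fold <- .stratified_folds(as.character(y_train), folds)
    fit_one <- function(Xtr, ytr, par, fit_seed) {
      ranger::ranger(
        x = Xtr, y = ytr, probability = TRUE,
        num.trees = par$num_trees, max.depth = par$max_depth,
        mtry = par$mtry, seed = fit_seed, num.threads = 1L
      )
    }
    cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
      par <- grid[g, ]
      fold_auc <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        if (length(unique(y_train[!tr])) < 2L) return(NA_real_)
        m <- fit_one(X_train[tr, , drop = FALSE], y_train[tr], par,
                     fit_seed = 1000L * g + f)
        p <- stats::predict(m, X_train[!tr, , drop = FALSE])$predictions[, positive]
        .auc(as.character(y_train[!tr]), p, positive)
      }, numeric(1L))
      mean(fold_auc, na.rm = TRUE)
    }, numeric(1L))
    best <- order(-cv_auc, grid$num_trees, grid$max_depth, grid$mtry)[1L]
    model <- fit_one(X_train, y_train, grid[best, ], fit_seed = 99L)
    p_test <- stats::predict(model, d_test[, PREY_CATEGORIES, drop = FALSE]
                             )$predictions[, positive]
    structure(list(
      label = label %||% target,
      target = target, levels = lev, positive = positive,
      model = model,
      best = as.list(grid[best, ]),
      cv_auc = cv_auc[best],
      test_auc = .auc(as.character(d_test[[target]]), p_test, positive),
      counts_before = counts_before, counts_after = counts_after,
      balanced = do_balance,
      n_train = nrow(d_train), n_test = nrow(d_test),
      train_data = d_train, test_data = d_test,
      seed = seed
    ), class = "diet_rf")
  })
}

#' @export
print.diet_rf <- function(x, ...) {
  cat(sprintf("Random-forest diet classifier [%s]: %s vs %s\n",
              x$label, x$levels[1L], x$levels[2L]))
  cat(sprintf("  tuned: %d trees, max depth %s, max features %d\n",
              x$best$num_trees,
              if (x$best$max_depth == 0L) "unlimited" else x$best$max_depth,
              x$best$mtry))
  cat(sprintf("  CV AUC %.3f | held-out test AUC %.3f\n", x$cv_auc, x$test_auc))
  cat(sprintf("  classes %s%s\n",
              paste(sprintf("%s=%d", names(x$counts_before), x$counts_before),
                    collapse = ", "),
              if (x$balanced) sprintf(" (balanced to %s in training)",
                                      paste(x$counts_after, collapse = "/")) else ""))
  invisible(x)
}

#' @export
predict.diet_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- stats::predict(object$model,
                      newdata[, PREY_CATEGORIES, drop = FALSE]
                      )$predictions[, object$positive]
  if (type == "prob") p else object$levels[(p >= 0.5) + 1L]
}
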