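# Shapley attributions: exact enumeration oracle and sampling estimator.

# simple deterministic models exercised through predict_fun
step_model <- function(X) as.numeric(X[, 1] > 0)
sum_model <- function(X) X[, 1] + X[, 2] + 0 * X[, ncol(X)]

test_that("exact values match hand calculations on toy models", {
  # p = 1: value is f(x) minus the mean background prediction
  bg1 <- data.frame(a = c(-1, -1, 1, 1))
  phi <- exact_shapley(NULL, c(a = 2), bg1, features = "a",
                       predict_fun = function(X) as.numeric(X[, 1] > 0))
  expect_equal(unname(phi["a"]), 1 - 0.5)
  expect_equal(attr(phi, "baseline"), 0.5)

  # two features, single split on the first: all credit goes to it
  bg2 <- data.frame(a = c(-1, -1, -1, 1), b = c(0, 1, 2, 3))
  phi2 <- exact_shapley(NULL, c(a = 1, b = 5), bg2, features = c("a", "b"),
                        predict_fun = step_model)
  expect_equal(unname(phi2["a"]), 1 - 0.25)
  expect_equal(unname(phi2["b"]), 0)

  # duplicated identical features share credit equally (symmetry axiom)
  bg3 <- data.frame(a = c(0, 0, 2, 2), b = c(0, 0, 2, 2))
  phi3 <- exact_shapley(NULL, c(a = 2, b = 2), bg3, features = c("a", "b"),
                        predict_fun = function(X) X[, 1] + X[, 2])
  expect_equal(unname(phi3["a"]), unname(phi3["b"]))
})

test_that("exact mode satisfies local accuracy on a real forest", {
  d <- simulate_diet(sipunculid_split_spec(n = 40L), seed = 1)
  fit <- rf_classify(d, "species", grid = small_rf_grid()[c(1, 2), ], seed = 1)
  x <- fit$test_data[1, ]
  bg <- fit$train_data[1:25, ]
  phi <- exact_shapley(fit, x, bg)
  f <- isopart:::.shap_predict_fun(fit)
  fx <- f(as.matrix(x[, prey_categories()]))
  expect_lt(abs(sum(phi) + attr(phi, "baseline") - fx), 1e-6)
  expect_error(exact_shapley(NULL, setNames(rnorm(13), letters[1:13]),
                             matrix(0, 2, 13, dimnames = list(NULL, letters[1:13])),
                             features = letters[1:13],
                             predict_fun = function(X) rowSums(X)),
               "p = 13 > 12")
})

test_that("a feature the model ignores gets zero attribution", {
  bg <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  x <- c(a = 1, b = 2, c = 3)
  ignore_c <- function(X) X[, "a"] * 2 + X[, "b"]
  phi <- exact_shapley(NULL, x, bg, features = c("a", "b", "c"),
                       predict_fun = ignore_c)
  expect_equal(unname(phi["c"]), 0)
  sh <- shapley_importance(NULL, d = data.frame(t(x)),
                           background = bg, n_samples = 50L, seed = 2,
                           predict_fun = ignore_c)
  expect_equal(unname(sh$values[1, "c"]), 0)
})

test_that("sampling estimator agrees with enumeration within MC error", {
  d <- simulate_diet(sipunculid_split_spec(n = 40L), seed = 3)
  # 3-feature toy forest
  feats <- c("sipunculids", "bivalves", "crabs")
  y <- factor(d$species)
  m <- ranger::ranger(x = d[, feats], y = y, probability = TRUE,
                      num.trees = 30, max.depth = 3, seed = 1,
                      num.threads = 1)
  pf <- function(X) predict(m, as.data.frame(X))$predictions[, 2]
  x <- d[1, feats]
  bg <- d[2:21, feats]
  exact <- exact_shapley(NULL, x, bg, features = feats, predict_fun = pf)
  runs <- t(vapply(1:8, function(s) {
    sh <- shapley_importance(NULL, d = x, background = bg,
                             n_samples = 120L, seed = s, predict_fun = pf)
    sh$values[1, feats]
  }, numeric(3L)))
  mc_mean <- colMeans(runs)
  mc_se <- apply(runs, 2, sd) / sqrt(nrow(runs))
  for (j in seq_along(feats)) {
    expect_lt(abs(mc_mean[j] - exact[feats[j]]),
              3 * max(mc_se[j], 1e-3))
  }
})

test_that("sampling estimator enforces local accuracy and guards", {
  d <- simulate_diet(sipunculid_split_spec(n = 30L), seed = 4)
  fit <- rf_classify(d, "species", grid = small_rf_grid()[c(1, 2), ], seed = 4)
  sh <- shapley_importance(fit, d = fit$test_data[1:4, ], n_samples = 30L,
                           seed = 5)
  gap <- rowSums(sh$values) + sh$baseline - sh$prediction
  expect_lt(max(abs(gap)), 1e-10)
  expect_error(shapley_importance(fit, d = fit$test_data[1:2, ],
                                  n_samples = 5L),
               "at least 2")
})

test_that("shapley_importance uses a feature's values, not its name order", {
  # swapping two identically distributed features swaps their attributions
  bg <- data.frame(a = c(0, 1), b = c(0, 1))
  f_ab <- function(X) 3 * X[, "a"] + 1 * X[, "b"]
  sh <- shapley_importance(NULL, d = data.frame(a = 1, b = 1),
                           background = bg, n_samples = 400L, seed = 6,
                           predict_fun = f_ab)
  expect_gt(sh$values[1, "a"], sh$values[1, "b"])
  expect_equal(unname(sh$values[1, "a"] / sh$values[1, "b"]), 3,
               tolerance = 0.4)
})
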