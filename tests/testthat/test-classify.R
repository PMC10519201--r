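# Balancing (undersampling + SMOTE) and the tuned random-forest stage.

test_that("balancing reaches the target sizes", {
  d <- simulate_diet(default_diet_spec(), seed = 1)
  hd <- d[d$species == "H_dipterurus", ] # stages 44 adults vs 161 juveniles
  expect_equal(unname(table(hd$stage)), c(44L, 161L), ignore_attr = TRUE)
  bal <- balance_classes(hd, "stage", n_target = 100L, seed = 2)
  expect_equal(unname(table(bal$stage)), c(100L, 100L), ignore_attr = TRUE)
  expect_identical(names(bal), names(hd)) # schema untouched

  # already balanced at target: the same rows come back
  even <- hd[c(which(hd$stage == "adult")[1:20],
               which(hd$stage == "juvenile")[1:20]), ]
  bal2 <- balance_classes(even, "stage", n_target = 20L, seed = 3)
  expect_setequal(bal2$id, even$id)

  tiny <- hd[c(which(hd$stage == "adult")[1:3],
               which(hd$stage == "juvenile")[1:30]), ]
  expect_error(balance_classes(tiny, "stage", n_target = 20L, k_neighbors = 5),
               "smaller k_neighbors")
})

test_that("SMOTE rows are convex combinations of minority rows", {
  d <- simulate_diet(default_diet_spec(), seed = 4)
  ne <- d[d$species == "N_entemedor", ] # stages 173 vs 14
  bal <- balance_classes(ne, "stage", n_target = 100L, seed = 5)
  syn <- bal[grepl("_syn", bal$id), ]
  expect_gt(nrow(syn), 0)
  expect_true(all(syn$stage == "juvenile"))
  minority <- ne[ne$stage == "juvenile", prey_categories()]
  for (pc in prey_categories()) {
    expect_true(all(syn[[pc]] >= min(minority[[pc]]) - 1e-9))
    expect_true(all(syn[[pc]] <= max(minority[[pc]]) + 1e-9))
  }
})

test_that("a single-prey occurrence split is learned almost perfectly", {
  d <- simulate_diet(sipunculid_split_spec(n = 100L), seed = 6)
  fit <- rf_classify(d, "species", grid = small_rf_grid(), seed = 6)
  expect_gt(fit$test_auc, 0.9)
  expect_gt(fit$cv_auc, 0.9)
  # sipunculids should dominate the Shapley ranking
  sh <- shapley_importance(fit, d = fit$test_data, n_samples = 40L, seed = 1)
  expect_equal(sh$ranking[1], "sipunculids")
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(7)
  d <- simulate_diet(sipunculid_split_spec(n = 60L), seed = 7)
  aucs <- vapply(1:10, function(s) {
    d$species <- sample(d$species)
    rf_classify(d, "species", grid = small_rf_grid()[c(1, 4), ],
                seed = s)$test_auc
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("classifier reports are reproducible and well-formed", {
  d <- simulate_diet(default_diet_spec(), seed = 8)
  ne <- d[d$species == "N_entemedor", ]
  f1 <- rf_classify(ne, "sex", grid = small_rf_grid(), seed = 11)
  f2 <- rf_classify(ne, "sex", grid = small_rf_grid(), seed = 11)
  expect_identical(f1$test_auc, f2$test_auc)
  expect_identical(f1$best, f2$best)
  expect_true(f1$balanced) # 154 females vs 33 males exceeds the 2:1 ratio
  expect_equal(unname(f1$counts_after), c(100L, 100L), ignore_attr = TRUE)
  expect_true(f1$test_auc >= 0 && f1$test_auc <= 1)

  expect_error(rf_classify(d[1:10, ], "species"), "at least 20 rows")
  one_class <- ne[ne$sex == "female", ]
  expect_error(rf_classify(one_class, "sex", grid = small_rf_grid()),
               "2 classes")
})
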