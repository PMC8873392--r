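fast_params <- function(mtry = 2, sf = 0.7, trees = 50)
  list(mtry = mtry, sample_fraction = sf, num_trees = trees)

make_signal_data <- function(n = 200, p = 6, seed = 1, strength = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- strength * X[, 1] + rnorm(n, 0, sqrt(max(0, 1 - strength^2))
                                 + (strength > 1) * 0)
  list(X = X, y = y)
}

test_that("tuning returns the OOB-MSE arg-min and is deterministic", {
  d <- make_signal_data(120, seed = 2)
  t1 <- tune_rf(d$X, d$y, budget = 8, num_trees = 100, seed = 3)
  t2 <- tune_rf(d$X, d$y, budget = 8, num_trees = 100, seed = 3)
  expect_identical(t1, t2)
  expect_true(t1$mtry >= 1 && t1$mtry <= ncol(d$X))
  expect_true(t1$sample_fraction > 0 && t1$sample_fraction <= 1)
  # single-point budget returns that point
  t3 <- tune_rf(d$X, d$y, budget = 1, num_trees = 50, seed = 4)
  expect_equal(nrow(data.frame(t3$mtry)), 1)
  # a strong single-feature signal is learnable: OOB-MSE < var(y)
  expect_lt(t1$oob_mse, var(d$y))
  expect_error(tune_rf(d$X, rep(1, 120), seed = 1), "zero variance")
  expect_error(tune_rf(d$X[1:10, ], d$y[1:10], seed = 1), "20 samples")
})

test_that("repeated CV detects strong signal and reports null accuracy near zero", {
  strong <- make_signal_data(200, seed = 5, strength = 0.98)
  acc <- repeated_cv(strong$X, strong$y, fast_params(mtry = 3, trees = 200),
                     folds = 4, repeats = 3, seed = 6)
  expect_gt(acc$cv_pearson_median, 0.9)
  expect_lt(acc$oob_mse, var(strong$y) / 2)
  null <- make_signal_data(150, seed = 7, strength = 0)
  acc0 <- repeated_cv(null$X, null$y, fast_params(), folds = 4, repeats = 3,
                      seed = 8)
  expect_lt(abs(acc0$cv_pearson_median), 0.3)
  # leave-one-out boundary runs
  tiny <- make_signal_data(24, seed = 9, strength = 0.9)
  loo <- repeated_cv(tiny$X, tiny$y, fast_params(trees = 25), folds = 24,
                     repeats = 1, seed = 10)
  expect_true(is.finite(loo$cv_pearson_median))
  expect_error(repeated_cv(tiny$X[1:3, ], tiny$y[1:3], fast_params(),
                           folds = 4), "as many samples as folds")
})

test_that("permutation p hits the add-one floor for an unbeatable signal", {
  strong <- make_signal_data(150, seed = 11, strength = 0.98)
  pt <- permutation_null_test(strong$X, strong$y, B = 19, folds = 2,
                              repeats = 1, seed = 12, retune = FALSE,
                              params = fast_params(mtry = 3, trees = 100))
  expect_equal(pt$p_pearson, 1 / 20)
  expect_equal(pt$p_oob, 1 / 20)
  expect_length(pt$null_pearson, 19)
  expect_error(permutation_null_test(strong$X, strong$y, B = 10), "B must")
})

test_that("Altmann importance isolates a planted feature and handles constants", {
  d <- make_signal_data(200, seed = 13, strength = 0.7)  # f1 ~ 50% of var(y)
  X <- cbind(d$X, const = 1)
  imp <- altmann_importance(X, d$y, fast_params(mtry = 3, trees = 150),
                            B = 99, seed = 14)
  f1 <- imp[imp$feature == "f1", ]
  expect_equal(f1$p, 1 / 100)
  expect_equal(imp$feature[1], "f1")   # sorted: strongest first
  cst <- imp[imp$feature == "const", ]
  expect_equal(cst$importance, 0)
  expect_equal(cst$p, 1)
  # pure-noise features should not be systematically significant
  noise_p <- imp$p[!imp$feature %in% c("f1", "const")]
  expect_gt(mean(noise_p), 0.2)
})

test_that("family BH correction delegates to the step-up procedure", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_identical(bh_over_models(p), bh_adjust(p))
})

test_that("the model family pairs each stool time point with itself and its successor", {
  sc <- small_cohort(n = 40, seed = 28, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  # restrict to one stool time point: a single cross-sectional + one future model
  sub <- list(cohort = sc$cohort, taxon_tables = sc$taxon_tables["10y"])
  fam <- run_model_family(sub, B = 19, folds = 2, repeats = 1,
                          tune_budget = 2, num_trees = 25, retune = FALSE,
                          importance_p = 0, seed = 29)
  expect_equal(unique(paste(fam$report$time_microbiota, fam$report$time_zbmi)),
               c("10y 10y", "10y 12y"))
  expect_equal(nrow(fam$report), 4)      # two models x two metrics
  expect_setequal(fam$report$metric, c("OOB", "Pearson"))
  expect_true(all(fam$report$p > 0 & fam$report$p <= 1))
  expect_true(all(fam$report$q > 0 & fam$report$q <= 1))
  # terminal stool time point only gets a cross-sectional model
  sub12 <- list(cohort = sc$cohort,
                taxon_tables = setNames(sc$taxon_tables["10y"], "12y"))
  sub12$taxon_tables[["12y"]]$counts <- local({
    m <- sub12$taxon_tables[["12y"]]$counts
    rownames(m) <- sub("_10y$", "_12y", rownames(m)); m
  })
  fam12 <- run_model_family(sub12, B = 19, folds = 2, repeats = 1,
                            tune_budget = 2, num_trees = 25, retune = FALSE,
                            importance_p = 0, seed = 30)
  expect_equal(unique(fam12$report$time_zbmi), "12y")
  expect_equal(nrow(fam12$report), 2)
})

test_that("family runs are deterministic under the master seed", {
  sc <- small_cohort(n = 40, seed = 31, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  sub <- list(cohort = sc$cohort, taxon_tables = sc$taxon_tables["6y"])
  f1 <- run_model_family(sub, B = 19, folds = 2, repeats = 1, tune_budget = 3,
                         num_trees = 25, importance_p = 0, seed = 32)
  f2 <- run_model_family(sub, B = 19, folds = 2, repeats = 1, tune_budget = 3,
                         num_trees = 25, importance_p = 0, seed = 32)
  expect_identical(f1$report, f2$report)
})
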