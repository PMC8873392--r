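test_that("standardization is exact, reversible, and rejects constants", {
  d <- data.frame(a = rnorm(30, 5, 2), b = runif(30), zbmi = rnorm(30))
  s <- standardize(d, c("a", "b"))
  expect_lt(abs(mean(s$data$a)), 1e-12)
  expect_equal(sd(s$data$a), 1, tolerance = 1e-12)
  expect_identical(s$data$zbmi, d$zbmi)   # untouched
  # recorded scaling reproduces training-scale values on new data
  new <- data.frame(a = c(5, 7), b = c(0.5, 0.2))
  scaled <- apply_scaling(new, s$scaling)
  expect_equal(scaled$a, (c(5, 7) - s$scaling$mean[1]) / s$scaling$sd[1])
  expect_error(standardize(data.frame(a = rep(1, 10)), "a"), "zero SD")
})

test_that("with known variance and no random effects the sampler matches the conjugate closed form", {
  set.seed(4)
  n <- 2000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 0.5 + 0.8 * X[, 1] - 0.4 * X[, 2] + rnorm(n)
  d <- data.frame(zbmi = y, x1 = X[, 1], x2 = X[, 2], subject_id = seq_len(n))
  spec <- model_spec(exposure = "x1", covariates = "x2", varying_slope = FALSE)
  fit <- fit_multilevel(d, spec, n_iter = 40000, n_chains = 1, seed = 9,
                        include_ranef = FALSE, fixed_sigma = 1)
  dm <- cbind(1, X)
  A <- crossprod(dm) + diag(1 / c(1, 0.5, 0.5)^2)   # prior precisions
  mu <- drop(solve(A, crossprod(dm, y)))
  sd_exact <- sqrt(diag(solve(A)))
  dr <- fit$draws[[1]]
  expect_lt(max(abs(colMeans(dr[, 1:3]) - mu)), 1e-3)
  expect_lt(max(abs(apply(dr[, 1:3], 2, sd) - sd_exact)), 1e-3)
})

test_that("with a flat likelihood the exposure slope posterior is its prior", {
  set.seed(5)
  d <- data.frame(zbmi = rnorm(40), x = rnorm(40), subject_id = 1:40)
  spec <- model_spec(exposure = "x", covariates = character(0),
                     varying_slope = FALSE)
  # residual SD huge: the data carry essentially no information
  fit <- fit_multilevel(d, spec, n_iter = 30000, n_chains = 1, seed = 2,
                        include_ranef = FALSE, fixed_sigma = 1e6)
  xdr <- fit$draws[[1]][, "x"]
  expect_lt(abs(mean(xdr)), 3 * 0.5 / sqrt(length(xdr)))
  expect_equal(sd(xdr), 0.5, tolerance = 0.02)
})

test_that("a planted negative genus effect is recovered with the right sign", {
  cfg <- simulation_config(n_subjects = 250,
                           effect_vector = c(Subdoligranulum = -0.3),
                           missing_rate_stool = 0, missing_rate_anthro = 0,
                           seed = 14)
  sc <- simulate_cohort(cfg)
  feats <- genus_clr_feature(sc, "Subdoligranulum")
  long <- lagged_dataset(sc$cohort, feats, "Subdoligranulum")
  long <- standardize(long, "birthweight")$data
  fit <- fit_multilevel(long, model_spec(exposure = "Subdoligranulum"),
                        n_iter = 1500, n_chains = 2, seed = 15)
  s <- posterior_summary(fit)
  slope <- s[s$param == "Subdoligranulum", ]
  expect_lt(slope$median, 0)
  expect_lt(slope$u95, 0)    # CI excludes zero for a strong planted effect
  expect_lt(slope$p_positive, 0.01)
  # residual SD recovered near its generative value
  expect_equal(s$median[s$param == "sigma"], 0.8, tolerance = 0.1)
})

test_that("chains converge on the shipped example configuration", {
  cfg <- simulation_config(n_subjects = 150, seed = 16,
                           missing_rate_stool = 0, missing_rate_anthro = 0)
  sc <- simulate_cohort(cfg)
  feats <- feature_table(sc$taxon_tables)
  long <- lagged_dataset(sc$cohort, feats, "scfa_sum_clr")
  long <- standardize(long, c("scfa_sum_clr", "birthweight"))$data
  fit <- fit_multilevel(long, model_spec(exposure = "scfa_sum_clr"),
                        n_iter = 2500, n_chains = 4, seed = 17)
  s <- posterior_summary(fit)
  expect_true(all(s$rhat < 1.01))
  expect_true(all(s$ess > 100))
  expect_true(all(s$l95 <= s$median & s$median <= s$u95))
  # chain-order invariance of the summary
  fit2 <- fit
  fit2$draws <- rev(fit2$draws)
  s2 <- posterior_summary(fit2)
  expect_equal(s$median, s2$median)
  expect_equal(s$l95, s2$l95)
})

test_that("pooling across imputations mixes draws with equal weight", {
  set.seed(18)
  n <- 120
  base <- data.frame(x = rnorm(n), subject_id = rep(1:40, 3))
  base$zbmi <- 0.4 * base$x + rnorm(n, 0, 0.7)
  spec <- model_spec(exposure = "x", covariates = character(0))
  # m identical datasets: pooled summary == single-dataset summary within MC error
  pooled <- fit_across_imputations(list(base, base, base), spec,
                                   n_iter = 1200, n_chains = 2, seed = 19)
  single <- fit_multilevel(base, spec, n_iter = 1200, n_chains = 2, seed = 20)
  sp <- posterior_summary(pooled); ss <- posterior_summary(single)
  expect_equal(sp$median[sp$param == "x"], ss$median[ss$param == "x"],
               tolerance = 0.05)
  expect_true(is.na(sp$rhat[1]))   # mixture: per-chain diagnostics withheld
  expect_true(all(pooled$per_dataset_rhat < 1.1))
  # shifted outcomes: pooled interval wider than either single interval
  shifted1 <- base; shifted1$zbmi <- base$zbmi + 0.4
  shifted2 <- base; shifted2$zbmi <- base$zbmi - 0.4
  pooled2 <- fit_across_imputations(list(shifted1, shifted2), spec,
                                    n_iter = 1200, n_chains = 2, seed = 21)
  w <- function(s) {
    r <- s[s$param == "Intercept", ]; r$u95 - r$l95
  }
  f1 <- fit_multilevel(shifted1, spec, n_iter = 1200, n_chains = 2, seed = 22)
  expect_gt(w(posterior_summary(pooled2)), w(posterior_summary(f1)))
  expect_error(fit_across_imputations(list(base), spec), "two completed")
})

test_that("posterior predictive checks pass on self-generated data and flag degeneracy", {
  set.seed(23)
  n_sub <- 60
  d <- data.frame(subject_id = rep(1:n_sub, each = 3),
                  x = rnorm(3 * n_sub))
  u <- rnorm(n_sub, 0, 0.4)
  d$zbmi <- 0.3 * d$x + u[d$subject_id] + rnorm(nrow(d), 0, 0.8)
  spec <- model_spec(exposure = "x", covariates = character(0))
  fit <- fit_multilevel(d, spec, n_iter = 1500, n_chains = 2, seed = 24)
  ppc <- posterior_predictive_check(fit, d, n_draws = 300, seed = 25)
  for (st in c("mean", "sd")) {
    p <- ppc$p_bayes[ppc$statistic == st]
    expect_gt(p, 0.05); expect_lt(p, 0.95)
  }
  # constant outcome: replicated sd always exceeds observed sd of 0
  d0 <- d; d0$zbmi <- 1
  fit0 <- fit_multilevel(d0, spec, n_iter = 600, n_chains = 1, seed = 26)
  ppc0 <- posterior_predictive_check(fit0, d0, n_draws = 100, seed = 27)
  expect_gt(ppc0$p_bayes[ppc0$statistic == "sd"], 0.99)
  expect_error(posterior_predictive_check(fit, d, n_draws = 0), "n_draws")
})

test_that("model specification guards its priors and shapes", {
  expect_error(model_spec(exposure = "x", prior_slope_sd = 0), "positive")
  expect_error(model_spec(exposure = c("a", "b"), varying_slope = TRUE),
               "single exposure")
  sp <- model_spec(exposure = c("a", "b"))
  expect_false(sp$varying_slope)
  expect_error(fit_multilevel(data.frame(zbmi = 1, subject_id = 1),
                              model_spec(exposure = "x")), "lacks columns")
})
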