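test_that("configuration invariants are enforced", {
  expect_error(simulation_config(library_size = 50), "library_size")
  expect_error(simulation_config(zbmi_ar = 1), "zbmi_ar")
  expect_error(simulation_config(missing_rate_stool = 1), "missing rates")
  expect_error(simulation_config(effect_vector = c(NotAGenus = 1)), "NotAGenus")
  cat2 <- default_genus_catalog()[1:5, ]
  expect_error(simulation_config(genus_catalog = cat2,
                                 composition_profiles =
                                   default_composition_profiles()),
               "catalogue size")
  prof <- default_composition_profiles()
  prof[1, 1] <- 0
  expect_error(simulation_config(composition_profiles = prof),
               "strictly positive")
})

test_that("equal seeds reproduce bit-identical cohorts; different seeds differ", {
  a <- small_cohort(n = 25, seed = 42)
  b <- small_cohort(n = 25, seed = 42)
  c <- small_cohort(n = 25, seed = 43)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$taxon_tables[["6y"]]$counts, b$taxon_tables[["6y"]]$counts)
  expect_false(identical(a$taxon_tables[["6y"]]$counts,
                         c$taxon_tables[["6y"]]$counts))
})

test_that("counts are complete multinomial draws at the drawn library size", {
  sc <- small_cohort(n = 30, seed = 2, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  for (tp in names(sc$taxon_tables)) {
    cnt <- sc$taxon_tables[[tp]]$counts
    expect_equal(nrow(cnt), 30)                 # no deletion at rate 0
    expect_true(all(rowSums(cnt) >= 100))
    expect_true(all(cnt == round(cnt)))
    expect_true(all(abs(rowSums(relative_abundance(sc$taxon_tables[[tp]])) - 1)
                    < 1e-12))
  }
})

test_that("null design yields no association between lagged CLR and zBMI", {
  sc <- simulate_cohort(simulation_config(
    n_subjects = 500, zbmi_ar = 0, missing_rate_stool = 0,
    missing_rate_anthro = 0, seed = 8))
  ct <- clr(sc$taxon_tables[["10y"]]$counts, pseudocount = 0.5)
  z12 <- sc$cohort$zbmi[sc$cohort$time_point == "12y"]
  # MC bound ~ 3/sqrt(n) for a null correlation
  for (g in c("Subdoligranulum", "Bifidobacterium", "Bacteroides")) {
    expect_lt(abs(cor(ct[, g], z12)), 3 / sqrt(500))
  }
})

test_that("infancy profiles leave most infant samples without Bacteroidetes", {
  sc <- small_cohort(n = 150, seed = 3, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  tt <- sc$taxon_tables[["1m"]]
  bgen <- tt$taxonomy$genus[tt$taxonomy$phylum == "Bacteroidetes"]
  frac_zero <- mean(rowSums(tt$counts[, bgen]) == 0)
  expect_gt(frac_zero, 0.5)
  # consequently the F/B ratio is mostly undefined in infancy
  f <- composition_features(tt)
  expect_gt(mean(is.na(f$fb_ratio)), 0.5)
})

test_that("phylum composition follows the configured infancy-to-childhood shift", {
  sc <- small_cohort(n = 150, seed = 4, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  m1 <- colMeans(relative_abundance(sc$taxon_tables[["1m"]], "phylum"))
  m10 <- colMeans(relative_abundance(sc$taxon_tables[["10y"]], "phylum"))
  expect_equal(unname(m1["Firmicutes"]), 0.27, tolerance = 0.25)
  expect_equal(unname(m10["Firmicutes"]), 0.72, tolerance = 0.1)
  expect_lt(m1["Bacteroidetes"], 0.05)
  expect_gt(m10["Bacteroidetes"], 0.05)
  expect_gt(m1["Actinobacteria"], m10["Actinobacteria"])
})

test_that("masking at rate zero is the identity", {
  sc <- small_cohort(n = 20, seed = 5, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  masked <- apply_missingness(sc, rates = list(stool = 0, anthro = 0),
                              mechanism = "MCAR", seed = 1)
  expect_identical(masked$cohort, sc$cohort)
  expect_identical(masked$taxon_tables[["1m"]]$counts,
                   sc$taxon_tables[["1m"]]$counts)
})

test_that("MCAR masking count falls in its binomial 99% interval", {
  # 125 subjects x 8 time points = 1000 anthropometry cells at rate 0.2
  sc <- small_cohort(n = 125, seed = 6, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  masked <- apply_missingness(sc, rates = list(stool = 0, anthro = 0.2),
                              mechanism = "MCAR", seed = 7)
  n_masked <- sum(is.na(masked$cohort$zbmi))
  expect_gte(n_masked, qbinom(0.005, 1000, 0.2))  # 160
  expect_lte(n_masked, qbinom(0.995, 1000, 0.2))  # 240
})

test_that("MAR masking probability increases with zBMI", {
  sc <- small_cohort(n = 250, seed = 9, missing_rate_stool = 0,
                     missing_rate_anthro = 0)
  masked <- apply_missingness(sc, rates = list(stool = 0, anthro = 0.25),
                              mechanism = "MAR-zbmi", seed = 10)
  miss <- is.na(masked$cohort$zbmi)
  z_true <- sc$truth$cohort_complete$zbmi
  fit <- glm(miss ~ z_true, family = binomial())
  expect_gt(coef(fit)["z_true"], 0)
  expect_lt(summary(fit)$coefficients["z_true", "Pr(>|z|)"], 0.01)
  # originals retained for imputation-quality scoring
  expect_false(anyNA(masked$truth$cohort_complete$zbmi))
  expect_error(apply_missingness(sc, rates = list(stool = 0, anthro = 1)),
               "rates")
})

test_that("planted effects act only at the configured exposure time points", {
  base <- list(n_subjects = 400, zbmi_ar = 0, missing_rate_stool = 0,
               missing_rate_anthro = 0, seed = 12,
               effect_vector = c(Subdoligranulum = -0.6))
  sc <- do.call(simulate_cohort,
                list(do.call(simulation_config,
                             c(base, list(effect_timepoints = "10y")))))
  z12 <- sc$cohort$zbmi[sc$cohort$time_point == "12y"]
  z3 <- sc$cohort$zbmi[sc$cohort$time_point == "3m"]
  clr10 <- sc$truth$clr_true[["10y"]][, "Subdoligranulum"]
  clr1 <- sc$truth$clr_true[["1m"]][, "Subdoligranulum"]
  expect_lt(cor(clr10, z12), -0.2)          # signal where planted
  expect_lt(abs(cor(clr1, z3)), 3 / sqrt(400))  # none elsewhere
})
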