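# Permutation-calibrated random-forest inference. The forest itself comes
# from ranger; the tuning loop, repeated cross-validation, permutation null
# distributions, add-one p-values and the Altmann importance test are
# implemented here.

rf_fit <- function(X, y, mtry, sample_fraction, num_trees, seed,
                   importance = "none") {
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = num_trees,
                 mtry = mtry, sample.fraction = sample_fraction,
                 replace = FALSE, importance = importance, seed = seed,
                 num.threads = 1)
}

#' Tune mtry and sample.fraction by out-of-bag error
#'
#' Randomised search: `budget` candidate pairs (mtry uniform over
#' 1..n_features, sample.fraction uniform over [0.3, 1]) are each fitted once
#' and scored by OOB mean squared error; the arg-min is returned.
#' Deterministic under `seed`.
#'
#' @param X predictor matrix or data.frame.
#' @param y numeric outcome.
#' @param budget number of candidate pairs.
#' @param num_trees trees per candidate fit.
#' @param seed RNG seed.
#' @return list of class `rf_hyperparams`: `mtry`, `sample_fraction`,
#'   `num_trees`, `oob_mse`.
#' @export
tune_rf <- function(X, y, budget = 20, num_trees = 500, seed = 1L) {
  stop_if(nrow(as.matrix(X)) < 20, "need at least 20 samples to tune")
  stop_if(ncol(as.matrix(X)) < 2, "need at least 2 features")
  stop_if(stats::sd(y) == 0, "outcome has zero variance")
  set.seed(seed)
  p <- ncol(as.matrix(X))
  cand <- data.frame(mtry = sample.int(p, budget, replace = TRUE),
                     sample_fraction = stats::runif(budget, 0.3, 1))
  cand <- unique(cand)
  oob <- vapply(seq_len(nrow(cand)), function(i) {
    rf_fit(X, y, cand$mtry[i], cand$sample_fraction[i], num_trees,
           seed = derive_seed(seed, i))$prediction.error
  }, numeric(1))
  best <- which.min(oob)
  structure(list(mtry = cand$mtry[best],
                 sample_fraction = cand$sample_fraction[best],
                 num_trees = num_trees, oob_mse = oob[best]),
            class = "rf_hyperparams")
}

#' Repeated k-fold cross-validated accuracy
#'
#' Per repeat, samples are split into `folds` folds; out-of-fold predictions
#' for every sample are pooled and their Pearson correlation with the
#' observed outcome computed. The median over repeats is the headline
#' accuracy; the OOB mean squared error of a full-data fit is reported
#' alongside.
#'
#' @param X,y predictors and outcome.
#' @param params an `rf_hyperparams` (see [tune_rf()]), or a list with
#'   `mtry`, `sample_fraction`, `num_trees`.
#' @param folds,repeats cross-validation layout (defaults: fourfold, ten
#'   repeats).
#' @param seed RNG seed.
#' @return list of class `rf_accuracy`: `cv_pearson_median`, `per_repeat`,
#'   `oob_mse`.
#' @export
repeated_cv <- function(X, y, params, folds = 4, repeats = 10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if(n < folds, "need at least as many samples as folds")
  set.seed(seed)
  per_repeat <- rep(NA_real_, repeats)
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      te <- fold_id == f
      fit <- rf_fit(X[!te, , drop = FALSE], y[!te], params$mtry,
                    params$sample_fraction, params$num_trees,
                    seed = derive_seed(seed, r * 100 + f))
      pred[te] <- stats::predict(fit, data = as.data.frame(X[te, , drop = FALSE]))$predictions
    }
    if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
      warning("constant predictions or outcome in repeat; repeat dropped",
              call. = FALSE)
      next
    }
    per_repeat[r] <- stats::cor(pred, y)
  }
  full <- rf_fit(X, y, params$mtry, params$sample_fraction, params$num_trees,
                 seed = derive_seed(seed, 99991))
  structure(list(cv_pearson_median = stats::median(per_repeat, na.rm = TRUE),
                 per_repeat = per_repeat,
                 oob_mse = full$prediction.error),
            class = "rf_accuracy")
}

#' Permutation-null significance of random-forest accuracy
#'
#' The observed accuracy (median cross-validated Pearson, and OOB MSE) is
#' compared with its distribution under `B` outcome permutations; tuning is
#' re-run inside every permutation by default so that the null carries the
#' same optimistic selection as the observed statistic. Add-one p-values:
#' `p_pearson = (1 + #{null >= obs}) / (B + 1)` and, since lower OOB error is
#' better, `p_oob = (1 + #{null <= obs}) / (B + 1)`.
#'
#' @param X,y predictors and outcome.
#' @param B number of permutations (>= 19 for p resolution).
#' @param folds,repeats cross-validation layout.
#' @param seed RNG seed.
#' @param retune re-tune hyperparameters inside each permutation.
#' @param params optional pre-tuned `rf_hyperparams`; tuned here when `NULL`.
#' @param tune_budget,num_trees tuning candidates and forest size.
#' @return list of class `rf_perm_test`: `observed` (`rf_accuracy`),
#'   `params`, `null_pearson`, `null_oob`, `p_pearson`, `p_oob`.
#' @export
permutation_null_test <- function(X, y, B = 199, folds = 4, repeats = 10,
                                  seed = 1L, retune = TRUE, params = NULL,
                                  tune_budget = 20, num_trees = 500) {
  stop_if(B < 19, "B must be >= 19")
  if (is.null(params))
    params <- tune_rf(X, y, budget = tune_budget, num_trees = num_trees,
                      seed = derive_seed(seed, 1))
  observed <- repeated_cv(X, y, params, folds = folds, repeats = repeats,
                          seed = derive_seed(seed, 2))
  null_pearson <- null_oob <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 1000 + b))
    yp <- sample(y)
    pb <- if (retune)
      tune_rf(X, yp, budget = tune_budget, num_trees = num_trees,
              seed = derive_seed(seed, 2000 + b)) else params
    acc <- repeated_cv(X, yp, pb, folds = folds, repeats = repeats,
                       seed = derive_seed(seed, 3000 + b))
    null_pearson[b] <- acc$cv_pearson_median
    null_oob[b] <- acc$oob_mse
  }
  structure(list(
    observed = observed, params = params,
    null_pearson = null_pearson, null_oob = null_oob,
    p_pearson = (1 + sum(null_pearson >= observed$cv_pearson_median)) / (B + 1),
    p_oob = (1 + sum(null_oob <= observed$oob_mse)) / (B + 1)
  ), class = "rf_perm_test")
}

#' BH adjustment over a model family
#'
#' Thin alias of [bh_adjust()] for the family of permutation p-values
#' produced by [run_model_family()].
#'
#' @param p vector of p-values.
#' @return q-values.
#' @export
bh_over_models <- function(p) bh_adjust(p)

#' Altmann permutation importance p-values
#'
#' The observed per-feature permutation importance (mean decrease in
#' accuracy) comes from a fit on the unpermuted outcome; `B` further fits on
#' permuted outcomes give each feature a null importance distribution, and
#' `p = (1 + #{null >= observed}) / (B + 1)`. Constant features have
#' importance 0 and p = 1 by convention.
#'
#' @param X,y predictors and outcome.
#' @param params `rf_hyperparams`.
#' @param B number of outcome permutations (>= 19).
#' @param seed RNG seed.
#' @return data.frame `feature`, `importance`, `p`.
#' @export
altmann_importance <- function(X, y, params, B = 199, seed = 1L) {
  stop_if(B < 19, "B must be >= 19")
  X <- as.matrix(X)
  obs_fit <- rf_fit(X, y, params$mtry, params$sample_fraction,
                    params$num_trees, seed = derive_seed(seed, 1),
                    importance = "permutation")
  obs <- obs_fit$variable.importance
  nulls <- matrix(NA_real_, B, length(obs),
                  dimnames = list(NULL, names(obs)))
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 4000 + b))
    yp <- sample(y)
    nulls[b, ] <- rf_fit(X, yp, params$mtry, params$sample_fraction,
                         params$num_trees, seed = derive_seed(seed, 5000 + b),
                         importance = "permutation")$variable.importance
  }
  p <- (1 + colSums(sweep(nulls, 2, obs, ">=") * 1)) / (B + 1)
  constant <- apply(X, 2, function(col) stats::sd(col) == 0)
  out <- data.frame(feature = names(obs), importance = unname(obs),
                    p = unname(p), stringsAsFactors = FALSE)
  out$importance[constant] <- 0
  out$p[constant] <- 1
  out[order(out$p, -out$importance), ]
}

#' Run the full cross-sectional / next-time-point model family
#'
#' For every stool time point, fits a cross-sectional model (zBMI at the same
#' time point) and, where a later anthropometry time point exists, a future
#' model (zBMI at the next time point), predicting zBMI from CLR genus
#' abundances. Each model is tuned, scored by [permutation_null_test()], and
#' the whole family's p-values are BH-adjusted per metric family. Altmann
#' importances are computed for models whose smaller p-value is below
#' `importance_p`.
#'
#' @param sc a `synthetic_cohort`, or a list with `taxon_tables` (named list
#'   of [taxon_table()]) and `cohort` (long anthropometry with `zbmi`).
#' @param B permutations per model.
#' @param folds,repeats,tune_budget,num_trees,retune settings forwarded to
#'   the per-model machinery.
#' @param importance_p compute importances for models with min(p) below this.
#' @param importance_B permutations for the Altmann test.
#' @param pseudocount CLR pseudocount for the feature matrix.
#' @param seed master seed; per-model seeds derive from it.
#' @param timepoint_order temporal order of time point labels.
#' @return list of class `rf_family`: `report` (data.frame
#'   `time_microbiota`, `time_zbmi`, `metric`, `median`, `p`, `q`),
#'   `params` (per model), `importances` (named list of data.frames).
#' @export
run_model_family <- function(sc, B = 199, folds = 4, repeats = 10,
                             tune_budget = 20, num_trees = 500, retune = TRUE,
                             importance_p = 0.05, importance_B = 199,
                             pseudocount = 0.5, seed = 1L,
                             timepoint_order = names(TP_AGE_DAYS)) {
  cohort <- sc$cohort
  tts <- sc$taxon_tables
  anthro_tps <- intersect(timepoint_order, unique(as.character(cohort$time_point)))
  stool_tps <- intersect(timepoint_order, names(tts))
  pairs <- list()
  for (tp in stool_tps) {
    pairs[[length(pairs) + 1]] <- c(tp, tp)           # cross-sectional
    later <- anthro_tps[which(anthro_tps == tp) + 1]
    if (length(later) == 1 && !is.na(later))
      pairs[[length(pairs) + 1]] <- c(tp, later)      # next time point
  }
  report <- list(); params <- list(); tests <- list()
  for (k in seq_along(pairs)) {
    tp_m <- pairs[[k]][1]; tp_z <- pairs[[k]][2]
    Xall <- clr(tts[[tp_m]]$counts, pseudocount = pseudocount)
    sample_subj <- sub(paste0("_", tp_m, "$"), "", rownames(Xall))
    zd <- cohort[cohort$time_point == tp_z, ]
    yv <- zd$zbmi[match(sample_subj, zd$subject_id)]
    keep <- !is.na(yv)
    # a subject absent from the cohort altogether is an id error; a subject
    # merely lacking zBMI at this time point is just dropped
    foreign <- !sample_subj %in% unique(cohort$subject_id)
    stop_if(any(foreign), "samples without cohort match: %s",
            paste(utils::head(rownames(Xall)[foreign], 5), collapse = ", "))
    pt <- permutation_null_test(Xall[keep, , drop = FALSE], yv[keep], B = B,
                                folds = folds, repeats = repeats,
                                seed = derive_seed(seed, 7000 + k),
                                retune = retune, tune_budget = tune_budget,
                                num_trees = num_trees)
    tests[[k]] <- pt
    params[[paste(tp_m, tp_z, sep = "->")]] <- pt$params
    report[[length(report) + 1]] <- data.frame(
      time_microbiota = tp_m, time_zbmi = tp_z,
      metric = c("OOB", "Pearson"),
      median = c(pt$observed$oob_mse, pt$observed$cv_pearson_median),
      p = c(pt$p_oob, pt$p_pearson), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  report$q <- bh_over_models(report$p)
  importances <- list()
  for (k in seq_along(pairs)) {
    tp_m <- pairs[[k]][1]; tp_z <- pairs[[k]][2]
    pmin_k <- min(tests[[k]]$p_oob, tests[[k]]$p_pearson)
    if (pmin_k < importance_p) {
      Xall <- clr(tts[[tp_m]]$counts, pseudocount = pseudocount)
      sample_subj <- sub(paste0("_", tp_m, "$"), "", rownames(Xall))
      zd <- cohort[cohort$time_point == tp_z, ]
      yv <- zd$zbmi[match(sample_subj, zd$subject_id)]
      keep <- !is.na(yv)
      importances[[paste(tp_m, tp_z, sep = "->")]] <-
        altmann_importance(Xall[keep, , drop = FALSE], yv[keep],
                           tests[[k]]$params, B = importance_B,
                           seed = derive_seed(seed, 8000 + k))
    }
  }
  structure(list(report = report, params = params, importances = importances),
            class = "rf_family")
}
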