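# Bayesian linear multilevel model: zBMI(T) on exposure(T-1), zBMI(T-1) and
# birthweight, with a varying intercept and (for a single exposure) a varying
# exposure slope per subject. Fitted by a Gibbs sampler with conjugate
# updates for coefficients and random effects and slice-sampling updates for
# the residual and random-effect SDs under their exponential priors.

#' Standardize variables, keeping the scaling record
#'
#' Centers and scales the named columns to mean 0, SD 1. zBMI is already on a
#' standard-normal scale and is left untouched by the shipped analyses.
#'
#' @param data data.frame.
#' @param variables columns to standardize.
#' @return list with `data` (transformed) and `scaling` (data.frame
#'   `variable`, `mean`, `sd`) for back-transformation or for applying the
#'   training-scale transform to new data via [apply_scaling()].
#' @export
standardize <- function(data, variables) {
  scaling <- data.frame(variable = variables, mean = NA_real_, sd = NA_real_,
                        stringsAsFactors = FALSE)
  for (k in seq_along(variables)) {
    v <- variables[k]
    stop_if(!v %in% names(data), "no column '%s'", v)
    mu <- mean(data[[v]], na.rm = TRUE)
    sdv <- stats::sd(data[[v]], na.rm = TRUE)
    stop_if(!is.finite(sdv) || sdv == 0, "variable '%s' has zero SD", v)
    data[[v]] <- (data[[v]] - mu) / sdv
    scaling$mean[k] <- mu; scaling$sd[k] <- sdv
  }
  list(data = data, scaling = scaling)
}

#' @rdname standardize
#' @param scaling a scaling record from [standardize()].
#' @export
apply_scaling <- function(data, scaling) {
  for (k in seq_len(nrow(scaling))) {
    v <- scaling$variable[k]
    if (v %in% names(data))
      data[[v]] <- (data[[v]] - scaling$mean[k]) / scaling$sd[k]
  }
  data
}

#' Multilevel model specification
#'
#' @param outcome outcome column name (zBMI at T).
#' @param exposure one or more exposure column names (values at T-1). With a
#'   single exposure its slope varies by subject; with a vector exposure only
#'   the intercept varies (see the methods vignette).
#' @param covariates covariate column names (lagged outcome, birthweight).
#' @param group grouping column (subject id).
#' @param prior_slope_sd SD of the zero-mean normal prior on the slopes of
#'   interest (0.5 default; 0.25 for many-genus exposure vectors).
#' @param prior_intercept_sd SD of the normal prior on the intercept.
#' @param prior_sd_rate rate of the exponential prior on the random-effect
#'   SDs (1 default; 15 as the stronger variant).
#' @param prior_resid_rate rate of the exponential prior on the residual SD.
#' @param varying_slope logical; force-disable the subject-varying exposure
#'   slope.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome = "zbmi", exposure, covariates = c("zbmi_lag",
                       "birthweight"), group = "subject_id",
                       prior_slope_sd = 0.5, prior_intercept_sd = 1,
                       prior_sd_rate = 1, prior_resid_rate = 1,
                       varying_slope = length(exposure) == 1) {
  stop_if(prior_slope_sd <= 0 || prior_intercept_sd <= 0 ||
            prior_sd_rate <= 0 || prior_resid_rate <= 0,
          "prior scales and rates must be positive")
  if (length(exposure) > 1 && varying_slope)
    stop("varying slope is supported for a single exposure only", call. = FALSE)
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, group = group,
                 prior_slope_sd = prior_slope_sd,
                 prior_intercept_sd = prior_intercept_sd,
                 prior_sd_rate = prior_sd_rate,
                 prior_resid_rate = prior_resid_rate,
                 varying_slope = varying_slope), class = "model_spec")
}

# draw from p(tau) propto exp(-(a*tau^2 - 2*b*tau)/(2*sigma2) - rate*tau),
# tau > 0: a normal truncated to the positive half-line
rtrunc_norm_pos <- function(a, b, sigma2, rate) {
  if (a <= 0) return(NA_real_)
  m <- (b - sigma2 * rate) / a
  s <- sqrt(sigma2 / a)
  lo <- stats::pnorm(0, m, s)
  if (lo > 1 - 1e-12) return(NA_real_)
  stats::qnorm(stats::runif(1, lo, 1), m, s)
}

# one Gibbs chain; returns matrix of draws (post-warmup) and last state
run_chain <- function(y, X, e, subj_idx, n_subj, spec, n_iter, warmup,
                      store_ranef = FALSE, include_ranef = TRUE,
                      fixed_sigma = NULL) {
  n <- length(y); p <- ncol(X)
  prior_prec <- 1 / c(spec$prior_intercept_sd,
                      rep(spec$prior_slope_sd, p - 1))^2
  vs <- include_ranef && spec$varying_slope && !is.null(e)
  # overdispersed initials
  b <- stats::rnorm(p, 0, 0.5)
  sigma <- if (is.null(fixed_sigma))
    stats::rexp(1, spec$prior_resid_rate) + 0.3 else fixed_sigma
  tau0 <- stats::rexp(1, spec$prior_sd_rate) + 0.1
  tau1 <- if (vs) stats::rexp(1, spec$prior_sd_rate) + 0.1 else 0
  u0 <- if (include_ranef) stats::rnorm(n_subj, 0, tau0) else rep(0, n_subj)
  u1 <- if (vs) stats::rnorm(n_subj, 0, tau1) else rep(0, n_subj)
  XtX <- crossprod(X)
  keep <- n_iter - warmup
  pn <- c(colnames(X), if (include_ranef) "sd_intercept", if (vs) "sd_slope",
          "sigma")
  out <- matrix(NA_real_, keep, length(pn), dimnames = list(NULL, pn))
  uout <- if (store_ranef) array(NA_real_, c(keep, n_subj, 2)) else NULL
  log_sd_target <- function(ls, ssq, cnt, rate) {
    s <- exp(ls)
    -cnt * ls - ssq / (2 * s^2) - rate * s + ls
  }
  for (it in seq_len(n_iter)) {
    # fixed effects | rest (conjugate normal)
    r <- y - u0[subj_idx] - (if (vs) u1[subj_idx] * e else 0)
    A <- XtX / sigma^2 + diag(prior_prec, p)
    Ra <- chol(A)
    mu_b <- backsolve(Ra, forwardsolve(t(Ra), crossprod(X, r) / sigma^2))
    b <- drop(mu_b + backsolve(Ra, stats::rnorm(p)))
    # subject effects | rest (conjugate, vectorised 2x2 / 1x1 solves)
    w <- y - drop(X %*% b)
    if (!include_ranef) {
      if (is.null(fixed_sigma)) {
        ssr <- sum(w^2)
        sigma <- exp(slice_sample1(log(sigma), function(ls)
          log_sd_target(ls, ssr, n, spec$prior_resid_rate), w = 0.5))
      }
      if (it > warmup) out[it - warmup, ] <- c(b, sigma)
      next
    }
    if (vs) {
      sw <- rowsum(cbind(1, e, e^2, w, w * e), subj_idx)
      nj <- sw[, 1]; se <- sw[, 2]; see <- sw[, 3]; swj <- sw[, 4]; swe <- sw[, 5]
      a11 <- nj / sigma^2 + 1 / tau0^2
      a12 <- se / sigma^2
      a22 <- see / sigma^2 + 1 / tau1^2
      det <- a11 * a22 - a12^2
      m1 <- (a22 * swj - a12 * swe) / (det * sigma^2)
      m2 <- (a11 * swe - a12 * swj) / (det * sigma^2)
      c11 <- a22 / det; c12 <- -a12 / det; c22 <- a11 / det
      l11 <- sqrt(c11); l21 <- c12 / l11; l22 <- sqrt(pmax(c22 - l21^2, 1e-12))
      z1 <- stats::rnorm(n_subj); z2 <- stats::rnorm(n_subj)
      u0 <- m1 + l11 * z1
      u1 <- m2 + l21 * z1 + l22 * z2
    } else {
      sw <- rowsum(cbind(1, w), subj_idx)
      a11 <- sw[, 1] / sigma^2 + 1 / tau0^2
      u0 <- sw[, 2] / (sigma^2 * a11) + stats::rnorm(n_subj) / sqrt(a11)
    }
    # residual SD | rest (slice on log scale, exponential prior)
    res <- w - u0[subj_idx] - (if (vs) u1[subj_idx] * e else 0)
    if (is.null(fixed_sigma)) {
      ssr <- sum(res^2)
      sigma <- exp(slice_sample1(log(sigma), function(ls)
        log_sd_target(ls, ssr, n, spec$prior_resid_rate), w = 0.5))
    }
    # random-effect SDs | rest: centered slice update, then a non-centered
    # (interweaving) update that treats u/tau as ancillary -- the conditional
    # for tau is then a positive-truncated normal, which keeps the SDs mixing
    # even when they sit near zero
    tau0 <- exp(slice_sample1(log(tau0), function(ls)
      log_sd_target(ls, sum(u0^2), n_subj, spec$prior_sd_rate), w = 1))
    if (tau0 > 1e-8) {
      ut <- u0 / tau0
      r0 <- w - (if (vs) u1[subj_idx] * e else 0)
      zc <- ut[subj_idx]
      tau_new <- rtrunc_norm_pos(
        a = sum(zc^2), b = sum(r0 * zc), sigma2 = sigma^2,
        rate = spec$prior_sd_rate)
      if (is.finite(tau_new) && tau_new > 0) {
        tau0 <- tau_new
        u0 <- ut * tau0
      }
    }
    if (vs) {
      tau1 <- exp(slice_sample1(log(tau1), function(ls)
        log_sd_target(ls, sum(u1^2), n_subj, spec$prior_sd_rate), w = 1))
      if (tau1 > 1e-8) {
        ut1 <- u1 / tau1
        r1 <- w - u0[subj_idx]
        zc <- ut1[subj_idx] * e
        tau_new <- rtrunc_norm_pos(
          a = sum(zc^2), b = sum(r1 * zc), sigma2 = sigma^2,
          rate = spec$prior_sd_rate)
        if (is.finite(tau_new) && tau_new > 0) {
          tau1 <- tau_new
          u1 <- ut1 * tau1
        }
      }
    }
    if (it > warmup) {
      out[it - warmup, ] <- c(b, tau0, if (vs) tau1, sigma)
      if (store_ranef) uout[it - warmup, , ] <- cbind(u0, u1)
    }
  }
  list(draws = out, ranef = uout)
}

#' Fit the Bayesian multilevel model by MCMC
#'
#' Stacked long data: one row per (subject, time point T) with the outcome at
#' T and exposure/lagged outcome at T-1 already joined (see
#' [lagged_dataset()]). Fixed effects get zero-mean normal priors
#' (`prior_slope_sd` on all slopes, `prior_intercept_sd` on the intercept);
#' random-effect SDs and the residual SD get exponential priors. Coefficients
#' and subject effects are updated by conjugate Gibbs draws, the three SDs by
#' univariate slice sampling on the log scale. Chains start overdispersed.
#'
#' @param data data.frame with the spec's columns; rows with any missing
#'   model variable are dropped (use [pmm_impute()] +
#'   [fit_across_imputations()] to propagate missingness instead).
#' @param spec a [model_spec()].
#' @param n_iter iterations per chain (first half is warmup).
#' @param n_chains number of chains.
#' @param seed RNG seed.
#' @param store_ranef keep subject-effect draws (needed only for
#'   subject-level summaries).
#' @param include_ranef set `FALSE` to drop all subject effects (plain
#'   Bayesian linear regression; used for closed-form validation).
#' @param fixed_sigma optionally hold the residual SD fixed at a known value
#'   instead of sampling it.
#' @return object of class `multilevel_fit`: `draws` (list of post-warmup
#'   draw matrices, one per chain), `spec`, `data_n`, `n_subjects`.
#' @export
fit_multilevel <- function(data, spec, n_iter = 2500, n_chains = 4,
                           seed = 1L, store_ranef = FALSE,
                           include_ranef = TRUE, fixed_sigma = NULL) {
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  stop_if(!all(c(vars, spec$group) %in% names(data)),
          "data lacks columns: %s",
          paste(setdiff(c(vars, spec$group), names(data)), collapse = ", "))
  cc <- stats::complete.cases(data[, c(vars, spec$group)])
  d <- data[cc, , drop = FALSE]
  stop_if(nrow(d) < 10, "too few complete rows (%d)", nrow(d))
  y <- d[[spec$outcome]]
  X <- cbind(Intercept = 1, as.matrix(d[, c(spec$exposure, spec$covariates),
                                        drop = FALSE]))
  stop_if(any(!is.finite(X)) || any(!is.finite(y)), "non-finite model inputs")
  subj <- factor(d[[spec$group]])
  subj_idx <- as.integer(subj)
  e <- if (spec$varying_slope) X[, spec$exposure[1]] else NULL
  warmup <- floor(n_iter / 2)
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(derive_seed(seed, 300 + ch))
    run_chain(y, X, e, subj_idx, nlevels(subj), spec, n_iter, warmup,
              store_ranef = store_ranef, include_ranef = include_ranef,
              fixed_sigma = fixed_sigma)
  })
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 ranef = lapply(chains, `[[`, "ranef"),
                 spec = spec, data_n = nrow(d), n_subjects = nlevels(subj),
                 subjects = levels(subj)),
            class = "multilevel_fit")
}

# split-Rhat (Gelman et al.) over a list of draw vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via initial positive autocorrelation sums
ess_basic <- function(chains) {
  n <- length(chains[[1]]); m <- length(chains)
  rho <- rowMeans(vapply(chains, function(x) {
    a <- stats::acf(x, lag.max = min(100, n - 2), plot = FALSE)$acf[-1]
    as.numeric(a)
  }, numeric(min(100, n - 2))))
  s <- 0
  for (t in seq_along(rho)) {
    if (rho[t] < 0) break
    s <- s + rho[t]
  }
  m * n / (1 + 2 * s)
}

#' Summarise posterior draws
#'
#' @param fit a `multilevel_fit` or `pooled_posterior`.
#' @param ... unused.
#' @return data.frame `param`, `median`, `l95`, `u95`, `p_positive`, `rhat`,
#'   `ess` (diagnostics are per-chain based and therefore `NA` for pooled
#'   mixtures, where between-imputation spread is intentional).
#' @export
posterior_summary <- function(fit, ...) {
  draws <- fit$draws
  pn <- colnames(draws[[1]])
  do.call(rbind, lapply(pn, function(par) {
    per_chain <- lapply(draws, function(d) d[, par])
    all <- unlist(per_chain)
    data.frame(param = par,
               median = stats::median(all),
               l95 = unname(stats::quantile(all, 0.025)),
               u95 = unname(stats::quantile(all, 0.975)),
               p_positive = mean(all > 0),
               rhat = if (isTRUE(fit$pooled)) NA_real_ else split_rhat(per_chain),
               ess = if (isTRUE(fit$pooled)) NA_real_ else ess_basic(per_chain),
               stringsAsFactors = FALSE)
  }))
}

#' Fit the model on every completed dataset and mix the draws
#'
#' Uncertainty propagation across multiple imputations for a Bayesian fit:
#' the model is fitted to each completed dataset with identical spec and
#' sampler settings and the posterior draws are concatenated with equal
#' weight (equal draw counts per dataset are enforced). The mixture's
#' quantiles are the pooled inference.
#'
#' @param datasets list of completed data.frames (e.g.
#'   `pmm_impute(...)$completed`).
#' @param spec a [model_spec()].
#' @param n_iter,n_chains,seed sampler settings per dataset.
#' @return object of class `pooled_posterior` (also `multilevel_fit`):
#'   mixture draws in `$draws`, per-dataset convergence diagnostics in
#'   `$per_dataset_rhat`.
#' @export
fit_across_imputations <- function(datasets, spec, n_iter = 1500,
                                   n_chains = 2, seed = 1L) {
  stop_if(length(datasets) < 2, "need at least two completed datasets")
  fits <- lapply(seq_along(datasets), function(i)
    fit_multilevel(datasets[[i]], spec, n_iter = n_iter, n_chains = n_chains,
                   seed = derive_seed(seed, 500 + i)))
  sizes <- vapply(fits, function(f) sum(vapply(f$draws, nrow, integer(1))),
                  numeric(1))
  stop_if(length(unique(sizes)) != 1,
          "unequal draw counts across datasets; pooling requires equal weights")
  pnames <- lapply(fits, function(f) colnames(f$draws[[1]]))
  stop_if(length(unique(vapply(pnames, paste, character(1), collapse = ","))) != 1,
          "divergent model specs across datasets")
  rhats <- vapply(fits, function(f) {
    s <- posterior_summary(f); max(s$rhat)
  }, numeric(1))
  structure(list(
    draws = list(do.call(rbind, unlist(lapply(fits, `[[`, "draws"),
                                       recursive = FALSE))),
    spec = spec, pooled = TRUE, m = length(datasets),
    per_dataset_rhat = rhats,
    data_n = fits[[1]]$data_n, n_subjects = fits[[1]]$n_subjects
  ), class = c("pooled_posterior", "multilevel_fit"))
}

#' Posterior predictive check
#'
#' Simulates replicate outcome vectors from the fitted model (coefficients,
#' SDs and residual noise from the posterior; subject effects redrawn from
#' their population distribution, i.e. a new-subjects replication) and
#' compares summary statistics of the replicates with the observed outcome.
#' Bayesian p-values near 0 or 1 flag misfit.
#'
#' @param fit a `multilevel_fit`.
#' @param data the data the model was fitted to.
#' @param n_draws number of replicate datasets.
#' @param seed RNG seed.
#' @return data.frame `statistic`, `observed`, `rep_mean`, `p_bayes`
#'   (`P(T(rep) >= T(obs))`).
#' @export
posterior_predictive_check <- function(fit, data, n_draws = 200, seed = 1L) {
  stop_if(n_draws < 1, "n_draws must be >= 1")
  spec <- fit$spec
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  d <- data[stats::complete.cases(data[, c(vars, spec$group)]), , drop = FALSE]
  y <- d[[spec$outcome]]
  X <- cbind(Intercept = 1, as.matrix(d[, c(spec$exposure, spec$covariates),
                                        drop = FALSE]))
  subj <- as.integer(factor(d[[spec$group]]))
  nsub <- max(subj)
  all_draws <- do.call(rbind, fit$draws)
  set.seed(seed)
  idx <- sample.int(nrow(all_draws), n_draws, replace = n_draws > nrow(all_draws))
  pn <- colnames(all_draws)
  bcols <- setdiff(pn, c("sd_intercept", "sd_slope", "sigma"))
  vs <- "sd_slope" %in% pn
  stats_fun <- function(v) c(mean = mean(v), sd = stats::sd(v),
                             min = min(v), max = max(v))
  obs <- stats_fun(y)
  reps <- vapply(idx, function(i) {
    dr <- all_draws[i, ]
    u0 <- if ("sd_intercept" %in% pn)
      stats::rnorm(nsub, 0, dr["sd_intercept"]) else rep(0, nsub)
    mu <- drop(X %*% dr[bcols]) + u0[subj]
    if (vs) {
      u1 <- stats::rnorm(nsub, 0, dr["sd_slope"])
      mu <- mu + u1[subj] * X[, spec$exposure[1]]
    }
    stats_fun(mu + stats::rnorm(length(mu), 0, dr["sigma"]))
  }, obs)
  data.frame(statistic = names(obs), observed = obs,
             rep_mean = rowMeans(reps),
             p_bayes = rowMeans(reps >= obs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stack lagged (T-1 exposure, T outcome) pairs into long format
#'
#' For every anthropometry time point whose immediate predecessor is a stool
#' time point, emits a row with zBMI at T, zBMI at T-1, birthweight, and the
#' exposure feature(s) measured at T-1. Subjects missing a lag contribute
#' only their available pairs.
#'
#' @param cohort long anthropometry data.frame (`subject_id`, `time_point`,
#'   `zbmi`, `birthweight_g`).
#' @param features data.frame `subject_id`, `time_point`, plus one column per
#'   feature, measured at stool time points.
#' @param exposure feature column(s) to carry as exposure.
#' @param timepoint_order temporal order of all time points.
#' @param subset `"all"`, `"infancy"` (exposure time points labelled in
#'   months) or `"childhood"` (labelled in years).
#' @return data.frame `subject_id`, `time_point`, `exposure_time`, `zbmi`,
#'   `zbmi_lag`, `birthweight`, exposure columns.
#' @export
lagged_dataset <- function(cohort, features, exposure,
                           timepoint_order = names(TP_AGE_DAYS),
                           subset = c("all", "infancy", "childhood")) {
  subset <- match.arg(subset)
  stop_if(!all(exposure %in% names(features)),
          "features lack exposure column(s): %s",
          paste(setdiff(exposure, names(features)), collapse = ", "))
  tps <- intersect(timepoint_order, unique(as.character(cohort$time_point)))
  stool_tps <- unique(as.character(features$time_point))
  rows <- list()
  for (k in seq_along(tps)[-1]) {
    prev <- tps[k - 1]
    if (!prev %in% stool_tps) next
    if (subset == "infancy" && !grepl("m$", prev)) next
    if (subset == "childhood" && !grepl("y$", prev)) next
    cur_d <- cohort[cohort$time_point == tps[k], ]
    prev_d <- cohort[cohort$time_point == prev, ]
    f <- features[features$time_point == prev, ]
    ids <- cur_d$subject_id
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = ids, time_point = tps[k], exposure_time = prev,
      zbmi = cur_d$zbmi,
      zbmi_lag = prev_d$zbmi[match(ids, prev_d$subject_id)],
      birthweight = cur_d$birthweight_g,
      f[match(ids, f$subject_id), exposure, drop = FALSE],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  stop_if(length(rows) == 0, "no (stool T-1, anthropometry T) pairs found")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
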