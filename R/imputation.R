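# Multiple imputation by chained equations with predictive mean matching
# (PMM), implemented from first principles: per sweep and per variable, a
# Bayesian linear regression on all other variables; missing cases get a
# coefficient draw (type-1 matching), observed cases the least-squares fit;
# each missing case copies the observed value of one of its k nearest
# predicted neighbours.

#' Imputation configuration
#'
#' @param m number of completed datasets.
#' @param iterations chained-equation sweeps per dataset.
#' @param donors donor-pool size k for predictive mean matching.
#' @param seed RNG seed; stream `i` of `m` derives from it.
#' @return validated list of class `imputation_config`.
#' @export
imputation_config <- function(m = 10, iterations = 10, donors = 5, seed = 1L) {
  stop_if(m < 2, "m must be >= 2")
  stop_if(iterations < 1, "iterations must be >= 1")
  stop_if(donors < 1, "donors must be >= 1")
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors = as.integer(donors), seed = as.integer(seed)),
            class = "imputation_config")
}

# Bayesian linear draw for PMM: returns predictions for missing cases under a
# posterior coefficient draw and for observed cases under the LS fit.
pmm_predict <- function(X, y, obs, ridge = 1e-5) {
  Xo <- X[obs, , drop = FALSE]
  yo <- y[obs]
  p <- ncol(Xo)
  XtX <- crossprod(Xo) + diag(ridge * pmax(diag(crossprod(Xo)), 1), p)
  R <- chol(XtX)
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, yo)))
  df <- max(length(yo) - p, 1)
  resid <- yo - Xo %*% beta_hat
  sigma2 <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- beta_hat + backsolve(R, stats::rnorm(p)) * sqrt(sigma2)
  list(yhat_obs = drop(Xo %*% beta_hat),
       yhat_mis = drop(X[!obs, , drop = FALSE] %*% beta_star))
}

pmm_match <- function(yhat_obs, y_obs, yhat_mis, k) {
  vapply(yhat_mis, function(h) {
    d <- abs(yhat_obs - h)
    pool <- order(d)[seq_len(min(k, length(d)))]
    y_obs[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

#' Multiple imputation with predictive mean matching
#'
#' Runs `config$m` independent chained-equation streams. Within a stream,
#' missing cells are first filled with random draws from the observed values
#' of their variable; then `config$iterations` sweeps update each incomplete
#' variable (visited in order of increasing missingness) by regressing it on
#' all other variables and copying, for every missing case, the observed
#' value of one of the `config$donors` nearest predicted neighbours. Imputed
#' values are therefore always members of the observed support of their
#' variable.
#'
#' @param data data.frame of numeric variables, `NA` marking missing cells.
#' @param config an [imputation_config()].
#' @return list of class `pmm_imputation`: `completed` (list of m completed
#'   data.frames), `chain_means` (array sweeps x variables x m of imputed-cell
#'   means, for convergence inspection), `config`.
#' @export
pmm_impute <- function(data, config = imputation_config()) {
  stop_if(!all(vapply(data, is.numeric, logical(1))),
          "all variables must be numeric (encode factors before imputing)")
  miss <- vapply(data, function(v) sum(is.na(v)), integer(1))
  stop_if(any(miss == nrow(data)), "fully missing variable(s): %s",
          paste(names(data)[miss == nrow(data)], collapse = ", "))
  n_obs <- nrow(data) - miss
  stop_if(any(n_obs < config$donors + 1 & miss > 0),
          "too few observed values to form a donor pool for: %s",
          paste(names(data)[n_obs < config$donors + 1 & miss > 0], collapse = ", "))
  incomplete <- names(data)[miss > 0][order(miss[miss > 0])]
  if (length(incomplete) == 0) {
    return(structure(list(completed = rep(list(data), config$m),
                          chain_means = NULL, config = config),
                     class = "pmm_imputation"))
  }
  completed <- vector("list", config$m)
  chain_means <- array(NA_real_,
                       dim = c(config$iterations, length(incomplete), config$m),
                       dimnames = list(NULL, incomplete, NULL))
  for (i in seq_len(config$m)) {
    set.seed(derive_seed(config$seed, 100 + i))
    cur <- data
    for (v in incomplete) {                      # initial fill
      obs_vals <- data[[v]][!is.na(data[[v]])]
      cur[[v]][is.na(data[[v]])] <-
        sample(obs_vals, miss[v], replace = TRUE)
    }
    for (it in seq_len(config$iterations)) {
      for (v in incomplete) {
        obs <- !is.na(data[[v]])
        X <- cbind(1, as.matrix(cur[, setdiff(names(data), v), drop = FALSE]))
        pred <- pmm_predict(X, ifelse(obs, data[[v]], 0), obs)
        cur[[v]][!obs] <- pmm_match(pred$yhat_obs, data[[v]][obs],
                                    pred$yhat_mis, config$donors)
        chain_means[it, v, i] <- mean(cur[[v]][!obs])
      }
    }
    completed[[i]] <- cur
  }
  structure(list(completed = completed, chain_means = chain_means,
                 config = config), class = "pmm_imputation")
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' @param estimates numeric vector (or matrix, one row per imputation) of
#'   point estimates.
#' @param variances matching squared standard errors.
#' @return list with `estimate`, `total_variance`, `within`, `between`, `df`
#'   (Barnard-Rubin small-sample form is not applied; classic Rubin df).
#' @export
pool_estimates <- function(estimates, variances) {
  estimates <- as.matrix(estimates); variances <- as.matrix(variances)
  stop_if(!all(dim(estimates) == dim(variances)),
          "estimates and variances must have matching shapes")
  m <- nrow(estimates)
  stop_if(m < 2, "need m >= 2 imputations to pool")
  qbar <- colMeans(estimates)
  ubar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  total <- ubar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2, Inf)
  list(estimate = qbar, total_variance = total, within = ubar, between = b,
       df = df)
}
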