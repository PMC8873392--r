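# Confirmatory descriptive layer: cross-time-point Spearman correlation
# matrices with Benjamini-Hochberg control restricted to the hypothesised
# cells.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks (ties get their mean
#' rank); the p-value uses `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom, two-sided. Pairwise-complete observations only.
#'
#' @param x,y numeric vectors of equal length; `NA`s dropped pairwise.
#' @return list with `rho`, `p`, `n`. When fewer than 3 complete pairs are
#'   available all three are `NA` (a missing cell, not an error).
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1]; `NA`s pass through.
#' @return adjusted p-values (q-values); rejection at level alpha
#'   corresponds to adjusted p <= alpha.
#' @export
bh_adjust <- function(p) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cross-time-point Spearman correlation matrix
#'
#' Builds the full grid of Spearman correlations between a predictor variable
#' at every time point and zBMI at every time point (pairwise-complete,
#' subjects aligned by id), then applies BH adjustment over the hypothesised
#' cells only. The default hypothesis mask selects same-time-point and
#' next-time-point (predictor earlier) cells — the a-priori directional
#' questions; all other cells are reported unadjusted.
#'
#' @param predictor data.frame `subject_id`, `time_point`, `value`.
#' @param outcome data.frame `subject_id`, `time_point`, `value` (zBMI).
#' @param timepoint_order character vector giving the temporal order of the
#'   union of time points.
#' @param mask optional logical matrix (predictor time x outcome time)
#'   marking hypothesised cells; `NULL` uses the default described above.
#' @return data.frame `var_a`, `time_a`, `var_b`, `time_b`, `rho`, `p`, `n`,
#'   `hypothesized`, `p_adj` (`NA` outside the mask).
#' @export
correlation_matrix <- function(predictor, outcome, timepoint_order,
                               mask = NULL) {
  ptps <- intersect(timepoint_order, unique(as.character(predictor$time_point)))
  otps <- intersect(timepoint_order, unique(as.character(outcome$time_point)))
  if (is.null(mask)) {
    mask <- matrix(FALSE, length(ptps), length(otps),
                   dimnames = list(ptps, otps))
    ord <- stats::setNames(seq_along(timepoint_order), timepoint_order)
    for (a in ptps) for (b in otps) {
      d <- ord[b] - ord[a]
      if (d == 0 || d == 1) mask[a, b] <- TRUE
    }
  }
  rows <- list()
  for (a in ptps) for (b in otps) {
    xa <- predictor[predictor$time_point == a, ]
    yb <- outcome[outcome$time_point == b, ]
    ids <- union(xa$subject_id, yb$subject_id)
    s <- spearman_cor(xa$value[match(ids, xa$subject_id)],
                      yb$value[match(ids, yb$subject_id)])
    rows[[length(rows) + 1]] <- data.frame(
      var_a = "predictor", time_a = a, var_b = "zbmi", time_b = b,
      rho = s$rho, p = s$p, n = s$n, hypothesized = mask[a, b],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  hyp <- out$hypothesized
  out$p_adj[hyp] <- bh_adjust(out$p[hyp])
  out
}
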