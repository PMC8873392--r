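#!/usr/bin/env Rscript
# Confirmatory descriptive layer: Spearman correlation matrices between each
# predictor (F/B ratio, SCFA sum score) and zBMI across all time points,
# BH-adjusted over the hypothesised (same and next time point) cells.

source(file.path("analysis", "00_common.R"))

sc <- load_cohort()
feats <- feature_table(sc$taxon_tables)
tp_order <- c("1m", "3m", "4m", "2y", "6y", "7y", "10y", "12y")

outcome <- data.frame(subject_id = sc$cohort$subject_id,
                      time_point = as.character(sc$cohort$time_point),
                      value = sc$cohort$zbmi)
for (pred in c("fb_ratio", "scfa_sum_clr")) {
  p <- data.frame(subject_id = feats$subject_id,
                  time_point = feats$time_point, value = feats[[pred]])
  m <- correlation_matrix(p, outcome, tp_order)
  m$var_a <- pred
  f <- file.path(RESULTS_DIR, sprintf("correlations_%s.tsv", pred))
  write.table(m, f, sep = "\t", quote = FALSE, row.names = FALSE)
  hyp <- m[m$hypothesized & !is.na(m$p), ]
  cat(sprintf("%s: %d hypothesised cells, %d nominal p < 0.05, %d with q < 0.05\n",
              pred, nrow(hyp), sum(hyp$p < 0.05), sum(hyp$p_adj < 0.05)))
}
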