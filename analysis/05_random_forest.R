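#!/usr/bin/env Rscript
# Exploratory layer: tuned random-forest regressions of zBMI on genus CLR
# abundances, one cross-sectional and one next-time-point model per stool
# time point, with permutation-null p-values, family-wide BH correction, and
# Altmann importances for models below the significance threshold.

source(file.path("analysis", "00_common.R"))

sc <- load_cohort()

# desk-scale run (~4 min on one CPU); raise B, repeats and num_trees for a
# production run
fam <- run_model_family(sc, B = 49, folds = 4, repeats = 3, tune_budget = 6,
                        num_trees = 100, retune = TRUE,
                        importance_p = 0.05, importance_B = 49,
                        seed = derive_seed(MASTER_SEED, 6))

write.table(fam$report, file.path(RESULTS_DIR, "rf_family.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(fam$report, digits = 3)

sig <- unique(with(fam$report, paste(time_microbiota, time_zbmi)[p < 0.05]))
cat(sprintf("\nmodels with p < 0.05: %s\n",
            if (length(sig)) paste(sig, collapse = "; ") else "none"))
for (nm in names(fam$importances)) {
  imp <- fam$importances[[nm]]
  write.table(cbind(model = nm, imp),
              file.path(RESULTS_DIR,
                        sprintf("rf_importance_%s.tsv", gsub("->", "_", nm))),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("top importances for %s: %s\n", nm,
              paste(head(imp$feature, 5), collapse = ", ")))
}
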