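# End-to-end orchestration: simulate or load inputs, compute zBMI and
# compositional features, screen correlations, impute and fit the multilevel
# models, run the random-forest family, and write every table plus a run
# manifest.

#' Pipeline configuration
#'
#' Either programmatic (a named list) or read from YAML via
#' [read_pipeline_config()]. Every stage seed derives from `seed`.
#'
#' @param input either `list(simulate = simulation_config(...))` or
#'   `list(taxon_counts = <named paths per time point>, taxonomy = path,
#'   anthro = path, reference = path)`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param proxy proxy definition data.frame (default [scfa_producers()]).
#' @param pseudocount CLR pseudocount.
#' @param zbmi_bound outlier cut-off on |zBMI|.
#' @param min_rel_abundance optional input-side abundance filter (0 = off).
#' @param imputation an [imputation_config()].
#' @param multilevel list with `exposure` (feature name), `n_iter`,
#'   `n_chains`, and any [model_spec()] prior overrides.
#' @param rf list of [run_model_family()] settings.
#' @param stages character vector of stages to run, a subset of
#'   `c("features", "screen", "multilevel", "rf")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, seed = 1L,
                            proxy = scfa_producers(), pseudocount = 0.5,
                            zbmi_bound = 3, min_rel_abundance = 0,
                            imputation = imputation_config(seed = seed),
                            multilevel = list(exposure = "scfa_sum_clr",
                                              n_iter = 1500, n_chains = 2),
                            rf = list(B = 99, folds = 4, repeats = 5,
                                      tune_budget = 10, num_trees = 200,
                                      retune = TRUE),
                            stages = c("features", "screen", "multilevel", "rf")) {
  stop_if(missing(input) || is.null(input), "input block required")
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 proxy = proxy, pseudocount = pseudocount,
                 zbmi_bound = zbmi_bound,
                 min_rel_abundance = min_rel_abundance,
                 imputation = imputation, multilevel = multilevel, rf = rf,
                 stages = stages), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same fields.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  imp <- do.call(imputation_config, y$imputation %||% list())
  args <- y[setdiff(names(y), c("imputation"))]
  args$imputation <- imp
  do.call(pipeline_config, args)
}

#' Validate pipeline inputs
#'
#' Checks id cross-references between taxon tables and the anthropometry
#' table, non-negative counts, per-subject age monotonicity across time
#' points, and sex coding. Violations are reported, not thrown.
#'
#' @param cohort anthropometry data.frame.
#' @param taxon_tables named list of [taxon_table()] per time point.
#' @param timepoint_order temporal order of time point labels.
#' @return character vector of violations (empty when clean).
#' @export
validate_inputs <- function(cohort, taxon_tables,
                            timepoint_order = names(TP_AGE_DAYS)) {
  v <- character(0)
  need <- c("subject_id", "time_point", "age_days", "sex", "weight_kg",
            "length_cm", "birthweight_g")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    v <- c(v, sprintf("anthropometry lacks columns: %s", paste(miss, collapse = ", ")))
  if ("sex" %in% names(cohort)) {
    bad <- setdiff(unique(stats::na.omit(cohort$sex)), c("F", "M"))
    if (length(bad) > 0)
      v <- c(v, sprintf("unexpected sex codes: %s", paste(bad, collapse = ", ")))
  }
  if (all(c("subject_id", "time_point", "age_days") %in% names(cohort))) {
    tp_rank <- stats::setNames(seq_along(timepoint_order), timepoint_order)
    for (s in unique(cohort$subject_id)) {
      d <- cohort[cohort$subject_id == s & !is.na(cohort$age_days), ]
      d <- d[order(tp_rank[as.character(d$time_point)]), ]
      if (nrow(d) > 1 && any(diff(d$age_days) <= 0))
        v <- c(v, sprintf("subject %s: age not increasing across time points", s))
    }
  }
  for (tp in names(taxon_tables)) {
    tt <- taxon_tables[[tp]]
    if (any(tt$counts < 0)) {
      idx <- which(tt$counts < 0, arr.ind = TRUE)[1, ]
      v <- c(v, sprintf("negative count at %s: sample %s, genus %s", tp,
                        rownames(tt$counts)[idx[1]], colnames(tt$counts)[idx[2]]))
    }
    subj <- sub(paste0("_", tp, "$"), "", rownames(tt$counts))
    foreign <- setdiff(subj, unique(cohort$subject_id))
    if (length(foreign) > 0)
      v <- c(v, sprintf("%s samples without anthropometry subject: %s", tp,
                        paste(utils::head(foreign, 5), collapse = ", ")))
  }
  v
}

#' Long feature table across stool time points
#'
#' Applies [composition_features()] to each time point's taxon table and
#' stacks the results, attaching `time_point` and `subject_id` (parsed from
#' `<subject>_<timepoint>` sample ids). The genus-level CLR matrices are kept
#' in attribute `"genus_clr"` (a named list).
#'
#' @param taxon_tables named list of [taxon_table()] keyed by time point.
#' @inheritParams composition_features
#' @return data.frame, one row per sample.
#' @export
feature_table <- function(taxon_tables, proxy = scfa_producers(),
                          pseudocount = 0.5,
                          clr_scope = c("modified", "full")) {
  clr_mats <- list()
  out <- do.call(rbind, lapply(names(taxon_tables), function(tp) {
    f <- composition_features(taxon_tables[[tp]], proxy = proxy,
                              pseudocount = pseudocount,
                              clr_scope = clr_scope)
    clr_mats[[tp]] <<- attr(f, "genus_clr")
    f$time_point <- tp
    f$subject_id <- sub(paste0("_", tp, "$"), "", f$sample_id)
    f
  }))
  attr(out, "genus_clr") <- clr_mats
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order: cohort assembly (simulation or file input), zBMI scoring and
#' outlier removal, compositional features, Spearman screening, multiple
#' imputation + multilevel fits, random-forest family. Writes
#' `zbmi_table.tsv`, `features.tsv`, `correlations_fb.tsv`,
#' `correlations_scfa.tsv`, `multilevel_summary.tsv`, `rf_family.tsv` and
#' `manifest.json` under `config$out_dir`; partial outputs are removed if a
#' stage fails. Idempotent under identical config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with all in-memory results (`cohort`, `features`,
#'   `screen`, `multilevel`, `rf`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stop_if(!inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    # ---- assemble inputs -------------------------------------------------
    if (!is.null(config$input$simulate)) {
      sc <- simulate_cohort(config$input$simulate)
      cohort <- sc$cohort
      taxon_tables <- sc$taxon_tables
      reference <- sc$reference
    } else {
      paths <- config$input
      for (p in c(unlist(paths$taxon_counts), paths$taxonomy, paths$anthro,
                  paths$reference))
        stop_if(!file.exists(p), "input file not found: %s", p)
      taxon_tables <- lapply(paths$taxon_counts, function(p)
        read_taxon_table(p, paths$taxonomy))
      cohort <- utils::read.csv(paths$anthro, stringsAsFactors = FALSE)
      reference <- read_growth_reference(paths$reference)
      sc <- list(cohort = cohort, taxon_tables = taxon_tables)
    }
    violations <- validate_inputs(cohort, taxon_tables)
    hard <- grepl("negative count|without anthropometry|lacks columns", violations)
    stop_if(any(hard), "input validation failed:\n%s",
            paste(violations[hard], collapse = "\n"))
    if (config$min_rel_abundance > 0)
      taxon_tables <- lapply(taxon_tables, abundance_filter,
                             min_rel_abundance = config$min_rel_abundance)

    # ---- zBMI ------------------------------------------------------------
    cohort$zbmi <- zbmi(cohort$weight_kg, cohort$length_cm, cohort$age_days,
                        cohort$sex, reference)
    fl <- flag_outliers(cohort, bound = config$zbmi_bound)
    cohort <- fl$kept
    written <- c(written, write_tsv(cohort, file.path(config$out_dir, "zbmi_table.tsv")))

    # ---- features --------------------------------------------------------
    features <- feature_table(taxon_tables, proxy = config$proxy,
                              pseudocount = config$pseudocount)
    written <- c(written, write_tsv(features, file.path(config$out_dir, "features.tsv")))
    results <- list(cohort = cohort, features = features,
                    flagged = fl$flagged, violations = violations)

    tp_order <- intersect(names(TP_AGE_DAYS),
                          union(unique(as.character(cohort$time_point)),
                                names(taxon_tables)))

    # ---- correlation screen ---------------------------------------------
    if ("screen" %in% config$stages) {
      outcome <- data.frame(subject_id = cohort$subject_id,
                            time_point = as.character(cohort$time_point),
                            value = cohort$zbmi, stringsAsFactors = FALSE)
      mk_pred <- function(col) data.frame(
        subject_id = features$subject_id, time_point = features$time_point,
        value = features[[col]], stringsAsFactors = FALSE)
      scr_fb <- correlation_matrix(mk_pred("fb_ratio"), outcome, tp_order)
      scr_scfa <- correlation_matrix(mk_pred("scfa_sum_clr"), outcome, tp_order)
      written <- c(written,
                   write_tsv(scr_fb, file.path(config$out_dir, "correlations_fb.tsv")),
                   write_tsv(scr_scfa, file.path(config$out_dir, "correlations_scfa.tsv")))
      results$screen <- list(fb = scr_fb, scfa = scr_scfa)
    }

    # ---- imputation + multilevel ----------------------------------------
    if ("multilevel" %in% config$stages) {
      ml <- config$multilevel
      exposure <- ml$exposure %||% "scfa_sum_clr"
      long <- lagged_dataset(cohort, features, exposure,
                             timepoint_order = tp_order,
                             subset = ml$subset %||% "all")
      std <- standardize(long, intersect(c(exposure, "birthweight"),
                                         names(long)))
      long <- std$data
      imp_cols <- c("zbmi", "zbmi_lag", "birthweight", exposure)
      spec <- model_spec(outcome = "zbmi", exposure = exposure,
                         covariates = c("zbmi_lag", "birthweight"),
                         prior_slope_sd = ml$prior_slope_sd %||%
                           (if (length(exposure) > 1) 0.25 else 0.5),
                         prior_sd_rate = ml$prior_sd_rate %||% 1)
      if (anyNA(long[, imp_cols])) {
        imp <- pmm_impute(long[, imp_cols], config$imputation)
        datasets <- lapply(imp$completed, function(d) {
          d[[spec$group]] <- long[[spec$group]]
          d
        })
        fit <- fit_across_imputations(datasets, spec,
                                      n_iter = ml$n_iter %||% 1500,
                                      n_chains = ml$n_chains %||% 2,
                                      seed = derive_seed(config$seed, 31))
      } else {
        fit <- fit_multilevel(long, spec, n_iter = ml$n_iter %||% 1500,
                              n_chains = ml$n_chains %||% 2,
                              seed = derive_seed(config$seed, 31))
      }
      summ <- posterior_summary(fit)
      written <- c(written, write_tsv(summ, file.path(config$out_dir,
                                                      "multilevel_summary.tsv")))
      results$multilevel <- list(fit = fit, summary = summ,
                                 scaling = std$scaling, data = long)
    }

    # ---- random forests --------------------------------------------------
    if ("rf" %in% config$stages) {
      rfc <- config$rf
      fam <- run_model_family(list(cohort = cohort, taxon_tables = taxon_tables),
                              B = rfc$B %||% 99, folds = rfc$folds %||% 4,
                              repeats = rfc$repeats %||% 5,
                              tune_budget = rfc$tune_budget %||% 10,
                              num_trees = rfc$num_trees %||% 200,
                              retune = rfc$retune %||% TRUE,
                              pseudocount = config$pseudocount,
                              seed = derive_seed(config$seed, 41),
                              timepoint_order = tp_order)
      written <- c(written, write_tsv(fam$report,
                                      file.path(config$out_dir, "rf_family.tsv")))
      if (length(fam$importances) > 0) {
        imp_df <- do.call(rbind, lapply(names(fam$importances), function(nm) {
          cbind(model = nm, fam$importances[[nm]])
        }))
        written <- c(written, write_tsv(imp_df,
                                        file.path(config$out_dir, "rf_importances.tsv")))
      }
      results$rf <- fam
    }

    # ---- manifest --------------------------------------------------------
    manifest <- list(
      package_version = as.character(utils::packageVersion("microgrowth")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      stages = config$stages,
      config_hash = digest_config(config),
      outputs = basename(written),
      n_validation_notes = length(violations)
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$manifest <- manifest
    invisible(results)
  }, error = on_fail)
}

# stable hash of the config (structure + values) for the run manifest
digest_config <- function(config) {
  s <- jsonlite::serializeJSON(config[setdiff(names(config), "out_dir")])
  # small rolling hash; enough to detect config drift in a manifest
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
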