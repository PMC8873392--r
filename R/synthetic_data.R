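# Synthetic longitudinal cohorts with the statistical structure the analysis
# assumes: Dirichlet-multinomial genus counts whose phylum balance shifts from
# an Actinobacteria(Bifidobacterium)-dominated infancy with near-absent
# Bacteroidetes to a Firmicutes-dominated childhood; autocorrelated zBMI
# trajectories with planted genus effects; MAR/MCAR missingness. Ground truth
# is retained so recovery and calibration tests can score themselves.

TP_AGE_DAYS <- c("1m" = 30, "3m" = 91, "4m" = 122, "2y" = 730, "6y" = 2190,
                 "7y" = 2555, "10y" = 3650, "12y" = 4380)
TP_AGE_JITTER <- c("1m" = 3, "3m" = 10, "4m" = 11, "2y" = 90, "6y" = 85,
                   "7y" = 65, "10y" = 105, "12y" = 105)

#' Default genus catalogue for simulation
#'
#' 30 genera over five phyla, including all 17 curated SCFA producers plus
#' common non-producer gut genera, so proxy aggregation, phylum ratios and
#' genus-level models are all exercised.
#'
#' @return data.frame with columns `genus`, `phylum`.
#' @export
default_genus_catalog <- function() {
  prox <- scfa_producers()[, c("genus", "phylum")]
  extra <- data.frame(
    genus = c("Collinsella", "Eggerthella",
              "Parabacteroides",
              "Lactobacillus", "Streptococcus", "Clostridium sensu stricto 1",
              "Ruminococcus 2", "Veillonella", "Enterococcus",
              "Lachnoclostridium", "Ruminococcaceae UCG-002",
              "Escherichia-Shigella", "Klebsiella"),
    phylum = c("Actinobacteria", "Actinobacteria",
               "Bacteroidetes",
               rep("Firmicutes", 8),
               "Proteobacteria", "Proteobacteria"),
    stringsAsFactors = FALSE
  )
  rbind(prox, extra)
}

#' Default Dirichlet concentration profiles per stool time point
#'
#' Concentrations are calibrated so expected phylum relative abundances track
#' the descriptive course of a western infant cohort: Firmicutes rising from
#' roughly 0.27 at 1 month to 0.72 at 10 years, Bacteroidetes from ~0.01 in
#' infancy to ~0.11-0.18 in childhood, Actinobacteria (Bifidobacterium)
#' dominating infancy. Total concentration is small in infancy (strong
#' overdispersion, frequent structural zeros for Bacteroidetes, so the F/B
#' ratio is often undefined there) and larger in childhood.
#'
#' @param catalog genus catalogue as from [default_genus_catalog()].
#' @return matrix, time points x genera, strictly positive.
#' @export
default_composition_profiles <- function(catalog = default_genus_catalog()) {
  # target expected phylum shares per stool time point
  targets <- rbind(
    "1m"  = c(Actinobacteria = 0.55, Bacteroidetes = 0.010, Firmicutes = 0.27,
              Proteobacteria = 0.15, Verrucomicrobia = 0.02),
    "3m"  = c(Actinobacteria = 0.60, Bacteroidetes = 0.010, Firmicutes = 0.21,
              Proteobacteria = 0.16, Verrucomicrobia = 0.02),
    "4m"  = c(Actinobacteria = 0.65, Bacteroidetes = 0.010, Firmicutes = 0.19,
              Proteobacteria = 0.13, Verrucomicrobia = 0.02),
    "6y"  = c(Actinobacteria = 0.12, Bacteroidetes = 0.180, Firmicutes = 0.63,
              Proteobacteria = 0.04, Verrucomicrobia = 0.03),
    "10y" = c(Actinobacteria = 0.10, Bacteroidetes = 0.110, Firmicutes = 0.72,
              Proteobacteria = 0.04, Verrucomicrobia = 0.03)
  )
  total_conc <- c("1m" = 6, "3m" = 6, "4m" = 6, "6y" = 25, "10y" = 25)
  # within-phylum weights: Bifidobacterium carries most of Actinobacteria in
  # infancy; Firmicutes spread over its genera with mild unevenness
  prof <- matrix(0, nrow(targets), nrow(catalog),
                 dimnames = list(rownames(targets), catalog$genus))
  for (tp in rownames(targets)) {
    infant <- tp %in% c("1m", "3m", "4m")
    for (ph in colnames(targets)) {
      g <- catalog$genus[catalog$phylum == ph]
      w <- rep(1, length(g))
      names(w) <- g
      if (ph == "Actinobacteria") w[] <- c(8, 1, 1)[seq_along(g)]
      if (ph == "Firmicutes" && !infant) {
        # childhood: butyrate producers prominent
        w[g %in% c("Faecalibacterium", "Blautia", "Subdoligranulum",
                   "Eubacterium rectale group")] <- 3
      }
      if (ph == "Firmicutes" && infant) {
        w[g %in% c("Veillonella", "Streptococcus", "Lactobacillus",
                   "Enterococcus")] <- 4
      }
      if (ph == "Bacteroidetes") w[g == "Bacteroides"] <- 2
      prof[tp, g] <- targets[tp, ph] * w / sum(w) * total_conc[tp]
    }
  }
  stopifnot(all(prof > 0))
  prof
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults are the study conditions all shipped analyses assume: 200
#' subjects, five stool and eight anthropometry time points over the first
#' twelve years, mean library size 20,000 reads, a null effect vector, zBMI
#' autocorrelation 0.45, subject-intercept SD 0.3, residual SD 0.8, and 10%
#' missingness (MAR on zBMI for anthropometry, MCAR for stool samples).
#'
#' @param n_subjects number of children.
#' @param stool_timepoints,anthro_timepoints ordered labels; every stool time
#'   point must also be an anthropometry time point (zBMI(T-1) is needed at
#'   the stool visit).
#' @param genus_catalog data.frame `genus`, `phylum`.
#' @param composition_profiles matrix time points x genera of strictly
#'   positive Dirichlet concentrations.
#' @param library_size mean sequencing depth (log-normal across samples).
#' @param library_size_sdlog log-scale SD of the depth distribution.
#' @param effect_vector named per-genus linear effect of CLR abundance at the
#'   previous stool time point on zBMI at the next anthropometry time point
#'   (standardized scale); genera not named get 0.
#' @param effect_timepoints stool time points at which the effects act
#'   (default all); restrict to plant a signal at a single exposure-outcome
#'   pair.
#' @param zbmi_ar autoregressive coefficient of the zBMI trajectory, |ar| < 1.
#' @param birthweight_effect standardized birthweight slope on zBMI.
#' @param subject_intercept_sd SD of per-subject zBMI intercepts.
#' @param noise_sd residual SD of zBMI.
#' @param missing_rate_stool,missing_rate_anthro probabilities in [0, 1).
#' @param seed master RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 200,
                              stool_timepoints = c("1m", "3m", "4m", "6y", "10y"),
                              anthro_timepoints = c("1m", "3m", "4m", "2y",
                                                    "6y", "7y", "10y", "12y"),
                              genus_catalog = default_genus_catalog(),
                              composition_profiles =
                                default_composition_profiles(genus_catalog),
                              library_size = 20000,
                              library_size_sdlog = 0.4,
                              effect_vector = NULL,
                              effect_timepoints = NULL,
                              zbmi_ar = 0.45,
                              birthweight_effect = 0.1,
                              subject_intercept_sd = 0.3,
                              noise_sd = 0.8,
                              missing_rate_stool = 0.1,
                              missing_rate_anthro = 0.1,
                              seed = 1L) {
  stop_if(n_subjects < 2, "need at least 2 subjects")
  stop_if(!all(stool_timepoints %in% anthro_timepoints),
          "every stool time point needs a matching anthropometry time point")
  stop_if(!all(anthro_timepoints %in% names(TP_AGE_DAYS)),
          "unknown time point label(s): %s",
          paste(setdiff(anthro_timepoints, names(TP_AGE_DAYS)), collapse = ", "))
  stop_if(nrow(composition_profiles) != length(stool_timepoints) &&
            !all(stool_timepoints %in% rownames(composition_profiles)),
          "composition_profiles must cover every stool time point")
  if (!is.null(rownames(composition_profiles)))
    composition_profiles <- composition_profiles[stool_timepoints, , drop = FALSE]
  stop_if(ncol(composition_profiles) != nrow(genus_catalog),
          "composition_profiles columns (%d) must match catalogue size (%d)",
          ncol(composition_profiles), nrow(genus_catalog))
  stop_if(any(composition_profiles <= 0), "concentrations must be strictly positive")
  stop_if(library_size < 100, "library_size must be >= 100")
  stop_if(abs(zbmi_ar) >= 1, "|zbmi_ar| must be < 1")
  stop_if(missing_rate_stool < 0 || missing_rate_stool >= 1 ||
            missing_rate_anthro < 0 || missing_rate_anthro >= 1,
          "missing rates must lie in [0, 1)")
  ev <- stats::setNames(rep(0, nrow(genus_catalog)), genus_catalog$genus)
  if (!is.null(effect_vector)) {
    stop_if(is.null(names(effect_vector)), "effect_vector must be named by genus")
    unknown <- setdiff(names(effect_vector), genus_catalog$genus)
    stop_if(length(unknown) > 0, "effect_vector names not in catalogue: %s",
            paste(unknown, collapse = ", "))
    ev[names(effect_vector)] <- effect_vector
  }
  if (is.null(effect_timepoints)) effect_timepoints <- stool_timepoints
  stop_if(!all(effect_timepoints %in% stool_timepoints),
          "effect_timepoints must be stool time points")
  structure(list(
    n_subjects = as.integer(n_subjects),
    stool_timepoints = stool_timepoints,
    anthro_timepoints = anthro_timepoints,
    genus_catalog = genus_catalog,
    composition_profiles = composition_profiles,
    library_size = library_size,
    library_size_sdlog = library_size_sdlog,
    effect_vector = ev,
    effect_timepoints = effect_timepoints,
    zbmi_ar = zbmi_ar,
    birthweight_effect = birthweight_effect,
    subject_intercept_sd = subject_intercept_sd,
    noise_sd = noise_sd,
    missing_rate_stool = missing_rate_stool,
    missing_rate_anthro = missing_rate_anthro,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# synthetic length-for-age (cm); smooth, not a population standard
length_for_age <- function(age_days, height_factor = 1) {
  (50 + 45 * (1 - exp(-age_days / 550)) + 0.0205 * age_days) * height_factor
}

#' Simulate a longitudinal cohort
#'
#' Draws genus counts per stool sample from a Dirichlet-multinomial with the
#' time point's concentration vector; generates zBMI trajectories as
#' `zBMI(T) = ar * zBMI(T-1) + sum_g effect[g] * CLR_g(T-1) + bw_effect *
#' birthweight_z + subject intercept + noise`, where the exposure term enters
#' only at anthropometry time points whose predecessor is a stool time point;
#' inverts z-scores through a synthetic LMS reference to produce weight and
#' length; applies MAR/MCAR missingness at the configured rates. Everything
#' is reproducible from `config$seed`, and the pre-missingness tables plus
#' all latent quantities are retained in `$truth`.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_cohort`: list with `cohort`
#'   (long-format anthropometry data.frame incl. `zbmi`), `taxon_tables`
#'   (named list of [taxon_table()], one per stool time point), `reference`
#'   (the [growth_reference()] used), `truth` (effect vector, random
#'   intercepts, true compositions and CLR matrices, complete tables) and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stop_if(!inherits(config, "simulation_config"), "config must be a simulation_config")
  set.seed(derive_seed(config$seed, 1))
  n <- config$n_subjects
  subjects <- sprintf("S%03d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.47, 0.53))
  birthweight_g <- stats::rnorm(n, 3613, 477)
  bw_z <- as.numeric(scale(birthweight_g))
  u0 <- stats::rnorm(n, 0, config$subject_intercept_sd)
  height_factor <- stats::rnorm(n, 1, 0.03)
  reference <- synthetic_growth_reference()

  # true compositions and counts per stool time point
  genera <- config$genus_catalog$genus
  true_comp <- list(); counts <- list(); clr_true <- list()
  for (tp in config$stool_timepoints) {
    p <- rdirichlet(n, config$composition_profiles[tp, ])
    colnames(p) <- genera
    rownames(p) <- paste(subjects, tp, sep = "_")
    depth <- pmax(100, round(stats::rlnorm(
      n, log(config$library_size) - config$library_size_sdlog^2 / 2,
      config$library_size_sdlog)))
    cnt <- t(vapply(seq_len(n),
                    function(i) stats::rmultinom(1, depth[i], p[i, ])[, 1],
                    numeric(length(genera))))
    dimnames(cnt) <- dimnames(p)
    true_comp[[tp]] <- p
    counts[[tp]] <- cnt
    # Effects enter via the CLR of the *true* composition, expressed at the
    # analysis's detection scale: expected counts at the mean library size
    # with the analysis pseudocount. A raw-proportion CLR would let
    # essentially-absent taxa (true share ~ 1e-30) dominate through log
    # magnitudes no count table can resolve.
    clr_true[[tp]] <- clr(p * config$library_size, pseudocount = 0.5)
  }

  # zBMI trajectories over anthropometry time points
  tps <- config$anthro_timepoints
  z <- matrix(NA_real_, n, length(tps), dimnames = list(subjects, tps))
  for (k in seq_along(tps)) {
    mu <- u0 + config$birthweight_effect * bw_z
    if (k > 1) {
      prev <- tps[k - 1]
      mu <- mu + config$zbmi_ar * z[, prev]
      if (prev %in% config$effect_timepoints &&
          any(config$effect_vector != 0)) {
        mu <- mu + clr_true[[prev]] %*% config$effect_vector
      }
    }
    z[, k] <- mu + stats::rnorm(n, 0, config$noise_sd)
  }

  # anthropometry records via LMS inversion
  age <- outer(rep(1, n), TP_AGE_DAYS[tps]) +
    matrix(stats::rnorm(n * length(tps), 0, TP_AGE_JITTER[tps][col(z)]),
           n, length(tps))
  age <- pmin(pmax(age, 1), max(reference$age_days) - 10)  # stay scoreable
  for (k in seq_along(tps)[-1])  # visits are ordered occasions per child
    age[, k] <- pmax(age[, k], age[, k - 1] + 1)
  cohort <- do.call(rbind, lapply(seq_along(tps), function(k) {
    a <- age[, k]
    len <- length_for_age(a, height_factor) * exp(stats::rnorm(n, 0, 0.005))
    bmi <- zbmi_to_bmi(z[, k], a, sex, reference)
    data.frame(subject_id = subjects, time_point = tps[k], age_days = a,
               sex = sex, weight_kg = bmi * (len / 100)^2, length_cm = len,
               birthweight_g = birthweight_g, zbmi = z[, k],
               stringsAsFactors = FALSE)
  }))
  cohort$time_point <- factor(cohort$time_point, levels = tps)
  cohort <- cohort[order(cohort$subject_id, cohort$time_point), ]
  rownames(cohort) <- NULL

  taxon_tables <- lapply(config$stool_timepoints, function(tp)
    taxon_table(counts[[tp]], config$genus_catalog))
  names(taxon_tables) <- config$stool_timepoints

  out <- structure(list(
    cohort = cohort,
    taxon_tables = taxon_tables,
    reference = reference,
    truth = list(effect_vector = config$effect_vector,
                 subject_intercepts = stats::setNames(u0, subjects),
                 birthweight_z = stats::setNames(bw_z, subjects),
                 zbmi = z,
                 true_composition = true_comp,
                 clr_true = clr_true,
                 cohort_complete = cohort,
                 taxon_tables_complete = taxon_tables),
    config = config
  ), class = "synthetic_cohort")

  if (config$missing_rate_stool > 0 || config$missing_rate_anthro > 0) {
    out <- apply_missingness(
      out, rates = list(stool = config$missing_rate_stool,
                        anthro = config$missing_rate_anthro),
      mechanism = "MAR-zbmi", seed = derive_seed(config$seed, 2))
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d anthropometry rows, %d stool time points\n",
              length(unique(x$cohort$subject_id)), nrow(x$cohort),
              length(x$taxon_tables)))
  invisible(x)
}

#' Mask cells missing-at-random or completely at random
#'
#' Anthropometry missingness removes the weight/length/zBMI triplet of a
#' (subject, time point) visit; stool missingness drops whole samples from
#' the taxon tables. Under `"MAR-zbmi"` the masking probability increases
#' with the (true) zBMI of the visit via a logistic model whose intercept is
#' calibrated so the average rate matches the request; `"MCAR"` masks
#' uniformly. Originals are kept in `$truth` so imputation quality can be
#' scored.
#'
#' @param sc a `synthetic_cohort`.
#' @param rates list with elements `stool` and `anthro`, each in [0, 1).
#' @param mechanism `"MCAR"` or `"MAR-zbmi"`.
#' @param seed RNG seed.
#' @return the cohort with masked cells set `NA` / samples dropped.
#' @export
apply_missingness <- function(sc, rates, mechanism = c("MAR-zbmi", "MCAR"),
                              seed = 1L) {
  mechanism <- match.arg(mechanism)
  r_stool <- rates$stool %||% 0
  r_anthro <- rates$anthro %||% 0
  stop_if(r_stool < 0 || r_stool >= 1 || r_anthro < 0 || r_anthro >= 1,
          "rates must lie in [0, 1)")
  set.seed(seed)
  cohort <- sc$truth$cohort_complete
  z <- cohort$zbmi
  mask_prob <- function(rate) {
    if (rate == 0) return(rep(0, length(z)))
    if (mechanism == "MCAR") return(rep(rate, length(z)))
    # calibrate logistic intercept so mean probability == rate
    a <- stats::uniroot(function(a) mean(stats::plogis(a + z)) - rate,
                        c(-20, 20))$root
    stats::plogis(a + z)
  }
  if (r_anthro > 0) {
    drop <- stats::runif(nrow(cohort)) < mask_prob(r_anthro)
    cohort[drop, c("weight_kg", "length_cm", "zbmi")] <- NA
  }
  taxon_tables <- sc$truth$taxon_tables_complete
  if (r_stool > 0) {
    for (tp in names(taxon_tables)) {
      zi <- cohort$zbmi[match(
        paste(rownames(taxon_tables[[tp]]$counts)),
        paste(cohort$subject_id, cohort$time_point, sep = "_"))]
      p <- if (mechanism == "MCAR" || all(is.na(zi))) {
        rep(r_stool, nrow(taxon_tables[[tp]]$counts))
      } else {
        zz <- ifelse(is.na(zi), mean(zi, na.rm = TRUE), zi)
        a <- stats::uniroot(function(a) mean(stats::plogis(a + zz)) - r_stool,
                            c(-20, 20))$root
        stats::plogis(a + zz)
      }
      keep <- stats::runif(length(p)) >= p
      taxon_tables[[tp]] <- taxon_table(
        taxon_tables[[tp]]$counts[keep, , drop = FALSE],
        taxon_tables[[tp]]$taxonomy)
    }
  }
  sc$cohort <- cohort
  sc$taxon_tables <- taxon_tables
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
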