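# Shared setup for the analysis drivers: one master seed, one cohort
# configuration, one output root. Every driver reconstructs the cohort
# deterministically from the seed, so the scripts can be run independently
# or in sequence.

library(microgrowth)

MASTER_SEED <- 20260101
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Study conditions: 200 children, five stool / eight anthropometry time
# points, 10% missingness (MAR on zBMI for visits, MCAR-calibrated logistic
# for stool), and a modest planted negative effect of Subdoligranulum on
# next-time-point zBMI so the exploratory stages have something to find.
cohort_config <- function(seed = MASTER_SEED) {
  simulation_config(
    n_subjects = 200,
    effect_vector = c(Subdoligranulum = -0.4),
    seed = seed
  )
}

load_cohort <- function(seed = MASTER_SEED) simulate_cohort(cohort_config(seed))
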