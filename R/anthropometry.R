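# Sex/age-standardized BMI via the LMS method, plus the outlier rule used
# before modelling.

#' Construct a growth reference
#'
#' An LMS growth reference tabulates, per sex and age in days, the Box-Cox
#' power (L), the median BMI (M, kg/m^2) and the coefficient of variation
#' (S). z-scores are computed with L, M and S linearly interpolated at the
#' child's exact age; no extrapolation beyond the tabulated span.
#'
#' @param df data.frame with columns `sex` (`"F"`/`"M"`), `age_days`, `L`,
#'   `M`, `S`.
#' @return object of class `growth_reference`.
#' @export
growth_reference <- function(df) {
  need <- c("sex", "age_days", "L", "M", "S")
  stop_if(!all(need %in% names(df)), "reference needs columns %s",
          paste(need, collapse = ", "))
  stop_if(any(df$M <= 0) || any(df$S <= 0), "M and S must be positive")
  df <- df[order(df$sex, df$age_days), need]
  for (s in unique(df$sex)) {
    a <- df$age_days[df$sex == s]
    stop_if(any(diff(a) <= 0), "ages must be strictly increasing within sex %s", s)
  }
  structure(df, class = c("growth_reference", "data.frame"))
}

#' @rdname growth_reference
#' @param path CSV with header `sex,age_days,L,M,S`.
#' @export
read_growth_reference <- function(path) {
  growth_reference(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Synthetic LMS reference grid
#'
#' A smooth, internally consistent LMS grid spanning birth to 13 years, used
#' by the test-suite and the synthetic-cohort generator so that no external
#' reference download is required. Real WHO-style tables in the same CSV
#' layout drop in unchanged. The shapes are loosely child-like (BMI median
#' rising in infancy, dipping in mid-childhood, rising again) but the grid is
#' synthetic and carries no population meaning.
#'
#' @param by grid spacing in days.
#' @return a [growth_reference()].
#' @export
synthetic_growth_reference <- function(by = 30) {
  age <- seq(0, 4800, by = by)
  grid <- do.call(rbind, lapply(c("F", "M"), function(s) {
    off <- if (s == "M") 0.25 else 0
    # median BMI: infancy peak ~ 17 around 8 months, dip ~15.3 near 5-6y
    m <- 13.4 + off + 3.6 * exp(-((age - 240) / 400)^2) +
      2.2 * pmax(0, (age - 2000)) / 2800
    l <- -0.2 - 0.8 * pmin(1, age / 2500)          # mild, age-varying skewness
    scv <- 0.082 + 0.035 * pmin(1, age / 4000)     # CV grows with age
    data.frame(sex = s, age_days = age, L = l, M = m, S = scv)
  }))
  growth_reference(grid)
}

# interpolate L, M, S at exact ages for one sex
lms_at <- function(ref, sex, age_days) {
  sub <- ref[ref$sex == sex, ]
  stop_if(nrow(sub) == 0, "sex '%s' not in reference", sex)
  rng <- range(sub$age_days)
  out <- age_days < rng[1] | age_days > rng[2]
  stop_if(any(out), "age(s) outside reference span [%g, %g]: %s",
          rng[1], rng[2], paste(age_days[out], collapse = ", "))
  list(L = stats::approx(sub$age_days, sub$L, xout = age_days)$y,
       M = stats::approx(sub$age_days, sub$M, xout = age_days)$y,
       S = stats::approx(sub$age_days, sub$S, xout = age_days)$y)
}

#' BMI-for-age z-score (LMS method)
#'
#' `BMI = weight / (length/100)^2`; the z-score is
#' `((BMI/M)^L - 1) / (L * S)`, or `log(BMI/M) / S` when `L = 0`, with L, M,
#' S linearly interpolated at the child's age within sex. A z of +3
#' corresponds to the 99.865th percentile, -3 to the 0.135th.
#'
#' @param weight_kg,length_cm,age_days,sex vectors (recycled to common
#'   length); `sex` coded as in the reference.
#' @param reference a [growth_reference()].
#' @return numeric vector of z-scores.
#' @export
zbmi <- function(weight_kg, length_cm, age_days, sex, reference) {
  n <- max(length(weight_kg), length(length_cm), length(age_days), length(sex))
  weight_kg <- rep_len(weight_kg, n); length_cm <- rep_len(length_cm, n)
  age_days <- rep_len(age_days, n); sex <- rep_len(as.character(sex), n)
  stop_if(any(weight_kg <= 0, na.rm = TRUE) || any(length_cm <= 0, na.rm = TRUE),
          "weight and length must be positive")
  bmi <- weight_kg / (length_cm / 100)^2
  z <- rep(NA_real_, n)
  ok <- !is.na(bmi) & !is.na(age_days) & !is.na(sex)
  for (s in unique(sex[ok])) {
    i <- ok & sex == s
    p <- lms_at(reference, s, age_days[i])
    r <- bmi[i] / p$M
    z[i] <- ifelse(p$L == 0, log(r) / p$S, (r^p$L - 1) / (p$L * p$S))
  }
  z
}

#' Invert a z-score back to BMI
#'
#' `BMI = M * (1 + L*S*z)^(1/L)` (or `M * exp(S*z)` at `L = 0`); used for
#' round-trip checks and by the synthetic-cohort generator to turn latent
#' z-scores into weights.
#'
#' @inheritParams zbmi
#' @param z z-score vector.
#' @return BMI in kg/m^2.
#' @export
zbmi_to_bmi <- function(z, age_days, sex, reference) {
  n <- max(length(z), length(age_days), length(sex))
  z <- rep_len(z, n); age_days <- rep_len(age_days, n)
  sex <- rep_len(as.character(sex), n)
  bmi <- rep(NA_real_, n)
  ok <- !is.na(z)
  for (s in unique(sex[ok])) {
    i <- ok & sex == s
    p <- lms_at(reference, s, age_days[i])
    bmi[i] <- ifelse(p$L == 0, p$M * exp(p$S * z[i]),
                     p$M * (1 + p$L * p$S * z[i])^(1 / p$L))
  }
  bmi
}

#' Remove implausible z-scores
#'
#' Entry or measurement errors show up as zBMI far outside the reference
#' range; records with `|zbmi| > bound` are moved to a flagged set and
#' excluded from analysis, per observation (a child keeps their other time
#' points).
#'
#' @param records data.frame with a `zbmi` column.
#' @param bound absolute z cut-off (default 3).
#' @return list with elements `kept` and `flagged`.
#' @export
flag_outliers <- function(records, bound = 3) {
  stop_if(!"zbmi" %in% names(records), "records need a zbmi column")
  bad <- !is.na(records$zbmi) & abs(records$zbmi) > bound
  list(kept = records[!bad, , drop = FALSE],
       flagged = records[bad, , drop = FALSE])
}
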