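#' Average repeated anthropometric measures
#'
#' Height and weight are taken as the average of up to three separate
#' measures; missing measures are simply dropped.
#'
#' @param values numeric vector of up to 3 positive measurements (`NA`
#'   allowed and ignored).
#' @return the arithmetic mean, or `NA` if no measure is available.
#' @export
mean_measures <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (length(values) > 3) abort("at most 3 measures are expected")
  if (any(values <= 0)) abort("measures must be positive")
  mean(values)
}

#' Body mass index
#'
#' @param height_cm height in centimetres (> 0).
#' @param weight_kg weight in kilograms (> 0).
#' @return BMI in kg/m^2; `NA` inputs give `NA`.
#' @export
bmi <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    abort("height and weight must be positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' Load an LMS growth-reference table
#'
#' Reads a CSV in the CDC file dialect (columns sex, agemos, L, M, S; sex
#' coded M/F or 1/2). Without a path, the synthetic reference bundled with
#' the package (CDC-like magnitudes, 102-138 months) is used; point `path`
#' at a real CDC BMI-for-age file for production use.
#'
#' @param path optional CSV path.
#' @return tibble with columns sex, agemos, L, M, S.
#' @export
load_lms_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "synthetic_lms_reference.csv",
                                package = "pubsync", mustWork = TRUE)
  ref <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  names(ref) <- tolower(names(ref))
  need <- c("sex", "agemos", "l", "m", "s")
  if (!all(need %in% names(ref))) {
    abort("LMS reference must have columns sex, agemos, L, M, S")
  }
  ref$sex <- dplyr::case_when(ref$sex %in% c("1", "M", "m") ~ "M",
                              ref$sex %in% c("2", "F", "f") ~ "F")
  if (any(ref$m <= 0) || any(ref$s <= 0)) abort("LMS reference needs M > 0, S > 0")
  tibble::tibble(sex = ref$sex, agemos = as.numeric(ref$agemos),
                 L = as.numeric(ref$l), M = as.numeric(ref$m),
                 S = as.numeric(ref$s))
}

# nearest half-month reference row per (sex, age); errors outside the table
lms_lookup <- function(ref, sex, age_months) {
  lo <- min(ref$agemos); hi <- max(ref$agemos)
  if (anyNA(age_months) ||
      any(age_months < lo - 0.25) || any(age_months > hi + 0.25)) {
    abort(paste0("age (months) outside LMS reference range [", lo, ", ", hi, "]"))
  }
  near <- pmin(pmax(round(age_months * 2) / 2, lo), hi)
  idx <- match(paste(sex, near), paste(ref$sex, ref$agemos))
  if (anyNA(idx)) abort("no LMS reference row for some (sex, age) pairs")
  ref[idx, ]
}

#' LMS z-score
#'
#' Converts a measurement to an age- and sex-specific z-score under the LMS
#' (skewness L, median M, coefficient of variation S) transformation:
#' z = ((x/M)^L - 1) / (L S) for L != 0, and z = ln(x/M) / S for L = 0.
#'
#' @param x measurement (> 0), e.g. BMI in kg/m^2.
#' @param l,m,s LMS parameters (vectorized).
#' @return z-score.
#' @export
lms_zscore <- function(x, l, m, s) {
  if (any(x <= 0, na.rm = TRUE)) abort("LMS measurement must be positive")
  ifelse(abs(l) < 1e-12, log(x / m) / s, ((x / m)^l - 1) / (l * s))
}

#' Inverse LMS transform
#'
#' Returns the measurement at a given z-score: x = M (1 + L S z)^(1/L), or
#' M exp(S z) for L = 0.
#'
#' @inheritParams lms_zscore
#' @param z z-score.
#' @export
lms_inverse <- function(z, l, m, s) {
  ifelse(abs(l) < 1e-12, m * exp(s * z), m * (1 + l * s * z)^(1 / l))
}

#' Weight-status category from a BMI z-score
#'
#' Percentile is the standard-normal CDF of z. Cut-offs: underweight below
#' the 5th percentile; healthy 5th to below the 85th; overweight 85th to
#' below the 95th; obese at or above the 95th.
#'
#' @param z BMI z-score.
#' @return ordered factor underweight < healthy < overweight < obese.
#' @export
weight_status <- function(z) {
  # compare on the z scale so the percentile boundaries are exact
  cuts <- qnorm(c(0.05, 0.85, 0.95))
  out <- dplyr::case_when(
    z < cuts[1] ~ "underweight",
    z < cuts[2] ~ "healthy",
    z < cuts[3] ~ "overweight",
    TRUE ~ "obese"
  )
  factor(out, levels = c("underweight", "healthy", "overweight", "obese"),
         ordered = TRUE)
}

#' Append BMI, BMIz and weight status to a cohort table
#'
#' Averages the repeated height/weight measures (`height1..3`, `weight1..3`),
#' computes BMI, the LMS-based z-score and percentile at the child's age and
#' sex, and the weight-status category.
#'
#' @param cohort cohort tibble with child_id, sex, age_months and measure
#'   columns.
#' @param ref LMS reference from [load_lms_reference()].
#' @return the cohort with columns bmi, bmiz, bmi_percentile, weight_status
#'   appended.
#' @export
add_anthropometrics <- function(cohort, ref = load_lms_reference()) {
  hm <- as.matrix(cohort[paste0("height", 1:3)])
  wm <- as.matrix(cohort[paste0("weight", 1:3)])
  height <- rowMeans(hm, na.rm = TRUE)
  weight <- rowMeans(wm, na.rm = TRUE)
  height[is.nan(height)] <- NA; weight[is.nan(weight)] <- NA
  b <- bmi(height, weight)
  rows <- lms_lookup(ref, cohort$sex, cohort$age_months)
  z <- lms_zscore(b, rows$L, rows$M, rows$S)
  dplyr::mutate(cohort, bmi = b, bmiz = z, bmi_percentile = pnorm(z),
                weight_status = weight_status(z))
}
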