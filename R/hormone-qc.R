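#' Salivary immunoassay specifications
#'
#' Default Salimetrics specifications for the three salivary hormones:
#' calibrator ranges 6.1-600 pg/ml (testosterone), 10.2-1,000 pg/ml (DHEA),
#' 1-32 pg/ml (estradiol) and lower limits of sensitivity 1, 5 and
#' 0.1 pg/ml respectively. Estradiol is assayed in females only.
#'
#' @param overrides optional named list of rows to replace, each a list with
#'   `lower_limit`, `calibrator_low`, `calibrator_high`.
#' @return tibble: analyte, lower_limit, calibrator_low, calibrator_high, sexes.
#' @export
assay_specs <- function(overrides = NULL) {
  spec <- tibble::tribble(
    ~analyte,       ~lower_limit, ~calibrator_low, ~calibrator_high, ~sexes,
    "testosterone", 1,            6.1,             600,              "MF",
    "dhea",         5,            10.2,            1000,             "MF",
    "estradiol",    0.1,          1,               32,               "F"
  )
  for (nm in names(overrides)) {
    i <- match(nm, spec$analyte)
    if (is.na(i)) abort(paste0("unknown analyte in overrides: ", nm))
    for (f in names(overrides[[nm]])) spec[[f]][i] <- overrides[[nm]][[f]]
  }
  bad <- with(spec, !(lower_limit > 0 & lower_limit <= calibrator_low &
                        calibrator_low < calibrator_high))
  if (any(bad)) abort("assay spec must satisfy 0 < lower_limit <= calibrator_low < calibrator_high")
  spec
}

#' Session-level gates of the hormone QC decision tree
#'
#' A child's saliva session is usable only if, in order: (1) the sex
#' recorded at collection matches sex at birth, (2) a sample was collected,
#' and (3) the sample was processed. The first failed gate wins.
#'
#' @param recorded_sex,birth_sex sex codes at collection and at birth.
#' @param collected,processed logical flags.
#' @return character vector: `"pass"` or `"fail_sex_mismatch"`,
#'   `"fail_not_collected"`, `"fail_not_processed"`.
#' @export
session_gate <- function(recorded_sex, birth_sex, collected, processed) {
  dplyr::case_when(
    is.na(recorded_sex) | recorded_sex != birth_sex ~ "fail_sex_mismatch",
    !collected ~ "fail_not_collected",
    !processed ~ "fail_not_processed",
    TRUE ~ "pass"
  )
}

# parse a raw replicate entry: numeric string, below-limit token, or absent
parse_replicate <- function(x) {
  x <- as.character(x)
  low <- toupper(trimws(ifelse(is.na(x), "", x)))
  type <- dplyr::case_when(
    low == "" ~ "absent",
    low %in% c("BLQ", "NDS", "<LLOQ", "BELOW") ~ "below_limit",
    TRUE ~ "numeric"
  )
  val <- suppressWarnings(as.numeric(ifelse(type == "numeric", x, NA)))
  if (any(type == "numeric" & is.na(val))) {
    abort(paste0("unparseable replicate value(s): ",
                 paste(unique(x[type == "numeric" & is.na(val)]), collapse = ", ")))
  }
  if (any(val < 0, na.rm = TRUE)) abort("negative replicate value")
  list(type = type, value = val)
}

#' Validate one assay replicate
#'
#' A replicate is unusable if it is absent, coded below the detection limit,
#' numerically below the analyte's lower limit of sensitivity, or endorsed
#' as problematic by a research assistant. Values above the calibrator range
#' are retained but flagged `out_of_range_high`.
#'
#' @param rep raw replicate entries (numeric string, `"BLQ"`/`"NDS"`, or
#'   `NA`/`""` for absent).
#' @param ra_flag logical: RA endorsed the replicate as problematic.
#' @param spec one row of [assay_specs()].
#' @return tibble: value, valid, reason (`NA` when valid), out_of_range_high.
#' @export
replicate_valid <- function(rep, ra_flag, spec) {
  p <- parse_replicate(rep)
  ra_flag <- ifelse(is.na(ra_flag), FALSE, ra_flag)
  reason <- dplyr::case_when(
    p$type == "absent" ~ "absent",
    p$type == "below_limit" ~ "below_limit",
    ra_flag ~ "ra_flag",
    p$value < spec$lower_limit ~ "below_limit",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    value = ifelse(is.na(reason), p$value, NA_real_),
    valid = is.na(reason),
    reason = reason,
    out_of_range_high = is.na(reason) & p$value > spec$calibrator_high
  )
}

#' Session timing and behaviour covariates
#'
#' Emits the three minute-valued covariates used downstream of hormone
#' models: collection time (minutes since midnight of the start time),
#' collection duration (start to end), and time to freezer (end to freeze),
#' plus the caffeine and exercise flags.
#'
#' @param start,end,freeze clock times as `"HH:MM"` strings (`NA` allowed).
#' @param caffeine_12h,exercise_12h logical flags.
#' @return tibble: minutes_since_midnight, duration_min, to_freeze_min,
#'   caffeine_12h, exercise_12h.
#' @export
session_covariates <- function(start, end, freeze = NA_character_,
                               caffeine_12h = NA, exercise_12h = NA) {
  s <- parse_clock_minutes(start)
  e <- parse_clock_minutes(end)
  f <- parse_clock_minutes(freeze)
  if (any(e < s, na.rm = TRUE) || any(f < e, na.rm = TRUE)) {
    abort("collection times must satisfy start <= end <= freeze")
  }
  tibble::tibble(
    minutes_since_midnight = s,
    duration_min = e - s,
    to_freeze_min = f - e,
    caffeine_12h = caffeine_12h,
    exercise_12h = exercise_12h
  )
}

#' Finalize one hormone value from a duplicate-assayed session
#'
#' Implements the replicate step of the QC decision tree: both replicates
#' valid gives their arithmetic mean, exactly one valid gives that single
#' replicate, none gives a missing value. When two valid replicates disagree
#' by a coefficient of variation above `cv_warn`, the mean is kept and a
#' warning issued.
#'
#' @param rep1,rep2 raw replicate entries.
#' @param flag1,flag2 RA problem flags.
#' @param spec one row of [assay_specs()].
#' @param cv_warn CV threshold for the discordance warning (default 0.15).
#' @return tibble: value, provenance, out_of_range_high.
#' @export
finalize_hormone <- function(rep1, rep2, flag1, flag2, spec, cv_warn = 0.15) {
  r1 <- replicate_valid(rep1, flag1, spec)
  r2 <- replicate_valid(rep2, flag2, spec)
  both <- r1$valid & r2$valid
  one <- xor(r1$valid, r2$valid)
  value <- dplyr::case_when(
    both ~ (r1$value + r2$value) / 2,
    r1$valid ~ r1$value,
    r2$valid ~ r2$value,
    TRUE ~ NA_real_
  )
  if (any(both)) {
    m <- value[both]
    cv <- abs(r1$value[both] - r2$value[both]) / (sqrt(2) * m)
    if (any(cv > cv_warn)) {
      warn(paste0(sum(cv > cv_warn), " duplicate pair(s) with CV > ",
                  round(100 * cv_warn), "%; mean retained"))
    }
  }
  tibble::tibble(
    value = value,
    provenance = dplyr::case_when(
      both ~ "mean_of_two",
      one ~ "single_replicate",
      TRUE ~ "missing_all_replicates_invalid"
    ),
    out_of_range_high = (r1$out_of_range_high | r2$out_of_range_high) & !is.na(value)
  )
}

#' Run hormone quality control over a cohort table
#'
#' Applies the full decision tree per child and analyte: session gates
#' (sex-at-collection match, collected, processed), replicate validation
#' (below-limit and RA-flag exclusion), and final-value construction, plus
#' the session covariates. Estradiol rows are produced for females only.
#'
#' @param cohort cohort tibble with columns recorded_sex, collected,
#'   processed, `<analyte>_rep1/2`, `<analyte>_flag1/2`, collection_start,
#'   collection_end, freeze_time, caffeine_12h, exercise_12h.
#' @param specs [assay_specs()] table.
#' @param exclude_out_of_range_high if `TRUE`, values above the calibrator
#'   range are dropped instead of flagged.
#' @return tibble: child_id, sex, analyte, value, provenance,
#'   out_of_range_high, covariates.
#' @export
qc_hormones <- function(cohort, specs = assay_specs(),
                        exclude_out_of_range_high = FALSE) {
  if (any(cohort$sex == "M" & !is.na(cohort$estradiol_rep1) &
            cohort$estradiol_rep1 != "")) {
    abort("estradiol replicates present for male children; estradiol is assayed in females only")
  }
  gate <- session_gate(cohort$recorded_sex, cohort$sex,
                       cohort$collected, cohort$processed)
  cov <- session_covariates(cohort$collection_start, cohort$collection_end,
                            cohort$freeze_time, cohort$caffeine_12h,
                            cohort$exercise_12h)
  purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    keep <- if (spec$sexes == "F") cohort$sex == "F" else rep(TRUE, nrow(cohort))
    rows <- cohort[keep, ]
    fin <- finalize_hormone(rows[[paste0(spec$analyte, "_rep1")]],
                            rows[[paste0(spec$analyte, "_rep2")]],
                            rows[[paste0(spec$analyte, "_flag1")]],
                            rows[[paste0(spec$analyte, "_flag2")]],
                            spec)
    g <- gate[keep]
    value <- ifelse(g == "pass", fin$value, NA_real_)
    provenance <- dplyr::case_when(
      g == "fail_sex_mismatch" ~ "missing_sex_mismatch",
      g == "fail_not_collected" ~ "missing_not_collected",
      g == "fail_not_processed" ~ "missing_not_processed",
      TRUE ~ fin$provenance
    )
    oor <- fin$out_of_range_high & g == "pass"
    if (exclude_out_of_range_high) {
      provenance[oor & !is.na(value)] <- "missing_all_replicates_invalid"
      value[oor] <- NA_real_
      oor[] <- FALSE
    }
    tibble::tibble(child_id = rows$child_id, sex = rows$sex,
                   analyte = spec$analyte, value = value,
                   provenance = provenance, out_of_range_high = oor,
                   cov[keep, ])
  })
}
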