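#' Code a raw Pubertal Development Scale response
#'
#' Maps raw questionnaire tokens to the 1-4 ordinal codes. Responses left
#' blank, answered "I don't know", or "Refuse to answer" are treated as
#' missing; the subtype is recoverable with [pds_missing_subtype()].
#'
#' @param x character or numeric vector of raw responses. Recognised tokens:
#'   `"1"`-`"4"` (or numerics 1-4), `"I don't know"` / `"idk"`,
#'   `"Refuse to answer"` / `"refuse"`, `""` / `NA` (blank).
#' @return integer vector with `NA` for every missing subtype.
#' @examples
#' pds_code_item(c("3", "I don't know", NA))
#' @export
pds_code_item <- function(x) {
  sub <- pds_missing_subtype(x)
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  valid <- is.na(sub)
  num <- suppressWarnings(as.integer(x[valid]))
  if (anyNA(num) || any(!num %in% 1:4)) {
    bad <- unique(x[valid][is.na(num) | !num %in% 1:4])
    abort(paste0("unrecognized PDS response token(s): ",
                 paste(bad, collapse = ", ")))
  }
  out[valid] <- num
  out
}

#' Missing-response subtype of raw PDS tokens
#'
#' @inheritParams pds_code_item
#' @return character vector: `"blank"`, `"idk"`, `"refuse"`, or `NA` for a
#'   substantive response.
#' @export
pds_missing_subtype <- function(x) {
  x <- as.character(x)
  low <- tolower(trimws(x))
  dplyr::case_when(
    is.na(x) | low == "" | low == "blank" ~ "blank",
    low %in% c("i don't know", "i dont know", "idk", "don't know", "999") ~ "idk",
    low %in% c("refuse to answer", "refuse", "refused", "777") ~ "refuse",
    TRUE ~ NA_character_
  )
}

#' Code a menarche response for use inside PDS averages
#'
#' Menarche is a yes/no item; when it enters average scores it is coded
#' yes = 4, no = 1. Missing subtypes behave as for the ordinal items.
#'
#' @param x character vector: `"yes"`, `"no"`, or a missing token.
#' @return integer vector of 4 (yes), 1 (no) or `NA` (missing).
#' @export
pds_code_menarche <- function(x) {
  sub <- pds_missing_subtype(x)
  low <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  valid <- is.na(sub)
  bad <- valid & !low %in% c("yes", "no", "1", "4")
  if (any(bad)) {
    abort(paste0("unrecognized menarche token(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  out[valid] <- ifelse(low[valid] %in% c("yes", "4"), 4L, 1L)
  out
}

pds_item_names <- function(sex) {
  if (sex == "M") c("height", "body_hair", "skin", "facial_hair", "voice")
  else c("height", "body_hair", "skin", "breast")
}

#' Average PDS score for one respondent
#'
#' Mean of the five sex-appropriate items (for females the menarche item is
#' coded yes = 4 / no = 1 and counts as the fifth item). At most one item may
#' be missing, in which case the mean of the remaining four is used; with two
#' or more missing items the score is undefined.
#'
#' @param items named numeric vector of coded items (1-4, `NA` = missing).
#'   Males: height, body_hair, skin, facial_hair, voice. Females: height,
#'   body_hair, skin, breast.
#' @param sex `"M"` or `"F"`.
#' @param menarche coded menarche (4/1/`NA`), females only.
#' @return a list with `value` (numeric or `NA`), `n_missing`, and `reason`
#'   (`NA` or `"too_many_missing"`).
#' @export
pds_average <- function(items, sex, menarche = NULL) {
  nm <- pds_item_names(sex)
  vals <- unname(items[nm])
  if (sex == "F") vals <- c(vals, menarche %||% NA_integer_)
  n_missing <- sum(is.na(vals))
  if (n_missing > 1) {
    list(value = NA_real_, n_missing = n_missing, reason = "too_many_missing")
  } else {
    list(value = mean(vals, na.rm = TRUE), n_missing = n_missing,
         reason = NA_character_)
  }
}

#' Gonadal and adrenal PDS sub-scores
#'
#' Gonadal score: females average growth spurt (height), breast development
#' and menarche; males average growth spurt, voice deepening and facial hair.
#' Adrenal score: both sexes average body hair and skin changes. Either score
#' is undefined if any constituent item is missing.
#'
#' @inheritParams pds_average
#' @return numeric value or `NA`.
#' @export
pds_gonadal <- function(items, sex, menarche = NULL) {
  vals <- if (sex == "F") {
    c(items[["height"]], items[["breast"]], menarche %||% NA_integer_)
  } else {
    c(items[["height"]], items[["voice"]], items[["facial_hair"]])
  }
  if (anyNA(vals)) NA_real_ else mean(vals)
}

#' @rdname pds_gonadal
#' @export
pds_adrenal <- function(items, sex, menarche = NULL) {
  vals <- c(items[["body_hair"]], items[["skin"]])
  if (anyNA(vals)) NA_real_ else mean(vals)
}

#' Puberty category score
#'
#' Males: sum body hair + voice + facial hair (range 3-12) and classify:
#' prepubertal = 3; early = 4-5 with no 3-point response (a 3-point response
#' escalates to midpubertal); mid = 6-8 with no 4-point response (a 4-point
#' response escalates to late); late = 9-11; post = 12. Females: sum body
#' hair + breast (range 2-8); without menarche: prepubertal = 2, early = 3,
#' mid > 3; with menarche: late if the sum is at most 7, post if 8. Undefined
#' if any constituent (including menarche for females) is missing.
#'
#' All arguments are vectorized; `sex` recycles.
#'
#' @param sex `"M"`/`"F"` vector.
#' @param body_hair,voice,facial_hair,breast coded items (1-4 or `NA`).
#' @param menarche coded menarche (4 = yes, 1 = no, `NA` = missing).
#' @return tibble with columns `category` (ordered factor
#'   prepubertal < early < mid < late < post) and `category_sum` (integer).
#' @export
pds_category <- function(sex, body_hair, voice = NA_integer_,
                         facial_hair = NA_integer_, breast = NA_integer_,
                         menarche = NA_integer_) {
  n <- max(lengths(list(sex, body_hair, voice, facial_hair, breast, menarche)))
  sex <- rep_len(sex, n); body_hair <- rep_len(body_hair, n)
  voice <- rep_len(voice, n); facial_hair <- rep_len(facial_hair, n)
  breast <- rep_len(breast, n); menarche <- rep_len(menarche, n)

  male <- sex == "M"
  sum_m <- body_hair + voice + facial_hair
  any3 <- pmax(body_hair, voice, facial_hair) >= 3
  any4 <- pmax(body_hair, voice, facial_hair) >= 4
  cat_m <- dplyr::case_when(
    sum_m == 3 ~ "prepubertal",
    sum_m <= 5 & !any3 ~ "early",
    sum_m <= 5 & any3 ~ "mid",
    sum_m <= 8 & !any4 ~ "mid",
    sum_m <= 8 & any4 ~ "late",
    sum_m <= 11 ~ "late",
    sum_m == 12 ~ "post"
  )

  sum_f <- body_hair + breast
  men_yes <- menarche == 4L
  cat_f <- dplyr::case_when(
    is.na(menarche) | is.na(sum_f) ~ NA_character_,
    men_yes & sum_f == 8 ~ "post",
    men_yes ~ "late",
    sum_f == 2 ~ "prepubertal",
    sum_f == 3 ~ "early",
    sum_f > 3 ~ "mid"
  )

  category <- ifelse(male, cat_m, cat_f)
  category_sum <- ifelse(male, sum_m, sum_f)
  tibble::tibble(
    category = factor(category, levels = pds_category_levels, ordered = TRUE),
    category_sum = as.integer(category_sum)
  )
}

#' Score a cohort table for one reporter
#'
#' Computes, per child, the average PDS, gonadal, adrenal and category scores
#' with the standard missing-data rules. Expects the raw response columns of
#' [generate_cohort()]: `<prefix>_height`, `<prefix>_body_hair`,
#' `<prefix>_skin`, `<prefix>_facial_hair`, `<prefix>_voice`,
#' `<prefix>_breast`, `<prefix>_menarche` with prefix `cg` (caregiver) or
#' `y` (youth), plus `child_id` and `sex`.
#'
#' @param cohort a data frame of raw responses (one row per child).
#' @param reporter `"caregiver"` or `"youth"`.
#' @return tibble: child_id, reporter, sex, average_pds, gonadal, adrenal,
#'   category, category_sum, n_missing_items, undefined_reason.
#' @export
score_pds <- function(cohort, reporter = c("caregiver", "youth")) {
  reporter <- match.arg(reporter)
  prefix <- if (reporter == "caregiver") "cg" else "y"
  cols <- paste0(prefix, "_",
                 c("height", "body_hair", "skin", "facial_hair", "voice",
                   "breast", "menarche"))
  missing_cols <- setdiff(c("child_id", "sex", cols), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  item_of <- function(nm) pds_code_item(cohort[[paste0(prefix, "_", nm)]])
  coded <- list(
    height = item_of("height"), body_hair = item_of("body_hair"),
    skin = item_of("skin"), facial_hair = item_of("facial_hair"),
    voice = item_of("voice"), breast = item_of("breast")
  )
  menarche <- pds_code_menarche(cohort[[paste0(prefix, "_menarche")]])

  sex <- cohort$sex
  n <- nrow(cohort)
  avg <- gon <- adr <- rep(NA_real_, n)
  nmis <- integer(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    items <- vapply(coded, `[`, 1L, i)
    a <- pds_average(items, sex[i], menarche[i])
    avg[i] <- a$value; nmis[i] <- a$n_missing; reason[i] <- a$reason
    gon[i] <- pds_gonadal(items, sex[i], menarche[i])
    adr[i] <- pds_adrenal(items, sex[i], menarche[i])
  }
  cat <- pds_category(sex,
                      body_hair = coded$body_hair, voice = coded$voice,
                      facial_hair = coded$facial_hair, breast = coded$breast,
                      menarche = menarche)
  tibble::tibble(
    child_id = cohort$child_id, reporter = reporter, sex = sex,
    average_pds = avg, gonadal = gon, adrenal = adr,
    category = cat$category, category_sum = cat$category_sum,
    n_missing_items = nmis, undefined_reason = reason
  )
}
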