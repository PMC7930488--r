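#' Configuration for the synthetic ABCD-like cohort generator
#'
#' Defaults emulate the baseline structure of a large US 9-10 year-old
#' cohort: half female, ages 108-131 months, caregiver and youth PDS
#' responses generated from an ordinal-threshold model on a latent
#' maturation score, ~3% menarche prevalence among females, right-skewed
#' salivary hormones tied to maturation (plus a shared within-child hormone
#' latent giving the hormone block its own covariance), duplicate-assay
#' noise with lower-limit censoring, and realistic "I don't know"/refusal
#' missingness (much higher for youth, especially the height item).
#'
#' @param n_children cohort size.
#' @param sex_ratio fraction female in `[0, 1]`.
#' @param age_range age range in months, within `[108, 131]`.
#' @param category_probs named list of probability vectors: `race`
#'   (White/Black/Hispanic/Asian/Other), `income` (low/mid/high),
#'   `education` (5 levels).
#' @param effect_sizes linear coefficients on the latent maturation score:
#'   `age` (per month past 108), `female`, `bmiz`, plus named offset vectors
#'   `race` and `income`.
#' @param item_loadings per-item slopes of the item latent on maturation.
#' @param thresholds per-item ordinal cut-points (3 each).
#' @param menarche_intercept,menarche_slope logistic model of menarche on
#'   the maturation latent (calibrated to ~3% female prevalence).
#' @param hormone_params per-analyte list: `intercept` and `slope` on
#'   maturation and `shared` on the hormone latent (log pg/ml scale),
#'   residual log-scale `sd`, `duplicate_cv`, `lower_limit` (pg/ml).
#' @param missingness per-reporter named lists of "I don't know"
#'   probabilities per item, plus `refuse` rates.
#' @param youth_bias upward shift of youth item latents before thresholding.
#' @param session_rates rates of session defects: `sex_mismatch`,
#'   `not_collected`, `not_processed`, `ra_flag`, `rep_absent`, and
#'   behaviour flags `caffeine`, `exercise`.
#' @param seed integer RNG seed (single stream per cohort).
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(
    n_children = 4000,
    sex_ratio = 0.5,
    age_range = c(108, 131),
    category_probs = list(
      race = c(White = 0.52, Black = 0.15, Hispanic = 0.20,
               Asian = 0.02, Other = 0.11),
      income = c(low = 0.27, mid = 0.26, high = 0.47),
      education = c(less_hs = 0.05, hs_ged = 0.09, some_college = 0.26,
                    bachelor = 0.25, postgrad = 0.35)
    ),
    effect_sizes = list(
      age = 0.025, female = 0.7, bmiz = 0.25,
      race = c(White = 0, Black = 0.3, Hispanic = 0.05, Asian = -0.05,
               Other = 0.05),
      income = c(low = 0.15, mid = 0, high = -0.1)
    ),
    item_loadings = c(height = 0.5, body_hair = 0.85, skin = 0.7,
                      facial_hair = 0.7, voice = 0.7, breast = 0.95),
    thresholds = list(
      height = c(-0.5, 0.2, 2.2),
      body_hair = c(1.0, 1.9, 2.9),
      skin = c(1.1, 2.1, 3.1),
      facial_hair = c(1.8, 2.7, 3.4),
      voice = c(2.0, 2.9, 3.5),
      breast = c(0.6, 1.9, 3.3)
    ),
    menarche_intercept = -4.9,
    menarche_slope = 1.0,
    hormone_params = list(
      dhea = list(intercept = 3.70, slope = 0.20, shared = 0.68, sd = 0.24,
                  duplicate_cv = 0.05, lower_limit = 5),
      testosterone = list(intercept = 3.23, slope = 0.18, shared = 0.55,
                          sd = 0.22, duplicate_cv = 0.05, lower_limit = 1),
      estradiol = list(intercept = -0.13, slope = 0.15, shared = 0.42,
                       sd = 0.25, duplicate_cv = 0.05, lower_limit = 0.1)
    ),
    missingness = list(
      caregiver = list(idk = c(height = 0.04, body_hair = 0.03, skin = 0.02,
                               facial_hair = 0.01, voice = 0.01,
                               breast = 0.01, menarche = 0.01),
                       refuse = 0),
      youth = list(idk = c(height = 0.38, body_hair = 0.05, skin = 0.14,
                           facial_hair = 0.05, voice = 0.04, breast = 0.17,
                           menarche = 0.10),
                   refuse = 0.004)
    ),
    youth_bias = 0.3,
    session_rates = list(sex_mismatch = 0.005, not_collected = 0.05,
                         not_processed = 0.02, ra_flag = 0.01,
                         rep_absent = 0.02, caffeine = 0.07,
                         exercise = 0.13),
    seed = 1L) {
  cfg <- list(n_children = n_children, sex_ratio = sex_ratio,
              age_range = age_range, category_probs = category_probs,
              effect_sizes = effect_sizes, item_loadings = item_loadings,
              thresholds = thresholds,
              menarche_intercept = menarche_intercept,
              menarche_slope = menarche_slope,
              hormone_params = hormone_params, missingness = missingness,
              youth_bias = youth_bias, session_rates = session_rates,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_children < 0) abort("configuration error: `n_children` must be >= 0")
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    abort("configuration error: `sex_ratio` must be in [0, 1]")
  }
  if (cfg$age_range[1] < 108 || cfg$age_range[2] > 131 ||
        cfg$age_range[1] > cfg$age_range[2]) {
    abort("configuration error: `age_range` must lie within [108, 131] months")
  }
  for (nm in names(cfg$category_probs)) {
    assert_prob_vector(cfg$category_probs[[nm]],
                       paste0("category_probs$", nm))
  }
  for (h in names(cfg$hormone_params)) {
    p <- cfg$hormone_params[[h]]
    if (p$duplicate_cv < 0) {
      abort(paste0("configuration error: `hormone_params$", h,
                   "$duplicate_cv` must be >= 0"))
    }
    if (p$lower_limit <= 0) {
      abort(paste0("configuration error: `hormone_params$", h,
                   "$lower_limit` must be > 0"))
    }
  }
  invisible(cfg)
}

cohort_column_schema <- function() {
  c("child_id", "family_id", "site_id", "sex", "age_months",
    "race_ethnicity", "income_band", "education_band", "true_maturation",
    paste0("height", 1:3), paste0("weight", 1:3),
    paste0("cg_", c("height", "body_hair", "skin", "facial_hair", "voice",
                    "breast", "menarche")),
    paste0("y_", c("height", "body_hair", "skin", "facial_hair", "voice",
                   "breast", "menarche")),
    "menarche_age",
    as.vector(t(outer(c("dhea", "testosterone", "estradiol"),
                      c("_rep1", "_rep2", "_flag1", "_flag2"), paste0))),
    "recorded_sex", "collected", "processed",
    "collection_start", "collection_end", "freeze_time",
    "caffeine_12h", "exercise_12h")
}

# draw ordinal 1..4 codes from the threshold model, then overlay missingness
draw_item_tokens <- function(latent, cuts, idk_p, refuse_p, n) {
  code <- findInterval(latent, cuts) + 1L
  tok <- as.character(code)
  u <- runif(n)
  tok[u < idk_p] <- "I don't know"
  tok[u >= idk_p & u < idk_p + refuse_p] <- "Refuse to answer"
  tok
}

#' Generate a synthetic ABCD-like baseline cohort
#'
#' One row per child, with sociodemographics, repeated anthropometric
#' measures, caregiver and youth raw PDS responses (with explicit
#' "I don't know"/"Refuse to answer" tokens), menarche status and age,
#' duplicate salivary-assay replicates with RA flags and below-limit
#' censoring codes (`"BLQ"`), and saliva-session metadata. The latent
#' maturation score driving everything is returned in `true_maturation`.
#' Identical configurations (including seed) give identical tables.
#'
#' @param config a [cohort_config()].
#' @return tibble with the documented column schema.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_children
  empty <- tibble::as_tibble(setNames(
    purrr::map(cohort_column_schema(), ~ character(0)),
    cohort_column_schema()))
  if (n == 0) return(empty)
  set.seed(config$seed)

  sex <- ifelse(runif(n) < config$sex_ratio, "F", "M")
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  race <- sample(names(config$category_probs$race), n, replace = TRUE,
                 prob = config$category_probs$race)
  income <- sample(names(config$category_probs$income), n, replace = TRUE,
                   prob = config$category_probs$income)
  education <- sample(names(config$category_probs$education), n,
                      replace = TRUE, prob = config$category_probs$education)
  site <- sample.int(21, n, replace = TRUE)
  # a few sibling pairs share a family id
  family <- seq_len(n)
  n_tw <- floor(0.02 * n)
  if (n_tw >= 1) {
    pick <- sample.int(n, 2 * n_tw)
    family[pick[seq_len(n_tw) * 2]] <- family[pick[seq_len(n_tw) * 2 - 1]]
  }

  es <- config$effect_sizes
  bmiz <- rnorm(n)
  eta <- unname(es$age * (age - 108) + es$female * (sex == "F") +
                  es$bmiz * bmiz + es$race[race] + es$income[income] +
                  rnorm(n))

  # anthropometry: height from age/sex, weight from an LMS-style BMI
  ref <- load_lms_reference()
  rows <- lms_lookup(ref, sex, age)
  height_true <- 137 + 0.45 * (age - 120) - 1.0 * (sex == "M") + rnorm(n, 0, 6)
  bmi_true <- lms_inverse(bmiz, rows$L, rows$M, rows$S)
  weight_true <- bmi_true * (height_true / 100)^2
  hm <- purrr::map(1:3, ~ round(height_true + rnorm(n, 0, 0.4), 1))
  wm <- purrr::map(1:3, ~ round(weight_true + rnorm(n, 0, 0.2), 1))

  # PDS items, ordinal-threshold model; youth latents shifted upward
  items <- c("height", "body_hair", "skin", "facial_hair", "voice", "breast")
  male_items <- c("height", "body_hair", "skin", "facial_hair", "voice")
  female_items <- c("height", "body_hair", "skin", "breast")
  resp <- list()
  for (it in items) {
    lam <- config$item_loadings[[it]]
    base_latent <- lam * eta + rnorm(n)
    for (rep_nm in c("caregiver", "youth")) {
      shift <- if (rep_nm == "youth") config$youth_bias else 0
      mis <- config$missingness[[rep_nm]]
      tok <- draw_item_tokens(base_latent + shift +
                                if (rep_nm == "youth") rnorm(n, 0, 0.6) else 0,
                              config$thresholds[[it]],
                              mis$idk[[it]], mis$refuse, n)
      applicable <- if (it %in% c("facial_hair", "voice")) sex == "M"
                    else if (it == "breast") sex == "F"
                    else rep(TRUE, n)
      tok[!applicable] <- NA_character_
      prefix <- if (rep_nm == "caregiver") "cg" else "y"
      resp[[paste0(prefix, "_", it)]] <- tok
    }
  }

  # menarche (females): logistic on the maturation latent
  men_p <- plogis(config$menarche_intercept + config$menarche_slope * eta)
  men_yes <- runif(n) < men_p
  menarche_age <- ifelse(men_yes & sex == "F",
                         sample(c(8, 9, 10), n, replace = TRUE,
                                prob = c(0.06, 0.30, 0.64)), NA)
  for (rep_nm in c("caregiver", "youth")) {
    mis <- config$missingness[[rep_nm]]
    tok <- ifelse(men_yes, "yes", "no")
    u <- runif(n)
    tok[u < mis$idk[["menarche"]]] <- "I don't know"
    tok[u >= mis$idk[["menarche"]] &
          u < mis$idk[["menarche"]] + mis$refuse] <- "Refuse to answer"
    tok[sex == "M"] <- NA_character_
    prefix <- if (rep_nm == "caregiver") "cg" else "y"
    resp[[paste0(prefix, "_menarche")]] <- tok
  }

  # hormones: log-normal in maturation + shared hormone latent; duplicates
  # with multiplicative noise; censoring below the lower limit -> "BLQ"
  sr <- config$session_rates
  xi <- rnorm(n)  # shared within-child hormone latent
  reps <- list()
  for (h in names(config$hormone_params)) {
    p <- config$hormone_params[[h]]
    mu <- p$intercept + p$slope * eta + p$shared * xi
    true_level <- exp(mu + rnorm(n, 0, p$sd))
    sd_dup <- sqrt(log(1 + p$duplicate_cv^2))
    for (r in 1:2) {
      val <- true_level * exp(rnorm(n, -sd_dup^2 / 2, sd_dup))
      tok <- ifelse(val < p$lower_limit, "BLQ", as.character(round(val, 2)))
      tok[runif(n) < sr$rep_absent] <- NA_character_
      if (h == "estradiol") tok[sex == "M"] <- NA_character_
      reps[[paste0(h, "_rep", r)]] <- tok
      reps[[paste0(h, "_flag", r)]] <- runif(n) < sr$ra_flag
    }
  }

  start_min <- sample(420:1140, n, replace = TRUE)
  dur <- pmax(1L, round(rlnorm(n, log(6), 0.6)))
  frz <- round(rlnorm(n, log(1.5), 1))

  out <- tibble::tibble(
    child_id = sprintf("C%05d", seq_len(n)),
    family_id = sprintf("F%05d", family),
    site_id = site,
    sex = sex, age_months = age,
    race_ethnicity = race, income_band = income, education_band = education,
    true_maturation = eta,
    height1 = hm[[1]], height2 = hm[[2]], height3 = hm[[3]],
    weight1 = wm[[1]], weight2 = wm[[2]], weight3 = wm[[3]]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(resp[
    c(paste0("cg_", c("height", "body_hair", "skin", "facial_hair", "voice",
                      "breast", "menarche")),
      paste0("y_", c("height", "body_hair", "skin", "facial_hair", "voice",
                     "breast", "menarche")))]))
  out$menarche_age <- menarche_age
  out <- dplyr::bind_cols(out, tibble::as_tibble(reps[
    as.vector(t(outer(c("dhea", "testosterone", "estradiol"),
                      c("_rep1", "_rep2", "_flag1", "_flag2"), paste0)))]))
  out$recorded_sex <- ifelse(runif(n) < sr$sex_mismatch,
                             ifelse(sex == "M", "F", "M"), sex)
  out$collected <- runif(n) >= sr$not_collected
  out$processed <- runif(n) >= sr$not_processed
  out$collection_start <- minutes_to_clock(start_min)
  out$collection_end <- minutes_to_clock(start_min + dur)
  out$freeze_time <- minutes_to_clock(start_min + dur + frz)
  out$caffeine_12h <- runif(n) < sr$caffeine
  out$exercise_12h <- runif(n) < sr$exercise
  out
}

#' Generate planted group-sparse factor data
#'
#' Oracle generator for factor-recovery tests: draws latent scores
#' `Z_true` (columns rescaled to exactly unit sample variance), per-group
#' loadings `W_true` that are exactly zero wherever `active_mask` is
#' `FALSE`, and observations X^(m) = Z_true W_true^(m)' + noise, with the
#' per-group noise SD set so that the signal-to-noise ratio (mean signal
#' power over noise variance) equals `snr`.
#'
#' @param n rows (children).
#' @param group_dims integer vector of block widths.
#' @param k number of planted factors.
#' @param active_mask groups x factors logical matrix.
#' @param snr positive signal-to-noise ratio; `Inf` for noise-free data.
#' @param seed RNG seed.
#' @return list(data = named list of observed blocks, truth = list(Z_true,
#'   W_true, active_mask, noise_sd)).
#' @export
generate_planted_groups <- function(n, group_dims, k,
                                    active_mask = NULL, snr = 10,
                                    seed = 1L) {
  if (k < 1) abort("k must be >= 1")
  if (any(group_dims < 1)) abort("each group dim must be >= 1")
  if (snr <= 0) abort("snr must be > 0")
  M <- length(group_dims)
  active_mask <- active_mask %||% matrix(TRUE, M, k)
  if (!all(dim(active_mask) == c(M, k))) {
    abort("active_mask must be groups x factors")
  }
  set.seed(seed)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- sweep(Z, 2, apply(Z, 2, sd), "/")
  W <- purrr::map(seq_len(M), function(m) {
    # loading magnitudes bounded away from zero (signed uniform on
    # [0.5, 1.5]) and columns fixed at norm sqrt(D_m): every variable and
    # every active block-factor carries a comparable, non-vanishing signal
    # share, so the planted rank is recoverable under a per-block noise
    # model on standardized data
    w <- matrix(sample(c(-1, 1), group_dims[m] * k, replace = TRUE) *
                  runif(group_dims[m] * k, 0.5, 1.5),
                group_dims[m], k)
    for (j in seq_len(k)) {
      if (active_mask[m, j]) {
        w[, j] <- w[, j] * sqrt(group_dims[m]) / sqrt(sum(w[, j]^2))
      } else {
        w[, j] <- 0
      }
    }
    w
  })
  noise_sd <- numeric(M)
  data <- purrr::map(seq_len(M), function(m) {
    S <- Z %*% t(W[[m]])
    pw <- mean(S^2)
    sdm <- if (is.infinite(snr)) 0 else sqrt(max(pw, 1e-12) / snr)
    noise_sd[m] <<- sdm
    X <- S + matrix(rnorm(n * group_dims[m], 0, sdm), n, group_dims[m])
    colnames(X) <- paste0("g", m, "v", seq_len(group_dims[m]))
    X
  })
  names(data) <- paste0("group", seq_len(M))
  list(data = data,
       truth = list(Z_true = Z, W_true = W, active_mask = active_mask,
                    noise_sd = noise_sd))
}

#' Write / read a cohort CSV with its configuration sidecar
#'
#' @param cohort cohort tibble.
#' @param path CSV path; the configuration is written alongside as
#'   `<path>.config.json`.
#' @param config the generating [cohort_config()] (optional).
#' @export
write_cohort_csv <- function(cohort, path, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write planted factor fixtures as CSV matrices with a JSON truth sidecar
#'
#' Each observed block goes to `<stem>_<block>.csv`; the generating truth
#' (latent scores, loadings, active mask, noise SDs) to `<stem>_truth.json`.
#'
#' @param planted output of [generate_planted_groups()].
#' @param stem path stem for the output files.
#' @export
write_planted_groups <- function(planted, stem) {
  for (nm in names(planted$data)) {
    utils::write.csv(planted$data[[nm]], paste0(stem, "_", nm, ".csv"),
                     row.names = FALSE)
  }
  tr <- planted$truth
  jsonlite::write_json(
    list(Z_true = tr$Z_true, W_true = tr$W_true,
         active_mask = tr$active_mask, noise_sd = tr$noise_sd),
    paste0(stem, "_truth.json"), digits = NA, matrix = "rowmajor")
  invisible(stem)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(cohort_column_schema(), names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw[raw == ""] <- NA
  num <- c("site_id", "age_months", "true_maturation",
           paste0("height", 1:3), paste0("weight", 1:3), "menarche_age")
  lgl <- c(paste0(c("dhea", "testosterone", "estradiol"), "_flag1"),
           paste0(c("dhea", "testosterone", "estradiol"), "_flag2"),
           "collected", "processed", "caffeine_12h", "exercise_12h")
  out <- tibble::as_tibble(raw)
  for (cn in num) out[[cn]] <- as.numeric(out[[cn]])
  for (cn in lgl) out[[cn]] <- as.logical(out[[cn]])
  out
}
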