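#' Build the grouped puberty blocks for one sex
#'
#' Assembles the two-block data the factor analysis runs on: a physical
#' block of coded PDS items (males: height, body hair, skin, facial hair,
#' voice; females: height, body hair, skin, breast, menarche coded 4/1) and
#' a hormone block (DHEA and testosterone, plus estradiol for females),
#' restricted to complete cases, then standardized.
#'
#' @param cohort raw cohort tibble.
#' @param hormones output of [qc_hormones()].
#' @param sex `"M"` or `"F"`.
#' @param reporter PDS reporter feeding the physical block.
#' @param log_hormones log-transform hormone levels before z-scoring.
#' @return a `pub_grouped` object (attribute `n_dropped` records the
#'   complete-case exclusions).
#' @export
puberty_blocks <- function(cohort, hormones, sex,
                           reporter = c("caregiver", "youth"),
                           log_hormones = FALSE) {
  reporter <- match.arg(reporter)
  prefix <- if (reporter == "caregiver") "cg" else "y"
  rows <- cohort[cohort$sex == sex, ]
  items <- if (sex == "M") {
    c("height", "body_hair", "skin", "facial_hair", "voice")
  } else {
    c("height", "body_hair", "skin", "breast")
  }
  phys <- sapply(items, function(it) {
    as.numeric(pds_code_item(rows[[paste0(prefix, "_", it)]]))
  })
  if (sex == "F") {
    phys <- cbind(phys,
                  menarche = as.numeric(pds_code_menarche(rows[[paste0(prefix, "_menarche")]])))
  }
  analytes <- if (sex == "F") c("dhea", "testosterone", "estradiol") else
    c("dhea", "testosterone")
  hw <- hormones |>
    dplyr::filter(.data$analyte %in% analytes) |>
    dplyr::select("child_id", "analyte", "value") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  hw <- hw[match(rows$child_id, hw$child_id), ]
  horm <- as.matrix(hw[, analytes])
  ok <- complete.cases(phys) & complete.cases(horm)
  g <- standardize_blocks(
    list(physical = phys[ok, , drop = FALSE],
         hormones = horm[ok, , drop = FALSE]),
    log_flags = if (log_hormones)
      list(hormones = rep(TRUE, length(analytes))) else NULL,
    row_ids = rows$child_id[ok]
  )
  attr(g, "n_dropped") <- sum(!ok)
  g
}

#' Model-ready analysis table with reference-level dummy coding
#'
#' Joins cohort, PDS summary scores, QC'd hormone values and session
#' covariates into one table per child, dummy-codes the categorical
#' covariates against the reference levels (age centered at 108 months,
#' sex = male, ethnicity = Hispanic, education = high school diploma/GED,
#' income = middle, weight status = healthy), and keeps complete cases
#' only. Reference-level columns are absent from the dummy set.
#'
#' @param cohort cohort tibble with anthropometrics appended.
#' @param scores [score_pds()] output for the chosen reporter.
#' @param hormones [qc_hormones()] output.
#' @return tibble; attribute `n_dropped` counts complete-case exclusions.
#' @export
build_analysis_table <- function(cohort, scores, hormones) {
  hw <- hormones |>
    dplyr::select("child_id", "analyte", "value") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  cov <- hormones |>
    dplyr::distinct(.data$child_id, .data$minutes_since_midnight,
                    .data$duration_min, .data$to_freeze_min,
                    .data$caffeine_12h, .data$exercise_12h)
  tab <- cohort |>
    dplyr::select("child_id", "family_id", "site_id", "sex", "age_months",
                  "race_ethnicity", "income_band", "education_band",
                  "bmiz", "weight_status") |>
    dplyr::inner_join(dplyr::select(scores, "child_id", "average_pds",
                                    "gonadal", "adrenal", "category_sum"),
                      by = "child_id") |>
    dplyr::left_join(hw, by = "child_id") |>
    dplyr::left_join(cov, by = "child_id") |>
    dplyr::mutate(age_c108 = .data$age_months - 108, female = as.integer(.data$sex == "F"))

  dummy <- function(x, levels, ref) {
    lv <- setdiff(levels, ref)
    out <- purrr::map(lv, ~ as.integer(x == .x))
    setNames(out, lv)
  }
  tab <- dplyr::bind_cols(
    tab,
    tibble::as_tibble(dummy(tab$race_ethnicity,
                            c("Hispanic", "White", "Black", "Asian", "Other"),
                            "Hispanic")) |>
      dplyr::rename_with(~ paste0("eth_", .x)),
    tibble::as_tibble(dummy(tab$income_band, c("mid", "low", "high"), "mid")) |>
      dplyr::rename_with(~ paste0("income_", .x)),
    tibble::as_tibble(dummy(tab$education_band,
                            c("hs_ged", "less_hs", "some_college", "bachelor",
                              "postgrad"), "hs_ged")) |>
      dplyr::rename_with(~ paste0("edu_", .x)),
    tibble::as_tibble(dummy(as.character(tab$weight_status),
                            c("healthy", "underweight", "overweight", "obese"),
                            "healthy")) |>
      dplyr::rename_with(~ paste0("ws_", .x))
  )
  # estradiol is structurally absent for males; complete-case filter applies
  # to the variables defined for the child's sex
  check_cols <- setdiff(names(tab), "estradiol")
  ok <- complete.cases(tab[check_cols])
  if ("estradiol" %in% names(tab)) {
    ok <- ok & (tab$sex == "M" | !is.na(tab$estradiol))
  }
  out <- tab[ok, ]
  attr(out, "n_dropped") <- sum(!ok)
  message(sum(!ok), " row(s) dropped by the complete-case filter")
  out
}

#' Run the full analysis pipeline on a synthetic or CSV cohort
#'
#' Executes, in order: cohort generation (or CSV ingestion), PDS scoring for
#' both reporters, anthropometrics, hormone QC, caregiver-youth agreement,
#' per-sex group factor analysis, stability checks (replicate runs with
#' loading summaries, split-half), synchrony profiling with sociodemographic
#' overlays, and the model-ready analysis table. Every stage's row count is
#' recorded in the manifest; the global seed fixes all randomness.
#'
#' @param config a [cohort_config()] (synthetic mode), or `NULL` with
#'   `input` a cohort CSV path.
#' @param input optional cohort CSV path (csv mode).
#' @param reporter PDS reporter for the factor analysis (default caregiver).
#' @param priors,mcmc GFA settings.
#' @param k_init factor dimension for the puberty GFA (default 4, the
#'   extracted rank at this age range; the ARD prior can still empty
#'   surplus factors). Set `NULL` for the total variable count.
#' @param n_rep replicate GFA runs for the stability stage.
#' @param stability run the replicate/split-half stage.
#' @param seed global seed.
#' @param out_dir optional directory for per-stage CSV/JSON outputs.
#' @return list with elements cohort, scores (both reporters), hormones,
#'   agreement, gfa (per sex), stability, profiles, overlay,
#'   analysis_table, manifest.
#' @export
run_pipeline <- function(config = cohort_config(), input = NULL,
                         reporter = c("caregiver", "youth"),
                         priors = gfa_priors(), mcmc = gfa_mcmc(),
                         k_init = 4, n_rep = 10, stability = TRUE, seed = 1L,
                         out_dir = NULL) {
  reporter <- match.arg(reporter)
  manifest <- list(seed = seed, reporter = reporter, stages = list())
  stage <- function(name, n) {
    manifest$stages[[name]] <<- list(rows = n)
  }

  cohort <- if (!is.null(input)) {
    read_cohort_csv(input)
  } else {
    cfg <- config; cfg$seed <- as.integer(seed)
    generate_cohort(cfg)
  }
  stage("cohort", nrow(cohort))

  scores_cg <- score_pds(cohort, "caregiver")
  scores_y <- score_pds(cohort, "youth")
  stage("pds_scoring", nrow(scores_cg))

  cohort <- add_anthropometrics(cohort)
  stage("anthropometrics", nrow(cohort))

  hormones <- qc_hormones(cohort)
  stage("hormone_qc", nrow(hormones))

  agreement <- agreement_report(cohort)
  stage("agreement", nrow(agreement))

  scores <- if (reporter == "caregiver") scores_cg else scores_y
  gfa <- list(); stab <- list(); profiles <- list(); overlay <- list()
  for (sx in intersect(c("M", "F"), unique(cohort$sex))) {
    blocks <- puberty_blocks(cohort, hormones, sx, reporter)
    m <- mcmc; m$seed <- as.integer(seed + 100L)
    fit <- fit_gfa(blocks, K = k_init, priors = priors, mcmc = m)
    gfa[[sx]] <- fit
    if (stability) {
      runs <- replicate_gfa(blocks, n_rep = n_rep,
                            base_seed = as.integer(seed + 200L),
                            K = k_init, priors = priors, mcmc = mcmc)
      al <- match_factors(runs)
      stab[[sx]] <- list(
        runs = length(runs),
        loadings = summarize_loadings(al),
        split_half = split_half(blocks, seed = as.integer(seed + 300L),
                                K = k_init, priors = priors, mcmc = mcmc)
      )
    }
    if (length(fit$retained) >= 2) {
      pr <- latent_profiles(fit, row_ids = blocks$row_ids)
      profiles[[sx]] <- pr
      overlay[[sx]] <- sociodemographic_overlay(pr, cohort, "weight_status")
    }
  }
  stage("gfa", length(gfa))
  stage("stability", length(stab))
  stage("profiles", sum(vapply(profiles, nrow, 1L)))

  analysis <- build_analysis_table(cohort, scores, hormones)
  stage("analysis_table", nrow(analysis))
  manifest$stages_complete <- length(manifest$stages)

  result <- list(cohort = cohort,
                 scores = list(caregiver = scores_cg, youth = scores_y),
                 hormones = hormones, agreement = agreement, gfa = gfa,
                 stability = stab, profiles = profiles, overlay = overlay,
                 analysis_table = analysis, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dplyr::bind_rows(result$scores),
                   file.path(out_dir, "pds_scores.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(result$hormones, file.path(out_dir, "hormones.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$agreement, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$analysis_table,
                   file.path(out_dir, "analysis_table.csv"),
                   row.names = FALSE, na = "")
  for (sx in names(result$gfa)) {
    fit <- result$gfa[[sx]]
    utils::write.csv(fit$Z, file.path(out_dir, paste0("gfa_Z_", sx, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(ve = fit$ve, retained = fit$retained, seed = fit$mcmc$seed,
           K = fit$K, blocks = fit$block_names),
      file.path(out_dir, paste0("gfa_summary_", sx, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
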