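# shared fixtures and independent oracles for the test suite

# brute-force lookup of the male puberty category: enumerate the quoted sum
# rules directly, with the parenthetical constraints applied literally
oracle_male_category <- function(bh, vo, fh) {
  s <- bh + vo + fh
  any3 <- max(bh, vo, fh) >= 3
  any4 <- max(bh, vo, fh) >= 4
  if (s == 3) "prepubertal"
  else if (s <= 5) { if (any3) "mid" else "early" }
  else if (s <= 8) { if (any4) "late" else "mid" }
  else if (s <= 11) "late"
  else "post"
}

oracle_female_category <- function(bh, br, menarche_yes) {
  s <- bh + br
  if (menarche_yes) { if (s == 8) "post" else "late" }
  else if (s == 2) "prepubertal"
  else if (s == 3) "early"
  else "mid"
}

# 1-D grid-search ML oracle for the polychoric correlation, built on
# mvtnorm::pmvnorm (independent of the package's quadrature)
oracle_polychoric_grid <- function(counts, step = 0.01) {
  n <- sum(counts)
  K1 <- nrow(counts); K2 <- ncol(counts)
  a <- c(-Inf, qnorm(cumsum(rowSums(counts) / n))[seq_len(K1 - 1)], Inf)
  b <- c(-Inf, qnorm(cumsum(colSums(counts) / n))[seq_len(K2 - 1)], Inf)
  ll <- function(r) {
    s <- matrix(c(1, r, r, 1), 2)
    tot <- 0
    for (i in seq_len(K1)) for (j in seq_len(K2)) {
      if (counts[i, j] > 0) {
        p <- mvtnorm::pmvnorm(lower = c(a[i], b[j]),
                              upper = c(a[i + 1], b[j + 1]), sigma = s)
        tot <- tot + counts[i, j] * log(max(as.numeric(p), 1e-12))
      }
    }
    tot
  }
  grid <- seq(-0.99, 0.99, by = step)
  grid[which.max(vapply(grid, ll, 1))]
}

# discretized bivariate-normal sample -> ordinal pair
simulate_ordinal_pair <- function(n, rho, cuts_x, cuts_y = cuts_x) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(x = findInterval(z1, cuts_x) + 1L, y = findInterval(z2, cuts_y) + 1L)
}

# minimal hand-built cohort rows with full raw-response schema
toy_cohort <- function(n = 3) {
  tibble::tibble(
    child_id = sprintf("T%03d", seq_len(n)),
    family_id = sprintf("TF%03d", seq_len(n)),
    site_id = 1L,
    sex = rep_len(c("M", "F"), n),
    age_months = 120,
    race_ethnicity = "White", income_band = "mid",
    education_band = "bachelor",
    true_maturation = 0,
    height1 = 140, height2 = 140.5, height3 = NA_real_,
    weight1 = 35, weight2 = 35.2, weight3 = NA_real_,
    cg_height = "2", cg_body_hair = "1", cg_skin = "1",
    cg_facial_hair = ifelse(rep_len(c(TRUE, FALSE), n), "1", NA),
    cg_voice = ifelse(rep_len(c(TRUE, FALSE), n), "1", NA),
    cg_breast = ifelse(rep_len(c(TRUE, FALSE), n), NA, "2"),
    cg_menarche = ifelse(rep_len(c(TRUE, FALSE), n), NA, "no"),
    y_height = "2", y_body_hair = "1", y_skin = "1",
    y_facial_hair = ifelse(rep_len(c(TRUE, FALSE), n), "1", NA),
    y_voice = ifelse(rep_len(c(TRUE, FALSE), n), "1", NA),
    y_breast = ifelse(rep_len(c(TRUE, FALSE), n), NA, "2"),
    y_menarche = ifelse(rep_len(c(TRUE, FALSE), n), NA, "no"),
    menarche_age = NA_real_,
    dhea_rep1 = "50", dhea_rep2 = "52",
    dhea_flag1 = FALSE, dhea_flag2 = FALSE,
    testosterone_rep1 = "30", testosterone_rep2 = "31",
    testosterone_flag1 = FALSE, testosterone_flag2 = FALSE,
    estradiol_rep1 = ifelse(rep_len(c(TRUE, FALSE), n), NA, "1.2"),
    estradiol_rep2 = ifelse(rep_len(c(TRUE, FALSE), n), NA, "1.3"),
    estradiol_flag1 = FALSE, estradiol_flag2 = FALSE,
    recorded_sex = rep_len(c("M", "F"), n),
    collected = TRUE, processed = TRUE,
    collection_start = "12:57", collection_end = "13:04",
    freeze_time = "13:06",
    caffeine_12h = FALSE, exercise_12h = FALSE
  )
}

# tiny pub_gfa stub for stability-function unit tests
fake_gfa <- function(W_blocks, retained = seq_len(ncol(W_blocks[[1]])),
                     N = 10) {
  K <- ncol(W_blocks[[1]])
  structure(list(
    Z = matrix(rnorm(N * K), N, K),
    W = W_blocks, alpha = matrix(1, length(W_blocks), K),
    tau = rep(1, length(W_blocks)), K = K, N = N,
    D = vapply(W_blocks, nrow, 1L),
    block_names = names(W_blocks) %||% paste0("b", seq_along(W_blocks)),
    var_names = purrr::map(W_blocks, rownames),
    ve = rev(seq_len(K)) / (2 * K), ve_by_block = NULL,
    retained = retained
  ), class = "pub_gfa")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small fast sampler settings for unit-scale fits
mcmc_fast <- function(seed = 1L) {
  pubsync::gfa_mcmc(n_iter = 2000, burn_in = 1000, thin = 5, seed = seed)
}
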