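#' Tucker congruence between two loading vectors
#'
#' phi = (w1 . w2) / (||w1|| ||w2||); 1 for identical direction, -1 for
#' opposite sign.
#'
#' @param w1,w2 numeric loading vectors.
#' @export
tucker_congruence <- function(w1, w2) {
  sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))
}

# stacked (all-block) loading matrix restricted to retained factors
stacked_loadings <- function(fit, factors = fit$retained) {
  do.call(rbind, fit$W)[, factors, drop = FALSE]
}

#' Replicate a group factor analysis across seeds
#'
#' Fits the same model `n_rep` times with seeds `base_seed + 0..(n_rep-1)`,
#' the replication scheme used to check that factor solutions are stable.
#'
#' @param data a `pub_grouped` object.
#' @param n_rep number of replicate fits (default 10).
#' @param base_seed first sampler seed.
#' @param ... passed to [fit_gfa()].
#' @return list of `pub_gfa` fits.
#' @export
replicate_gfa <- function(data, n_rep = 10, base_seed = 1L, K = NULL,
                          priors = gfa_priors(), mcmc = gfa_mcmc(), ...) {
  purrr::map(seq_len(n_rep) - 1L, function(r) {
    m <- mcmc; m$seed <- as.integer(base_seed + r)
    fit_gfa(data, K = K, priors = priors, mcmc = m, ...)
  })
}

# maximize total |cor| assignment; exhaustive for small k, greedy fallback
best_assignment <- function(score, exact_limit = 7) {
  k <- nrow(score)
  if (k <= exact_limit) {
    perms <- permutations_of(k)
    vals <- vapply(perms, function(p) sum(score[cbind(seq_len(k), p)]), 1)
    perms[[which.max(vals)]]
  } else {
    p <- integer(k); taken <- rep(FALSE, k)
    for (i in order(-apply(score, 1, max))) {
      j <- order(-score[i, ])
      j <- j[!taken[j]][1]
      p[i] <- j; taken[j] <- TRUE
    }
    p
  }
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- permutations_of(k - 1)
    out <- c(out, lapply(rest, function(p) c(i, (seq_len(k))[-i][p])))
  }
  out
}

#' Align factors across replicate runs
#'
#' Factor models are identified only up to permutation and sign; this
#' matches every run's retained factors to the first (reference) run by the
#' assignment maximizing summed |Pearson correlation| between stacked
#' loading vectors, then flips signs so each matched factor correlates
#' positively with its reference.
#'
#' @param runs list of `pub_gfa` fits (>= 2) with retained factors.
#' @return object of class `pub_alignment`: list(reference, permutations,
#'   signs, stack (runs x variables x factors array), match_score,
#'   var_names, factors).
#' @export
match_factors <- function(runs) {
  if (length(runs) < 1) abort("need at least one run")
  counts <- vapply(runs, function(f) length(f$retained), 1L)
  if (any(counts == 0)) abort("a run retained 0 factors; cannot align")
  k <- min(counts)
  if (length(unique(counts)) > 1) {
    warn(paste0("runs retain different factor counts; aligning on the first ",
                k, " factors of each"))
  }
  ref <- stacked_loadings(runs[[1]], runs[[1]]$retained[seq_len(k)])
  nv <- nrow(ref)
  stack <- array(NA_real_, dim = c(length(runs), nv, k))
  perms <- matrix(NA_integer_, length(runs), k)
  signs <- matrix(NA_real_, length(runs), k)
  scores <- numeric(length(runs))
  for (r in seq_along(runs)) {
    L <- stacked_loadings(runs[[r]], runs[[r]]$retained[seq_len(k)])
    cmat <- abs(cor(ref, L))
    p <- best_assignment(cmat)
    s <- vapply(seq_len(k), function(j) sign(cor(ref[, j], L[, p[j]])), 1)
    s[is.na(s) | s == 0] <- 1
    stack[r, , ] <- sweep(L[, p, drop = FALSE], 2, s, "*")
    perms[r, ] <- p
    signs[r, ] <- s
    scores[r] <- mean(cmat[cbind(seq_len(k), p)])
  }
  if (any(scores < 0.5)) {
    warn("low factor-match score for at least one run; solutions may not correspond")
  }
  vn <- unlist(purrr::map2(runs[[1]]$block_names,
                           seq_along(runs[[1]]$block_names), function(b, m) {
    v <- runs[[1]]$var_names[[m]] %||% seq_len(runs[[1]]$D[m])
    paste0(b, ".", v)
  }))
  structure(list(reference = 1L, permutations = perms, signs = signs,
                 stack = stack, match_score = scores,
                 var_names = if (length(vn) == nv) vn else paste0("v", seq_len(nv)),
                 factors = seq_len(k)),
            class = "pub_alignment")
}

#' Median loadings and 95% intervals across aligned runs
#'
#' @param alignment a `pub_alignment` from [match_factors()].
#' @return tibble: variable, factor, median, lower, upper.
#' @export
summarize_loadings <- function(alignment) {
  st <- alignment$stack
  purrr::map_dfr(alignment$factors, function(kk) {
    tibble::tibble(
      variable = alignment$var_names,
      factor = kk,
      median = apply(st[, , kk, drop = FALSE], 2, median),
      lower = apply(st[, , kk, drop = FALSE], 2, quantile, 0.025),
      upper = apply(st[, , kk, drop = FALSE], 2, quantile, 0.975)
    )
  })
}

#' Split-half replication of the factor solution
#'
#' Randomly splits the children into two disjoint halves, fits the model in
#' each, matches retained factors across halves, and reports the Tucker
#' congruence per factor. A factor is flagged replicated when
#' phi >= `phi_criterion` (default 0.90).
#'
#' @param data a `pub_grouped` object (N >= 4).
#' @param seed split seed.
#' @param phi_criterion replication threshold.
#' @inheritParams replicate_gfa
#' @return tibble: factor, congruence, replicated.
#' @export
split_half <- function(data, seed = 1L, K = NULL, priors = gfa_priors(),
                       mcmc = gfa_mcmc(), phi_criterion = 0.90, ...) {
  N <- nrow(data$blocks[[1]])
  if (N < 4) abort("need N >= 4 for split-half")
  set.seed(seed)
  idx <- sample.int(N)
  h1 <- sort(idx[seq_len(N %/% 2)])
  h2 <- sort(idx[(N %/% 2 + 1L):N])
  subset_grouped <- function(g, rows) {
    g$blocks <- purrr::map(g$blocks, ~ .x[rows, , drop = FALSE])
    g$blocks <- purrr::map(g$blocks, function(b) {
      sweep(sweep(b, 2, colMeans(b)), 2, apply(b, 2, sd), "/")
    })
    g$row_ids <- g$row_ids[rows]
    g
  }
  m1 <- mcmc; m1$seed <- as.integer(seed + 1000L)
  m2 <- mcmc; m2$seed <- as.integer(seed + 2000L)
  f1 <- fit_gfa(subset_grouped(data, h1), K = K, priors = priors, mcmc = m1, ...)
  f2 <- fit_gfa(subset_grouped(data, h2), K = K, priors = priors, mcmc = m2, ...)
  k <- min(length(f1$retained), length(f2$retained))
  if (k == 0) abort("a half retained 0 factors")
  L1 <- stacked_loadings(f1, f1$retained[seq_len(k)])
  L2 <- stacked_loadings(f2, f2$retained[seq_len(k)])
  p <- best_assignment(abs(cor(L1, L2)))
  phi <- vapply(seq_len(k), function(j) {
    abs(tucker_congruence(L1[, j], L2[, p[j]]))
  }, 1)
  tibble::tibble(factor = seq_len(k), congruence = phi,
                 replicated = phi >= phi_criterion)
}

#' Covariate-extended refits and loading-stability report
#'
#' Refits the model with each successive covariate extension entered as an
#' additional block and reports the Tucker congruence of the base
#' (puberty-block) loadings of the top retained factors against the base
#' model. Covariate blocks are pre-residualized on the previously entered
#' covariate blocks, in order; the puberty blocks are never residualized.
#'
#' @param data base `pub_grouped` object.
#' @param extensions named list of covariate blocks (numeric matrices
#'   row-aligned with `data`), entered cumulatively in order.
#' @inheritParams replicate_gfa
#' @param seed sampler seed for every refit.
#' @return tibble: model, factor, congruence.
#' @export
covariate_extension <- function(data, extensions, K = NULL,
                                priors = gfa_priors(), mcmc = gfa_mcmc(),
                                seed = 1L, ...) {
  m0 <- mcmc; m0$seed <- as.integer(seed)
  base <- fit_gfa(data, K = K, priors = priors, mcmc = m0, ...)
  kb <- length(base$retained)
  n_base_vars <- sum(base$D)
  if (length(extensions) == 0) {
    return(tibble::tibble(model = "base", factor = seq_len(kb),
                          congruence = rep(1, kb)))
  }
  base_L <- stacked_loadings(base)
  hormone_block <- data$blocks[[length(data$blocks)]]
  out <- list()
  prev <- list()
  cum <- data$blocks
  for (e in seq_along(extensions)) {
    ext <- as.matrix(extensions[[e]])
    if (nrow(ext) != nrow(data$blocks[[1]])) {
      abort("extension blocks must be row-aligned with the data")
    }
    if (length(prev)) {
      Xprev <- do.call(cbind, prev)
      ext <- apply(ext, 2, function(col) resid(lm(col ~ Xprev)))
    }
    # collinearity guard against existing blocks
    for (b in cum) {
      cc <- suppressWarnings(cor(b, ext))
      if (any(abs(cc) > 0.999, na.rm = TRUE)) {
        warn("an extension variable is collinear with an existing block")
      }
    }
    prev[[length(prev) + 1L]] <- ext
    cum[[names(extensions)[e] %||% paste0("ext", e)]] <- ext
    g <- standardize_blocks(cum, row_ids = data$row_ids)
    me <- mcmc; me$seed <- as.integer(seed + e)
    fit <- fit_gfa(g, K = K, priors = priors, mcmc = me, ...)
    k <- min(kb, length(fit$retained))
    if (k == 0) next
    L <- do.call(rbind, fit$W)[seq_len(n_base_vars), fit$retained[seq_len(k)],
                               drop = FALSE]
    p <- best_assignment(abs(cor(base_L[, seq_len(k), drop = FALSE], L)))
    out[[length(out) + 1L]] <- tibble::tibble(
      model = names(extensions)[e] %||% paste0("ext", e),
      factor = seq_len(k),
      congruence = vapply(seq_len(k), function(j) {
        abs(tucker_congruence(base_L[, j], L[, p[j]]))
      }, 1)
    )
  }
  dplyr::bind_rows(tibble::tibble(model = "base", factor = seq_len(kb),
                                  congruence = rep(1, kb)),
                   dplyr::bind_rows(out))
}

#' Latent synchrony profiles from the top two factors
#'
#' LF1 and LF2 are the posterior-mean score columns of the two top retained
#' factors (by variance explained). The joint signs classify each child:
#' both high = synchronous_high, both low = synchronous_low, high LF1 with
#' low LF2 = asynchronous_hormone_led (hormones ahead of perceived physical
#' features), and the reverse = asynchronous_physical_led.
#'
#' @param post a `pub_gfa` fit with >= 2 retained factors.
#' @param row_ids optional child identifiers.
#' @param split `"zero"` (default; scores are centered by construction) or
#'   `"median"` for a percentile split.
#' @return tibble: child_id, lf1, lf2, synchrony; class `pub_profiles`.
#' @export
latent_profiles <- function(post, row_ids = NULL, split = c("zero", "median")) {
  split <- match.arg(split)
  if (length(post$retained) < 2) {
    abort("need >= 2 retained factors for synchrony profiling")
  }
  lf1 <- post$Z[, post$retained[1]]
  lf2 <- post$Z[, post$retained[2]]
  if (all(abs(lf1) < 1e-10) || all(abs(lf2) < 1e-10)) {
    warn("degenerate (all-zero) factor scores; synchrony classes undefined")
    syn <- rep(NA_character_, length(lf1))
  } else {
    c1 <- if (split == "median") median(lf1) else 0
    c2 <- if (split == "median") median(lf2) else 0
    syn <- dplyr::case_when(
      lf1 >= c1 & lf2 >= c2 ~ "synchronous_high",
      lf1 < c1 & lf2 < c2 ~ "synchronous_low",
      lf1 >= c1 & lf2 < c2 ~ "asynchronous_hormone_led",
      TRUE ~ "asynchronous_physical_led"
    )
  }
  out <- tibble::tibble(
    child_id = row_ids %||% seq_along(lf1),
    lf1 = lf1, lf2 = lf2,
    synchrony = factor(syn, levels = c("synchronous_low", "synchronous_high",
                                       "asynchronous_hormone_led",
                                       "asynchronous_physical_led"))
  )
  class(out) <- c("pub_profiles", class(out))
  out
}

#' Sociodemographic overlay of latent factor scores
#'
#' Group means and dispersions of (LF1, LF2) by a grouping column of the
#' cohort (weight status, race/ethnicity, education, income), per sex.
#'
#' @param profiles a `pub_profiles` table.
#' @param cohort cohort tibble joinable on `child_id`.
#' @param group_var name of the grouping column.
#' @return tibble: sex, group, n, lf1_mean, lf1_sd, lf2_mean, lf2_sd.
#' @export
sociodemographic_overlay <- function(profiles, cohort, group_var) {
  joined <- dplyr::inner_join(profiles, cohort, by = "child_id")
  empty <- setdiff(unique(cohort[[group_var]]), unique(joined[[group_var]]))
  if (length(empty)) {
    message("omitting empty group(s): ", paste(empty, collapse = ", "))
  }
  joined |>
    dplyr::group_by(sex = .data$sex, group = .data[[group_var]]) |>
    dplyr::summarise(n = dplyr::n(),
                     lf1_mean = mean(.data$lf1), lf1_sd = sd(.data$lf1),
                     lf2_mean = mean(.data$lf2), lf2_sd = sd(.data$lf2),
                     .groups = "drop")
}
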