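#' Cross-tabulate two ordinal raters
#'
#' Builds the K x K contingency table over pairwise-complete observations,
#' rows indexed by the first rater (caregiver), columns by the second
#' (youth).
#'
#' @param x,y integer vectors with entries in 1..K or `NA`.
#' @param K number of ordered categories (>= 2).
#' @return object of class `pub_pair_table`: list(counts, K, n).
#' @export
build_pair_table <- function(x, y, K) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (K < 2) abort("K must be >= 2")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) abort("no complete pairs")
  if (any(!x %in% seq_len(K)) || any(!y %in% seq_len(K))) {
    abort("codes outside 1..K")
  }
  counts <- matrix(0L, K, K)
  for (i in seq_along(x)) counts[x[i], y[i]] <- counts[x[i], y[i]] + 1L
  structure(list(counts = counts, K = K, n = length(x)),
            class = "pub_pair_table")
}

as_pair_table <- function(tab) {
  if (inherits(tab, "pub_pair_table")) return(tab)
  counts <- as.matrix(tab)
  structure(list(counts = counts, K = nrow(counts), n = sum(counts)),
            class = "pub_pair_table")
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement with disagreement weights
#' w_ij = (|i - j| / (K - 1))^d, d = 1 (linear) or 2 (quadratic):
#' kappa = 1 - sum(w p_obs) / sum(w p_exp), expected proportions from the
#' marginal products. The large-sample standard error (Fleiss, Cohen &
#' Everitt form) gives a normal-approximation confidence interval.
#'
#' @param tab a `pub_pair_table` or square count matrix.
#' @param scheme `"quadratic"` (default) or `"linear"` weights.
#' @param conf_level confidence level for the interval.
#' @param boot use a seeded nonparametric bootstrap for the interval
#'   instead of the asymptotic SE.
#' @param n_boot,boot_seed bootstrap resamples (default 1,000) and seed.
#' @return tibble: kappa, se, conf_low, conf_high, scheme, n. `kappa` is `NA`
#'   with a `reason` column entry when the marginals are degenerate (all
#'   mass in one cell).
#' @export
weighted_kappa <- function(tab, scheme = c("quadratic", "linear"),
                           conf_level = 0.95, boot = FALSE, n_boot = 1000,
                           boot_seed = 1L) {
  scheme <- match.arg(scheme)
  tab <- as_pair_table(tab)
  K <- tab$K; n <- tab$n
  p <- tab$counts / n
  d <- if (scheme == "linear") 1 else 2
  idx <- seq_len(K)
  w_dis <- (abs(outer(idx, idx, "-")) / (K - 1))^d
  v <- 1 - w_dis                       # agreement weights
  pr <- rowSums(p); pc <- colSums(p)
  po <- sum(v * p)
  pe <- sum(v * outer(pr, pc))
  if (abs(1 - pe) < 1e-12) {
    return(tibble::tibble(kappa = NA_real_, se = NA_real_,
                          conf_low = NA_real_, conf_high = NA_real_,
                          scheme = scheme, n = n,
                          reason = "degenerate_marginals"))
  }
  kappa <- (po - pe) / (1 - pe)
  vbar_r <- as.vector(v %*% pc)        # row-wise expected agreement weight
  vbar_c <- as.vector(pr %*% v)
  term <- (v - outer(vbar_r, vbar_c, function(a, b) a + b) * (1 - kappa))^2
  varhat <- (sum(p * term) - (kappa - pe * (1 - kappa))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(varhat, 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  lo <- kappa - zq * se
  hi <- kappa + zq * se
  if (boot) {
    set.seed(boot_seed)
    cells <- which(tab$counts > 0, arr.ind = TRUE)
    probs <- tab$counts[cells]
    stats <- vapply(seq_len(n_boot), function(b) {
      draw <- sample.int(nrow(cells), n, replace = TRUE, prob = probs)
      cts <- matrix(0L, K, K)
      for (i in draw) cts[cells[i, 1], cells[i, 2]] <- cts[cells[i, 1], cells[i, 2]] + 1L
      weighted_kappa(cts, scheme, boot = FALSE)$kappa
    }, 1)
    se <- sd(stats, na.rm = TRUE)
    qs <- quantile(stats, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   na.rm = TRUE)
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  tibble::tibble(kappa = kappa, se = se,
                 conf_low = lo, conf_high = hi,
                 scheme = scheme, n = n, reason = NA_character_)
}

# standard bivariate normal CDF P(X <= a, Y <= b; rho) by Gauss-Legendre
# quadrature of the conditioning integral; vectorized over a, b
pbinorm <- function(a, b, rho, nodes = 64) {
  gl <- gauss_legendre(nodes)
  lo <- -8.5
  a <- pmin(pmax(a, lo), 8.5); b <- pmin(pmax(b, lo), 8.5)
  s <- sqrt(1 - rho^2)
  vapply(seq_along(a), function(i) {
    if (a[i] <= lo) return(0)
    mid <- (a[i] + lo) / 2; half <- (a[i] - lo) / 2
    x <- mid + half * gl$x
    fx <- dnorm(x) * pnorm((b[i] - rho * x) / s)
    half * sum(gl$w * fx)
  }, numeric(1))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch), cached
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    out <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
    ord <- order(out$x)
    out <- list(x = out$x[ord], w = out$w[ord])
    cache[[key]] <<- out
    out
  }
})

# cell probabilities of the discretized bivariate normal for thresholds
# (row_t, col_t, each length K-1, finite) at correlation rho
polychoric_cell_probs <- function(row_t, col_t, rho) {
  a <- c(-Inf, row_t, Inf); b <- c(-Inf, col_t, Inf)
  Kr <- length(row_t) + 1; Kc <- length(col_t) + 1
  Phi <- outer(seq_len(Kr + 1), seq_len(Kc + 1),
               function(i, j) pbinorm(a[i], b[j], rho))
  P <- Phi[-1, -1, drop = FALSE] - Phi[-(Kr + 1), -1, drop = FALSE] -
    Phi[-1, -(Kc + 1), drop = FALSE] + Phi[-(Kr + 1), -(Kc + 1), drop = FALSE]
  pmax(P, 0)
}

polychoric_loglik <- function(rho, counts, row_t, col_t) {
  P <- polychoric_cell_probs(row_t, col_t, rho)
  sum(counts[counts > 0] * log(pmax(P[counts > 0], 1e-12)))
}

#' Polychoric correlation
#'
#' Two-step maximum-likelihood estimate of the latent bivariate-normal
#' correlation underlying an ordinal contingency table: thresholds are the
#' inverse-normal transforms of the marginal cumulative proportions, then
#' rho maximizes the bivariate-normal cell-probability likelihood over
#' (-0.999, 0.999). The standard error comes from the numerical second
#' derivative of the profile log-likelihood at the optimum. When an entire
#' row or column category is empty, a +0.5 continuity correction is added to
#' every cell to keep the thresholds finite.
#'
#' @param tab a `pub_pair_table` or count matrix.
#' @return tibble: rho, se, boundary (logical), n; attributes
#'   `row_thresholds`, `col_thresholds`.
#' @export
polychoric <- function(tab) {
  tab <- as_pair_table(tab)
  counts <- tab$counts
  if (sum(rowSums(counts) > 0) < 2 || sum(colSums(counts) > 0) < 2) {
    abort("polychoric needs at least 2 non-empty rows and columns")
  }
  work <- counts
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    work <- counts + 0.5
  }
  n <- sum(work)
  row_t <- qnorm(cumsum(rowSums(work) / n))[seq_len(nrow(work) - 1)]
  col_t <- qnorm(cumsum(colSums(work) / n))[seq_len(ncol(work) - 1)]
  opt <- optimize(polychoric_loglik, c(-0.999, 0.999), counts = work,
                  row_t = row_t, col_t = col_t, maximum = TRUE, tol = 1e-6)
  rho <- opt$maximum
  boundary <- abs(rho) > 0.995
  h <- 1e-3
  ll <- function(r) polychoric_loglik(min(max(r, -0.999), 0.999),
                                      work, row_t, col_t)
  d2 <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  out <- tibble::tibble(rho = rho, se = se, boundary = boundary, n = tab$n)
  attr(out, "row_thresholds") <- row_t
  attr(out, "col_thresholds") <- col_t
  out
}

# map continuous summary scores onto their observed value grid for kappa/rho
discretize_to_grid <- function(x) {
  grid <- sort(unique(x[!is.na(x)]))
  list(codes = match(x, grid), K = length(grid), grid = grid)
}

#' Caregiver-youth agreement report
#'
#' For each sex and each PDS item and summary score, computes the weighted
#' Cohen's kappa (with CI) and the polychoric correlation (with SE) between
#' caregiver and youth report over pairwise-complete children. Continuous
#' summary scores are discretized to their observed value grid; menarche is
#' handled as a binary (K = 2) item.
#'
#' @param cohort raw cohort tibble (for item responses).
#' @param scheme kappa weighting scheme.
#' @return tibble: sex, measure, type, n, kappa, kappa_low, kappa_high,
#'   rho, rho_se, scheme.
#' @export
agreement_report <- function(cohort, scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  cg <- score_pds(cohort, "caregiver")
  yo <- score_pds(cohort, "youth")
  items_by_sex <- list(
    M = c("height", "body_hair", "skin", "voice", "facial_hair"),
    F = c("height", "body_hair", "skin", "breast")
  )
  purrr::map_dfr(intersect(c("M", "F"), unique(cohort$sex)), function(sx) {
    rows <- cohort$sex == sx
    one <- function(measure, x, y, K) {
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2) return(NULL)
      tab <- build_pair_table(x, y, K)
      kp <- weighted_kappa(tab, scheme)
      # degenerate tables (a single observed category on a margin) carry no
      # agreement information; report NA rather than fail the whole table
      rh <- tryCatch(polychoric(tab),
                     error = function(e) tibble::tibble(rho = NA_real_,
                                                       se = NA_real_))
      tibble::tibble(sex = sx, measure = measure, n = tab$n,
                     kappa = kp$kappa, kappa_low = kp$conf_low,
                     kappa_high = kp$conf_high, rho = rh$rho,
                     rho_se = rh$se, scheme = scheme)
    }
    item_rows <- purrr::map_dfr(items_by_sex[[sx]], function(it) {
      x <- pds_code_item(cohort[[paste0("cg_", it)]][rows])
      y <- pds_code_item(cohort[[paste0("y_", it)]][rows])
      one(it, x, y, 4L) %||% tibble::tibble()
    })
    men_rows <- if (sx == "F") {
      x <- pds_code_menarche(cohort$cg_menarche[rows])
      y <- pds_code_menarche(cohort$y_menarche[rows])
      one("menarche", match(x, c(1L, 4L)), match(y, c(1L, 4L)), 2L) %||%
        tibble::tibble()
    } else tibble::tibble()
    score_rows <- purrr::map_dfr(
      c("average_pds", "gonadal", "adrenal", "category_sum"),
      function(sc) {
        x <- cg[[sc]][rows]; y <- yo[[sc]][rows]
        both <- c(x, y)
        g <- discretize_to_grid(both)
        if (g$K < 2) return(tibble::tibble())
        nx <- length(x)
        one(sc, g$codes[seq_len(nx)], g$codes[nx + seq_len(nx)], g$K) %||%
          tibble::tibble()
      })
    dplyr::bind_rows(item_rows, men_rows, score_rows)
  })
}
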