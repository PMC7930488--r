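#' Assemble and standardize variable blocks for group factor analysis
#'
#' Takes named numeric blocks over the same children, optionally
#' natural-log-transforms flagged (strictly positive) variables, then
#' z-scores every variable. The centering/scaling record is kept for
#' back-transformation and reporting.
#'
#' @param blocks named list of numeric matrices / data frames with equal row
#'   counts (rows = children, in the same order).
#' @param log_flags optional named list (by block) of logical vectors
#'   marking variables to log-transform first.
#' @param row_ids optional vector of shared row identifiers.
#' @return object of class `pub_grouped`: list(blocks, row_ids, center,
#'   scale, log_flags).
#' @export
standardize_blocks <- function(blocks, log_flags = NULL, row_ids = NULL) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("blocks must be a named list")
  }
  blocks <- purrr::map(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  n <- unique(vapply(blocks, nrow, 1L))
  if (length(n) != 1) abort("all blocks must have the same number of rows")
  if (n < 2) abort("need at least 2 rows")
  if (any(vapply(blocks, anyNA, TRUE))) {
    abort("blocks must be complete cases (no missing entries)")
  }
  center <- list(); scale <- list()
  for (m in names(blocks)) {
    B <- blocks[[m]]
    lf <- log_flags[[m]] %||% rep(FALSE, ncol(B))
    if (any(lf)) {
      if (any(B[, lf] <= 0)) abort("log flag set on a nonpositive variable")
      B[, lf] <- log(B[, lf])
    }
    mu <- colMeans(B)
    sdv <- apply(B, 2, sd)
    if (any(sdv < 1e-12)) {
      abort(paste0("zero-variance variable in block '", m, "'"))
    }
    blocks[[m]] <- sweep(sweep(B, 2, mu), 2, sdv, "/")
    center[[m]] <- mu; scale[[m]] <- sdv
  }
  structure(list(blocks = blocks, row_ids = row_ids,
                 center = center, scale = scale,
                 log_flags = log_flags),
            class = "pub_grouped")
}

#' Priors for the group factor analysis
#'
#' Gamma priors on the per-(block, factor) ARD precisions alpha and the
#' per-block noise precisions tau; all default to diffuse Gamma(0.01, 0.01).
#'
#' @param ard_shape,ard_rate shape/rate of the ARD Gamma prior.
#' @param noise_shape,noise_rate shape/rate of the noise Gamma prior.
#' @export
gfa_priors <- function(ard_shape = 0.01, ard_rate = 0.01,
                       noise_shape = 0.01, noise_rate = 0.01) {
  vals <- c(ard_shape, ard_rate, noise_shape, noise_rate)
  if (any(vals <= 0)) abort("all hyperparameters must be > 0")
  list(ard_shape = ard_shape, ard_rate = ard_rate,
       noise_shape = noise_shape, noise_rate = noise_rate)
}

#' Gibbs sampler settings for the group factor analysis
#'
#' Defaults (6,000 sweeps, 3,000 burn-in) give stable posterior means at
#' cohort scale (N of a few thousand, a handful of variables) when the
#' factor dimension is kept near the expected rank; unit-scale problems can
#' use far fewer sweeps.
#'
#' @param n_iter total sweeps; `burn_in` discarded; every `thin`-th kept.
#' @param burn_in,thin,seed sampler settings.
#' @export
gfa_mcmc <- function(n_iter = 6000, burn_in = 3000, thin = 5, seed = 1L) {
  if (burn_in >= n_iter) abort("burn_in must be < n_iter")
  if (thin < 1) abort("thin must be >= 1")
  list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
       thin = as.integer(thin), seed = as.integer(seed))
}

#' Fit a Bayesian group factor analysis by Gibbs sampling
#'
#' Model, per block m: x_i^(m) = W^(m) z_i + eps_i^(m), with
#' z_i ~ N(0, I_K), eps ~ N(0, tau_m^-1 I), loadings
#' w_dk^(m) ~ N(0, alpha_mk^-1), ARD precisions alpha_mk ~ Gamma(a0, b0) and
#' noise precisions tau_m ~ Gamma(c0, d0). The ARD hierarchy drives entire
#' (block, factor) loading columns to zero, so factors switch on and off per
#' block and between-block structure separates from within-block structure.
#'
#' The Gibbs sweep alternates: latent scores (joint normal per subject),
#' loadings (joint normal per variable, shared covariance within block), ARD
#' precisions, and noise precisions. Posterior summaries are means over
#' post-burn-in thinned draws; results are reproducible for a fixed seed.
#'
#' @param data a `pub_grouped` object from [standardize_blocks()].
#' @param K number of factors to start with; defaults to the total variable
#'   count (ARD prunes the surplus).
#' @param priors [gfa_priors()].
#' @param mcmc [gfa_mcmc()].
#' @param ve_threshold variance-explained retention threshold (strictly
#'   greater than; default 0.10).
#' @param noise `"block"` (default) for one noise precision per block, the
#'   smallest model consistent with the block structure, or `"variable"`
#'   for a per-variable precision.
#' @return object of class `pub_gfa`: posterior mean scores `Z` (N x K),
#'   per-block loadings `W`, `alpha`, `tau` (per-block list of posterior
#'   mean per-variable noise precisions), per-factor variance explained
#'   `ve` and `ve_by_block`, `retained` factor indices (descending ve),
#'   log-likelihood trace, and the configs.
#' @export
fit_gfa <- function(data, K = NULL, priors = gfa_priors(), mcmc = gfa_mcmc(),
                    ve_threshold = 0.10, noise = c("block", "variable")) {
  noise <- match.arg(noise)
  if (!inherits(data, "pub_grouped")) abort("data must come from standardize_blocks()")
  X <- data$blocks
  M <- length(X)
  N <- nrow(X[[1]])
  D <- vapply(X, ncol, 1L)
  K <- as.integer(K %||% sum(D))
  if (K < 1) abort("K must be >= 1")
  if (N < K) abort("need at least K rows")

  a0 <- priors$ard_shape; b0 <- priors$ard_rate
  c0 <- priors$noise_shape; d0 <- priors$noise_rate
  set.seed(mcmc$seed)

  # warm start from principal components of the concatenated blocks: a
  # small random initialization lets the ARD hierarchy shut factors off
  # before they can pick up moderate structure
  Xall <- do.call(cbind, X)
  sv <- svd(Xall, nu = K, nv = 0)
  Z <- sv$u * sqrt(N)
  if (ncol(Z) < K) Z <- cbind(Z, matrix(rnorm(N * (K - ncol(Z))), N))
  W <- purrr::map(X, function(x) crossprod(x, Z) / N)
  alpha <- matrix(1, M, K)
  tau <- purrr::map(D, ~ rep(1, .x))   # per-variable precisions

  keep <- seq(mcmc$burn_in + 1L, mcmc$n_iter, by = mcmc$thin)
  Z_sum <- matrix(0, N, K)
  W_sum <- purrr::map(X, function(x) matrix(0, ncol(x), K))
  alpha_sum <- matrix(0, M, K)
  tau_sum <- purrr::map(D, ~ rep(0, .x))
  ll_trace <- numeric(length(keep))
  kept <- 0L
  block_ss <- vapply(X, function(x) sum(x^2), 1)
  total_ss <- sum(block_ss)
  ve_sum <- numeric(K)
  veb_sum <- matrix(0, M, K)

  draw_mvn_rows <- function(mean_mat, prec_chol_upper) {
    # rows ~ N(mean_row, Prec^-1) with Prec = R'R (R upper triangular)
    G <- matrix(rnorm(nrow(mean_mat) * ncol(mean_mat)),
                nrow(mean_mat), ncol(mean_mat))
    mean_mat + t(backsolve(prec_chol_upper, t(G)))
  }

  for (it in seq_len(mcmc$n_iter)) {
    # (i) latent scores
    Lam <- diag(K)
    for (m in seq_len(M)) Lam <- Lam + crossprod(W[[m]], W[[m]] * tau[[m]])
    R <- chol(Lam)
    B <- matrix(0, N, K)
    for (m in seq_len(M)) {
      B <- B + sweep(X[[m]], 2, tau[[m]], "*") %*% W[[m]]
    }
    Zmean <- t(backsolve(R, forwardsolve(t(R), t(B))))
    Z <- draw_mvn_rows(Zmean, R)

    ZtZ <- crossprod(Z)
    for (m in seq_len(M)) {
      # (ii) loadings
      if (noise == "block") {
        # shared posterior covariance within the block
        tm <- tau[[m]][1]
        A <- tm * ZtZ + diag(alpha[m, ], K)
        Ra <- chol(A)
        Wmean <- t(backsolve(Ra, forwardsolve(t(Ra), t(tm * crossprod(X[[m]], Z)))))
        W[[m]] <- draw_mvn_rows(Wmean, Ra)
      } else {
        XtZ <- crossprod(X[[m]], Z)
        for (d in seq_len(D[m])) {
          A <- tau[[m]][d] * ZtZ + diag(alpha[m, ], K)
          Ra <- chol(A)
          mu <- backsolve(Ra, forwardsolve(t(Ra), tau[[m]][d] * XtZ[d, ]))
          W[[m]][d, ] <- mu + backsolve(Ra, rnorm(K))
        }
      }
      # (iii) ARD precisions
      ssq <- colSums(W[[m]]^2)
      alpha[m, ] <- rgamma(K, shape = a0 + D[m] / 2, rate = b0 + ssq / 2)
      # (iv) noise precisions
      resid <- X[[m]] - Z %*% t(W[[m]])
      if (noise == "block") {
        tau[[m]][] <- rgamma(1, shape = c0 + N * D[m] / 2,
                             rate = d0 + sum(resid^2) / 2)
      } else {
        tau[[m]] <- rgamma(D[m], shape = c0 + N / 2,
                           rate = d0 + colSums(resid^2) / 2)
      }
    }

    if (!all(is.finite(unlist(tau))) || !all(is.finite(alpha))) {
      abort(paste0("non-finite draw at iteration ", it))
    }

    if (it > mcmc$burn_in && (it - mcmc$burn_in - 1L) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      # the factor basis is identified only up to rotation/sign; align each
      # kept draw to the first kept draw by orthogonal Procrustes before
      # averaging so posterior means are not washed out by basis drift
      Wstack <- do.call(rbind, W)
      if (kept == 1L) {
        ref_stack <- Wstack
      } else {
        sv <- svd(crossprod(Wstack, ref_stack))
        Q <- sv$u %*% t(sv$v)
        Z <- Z %*% Q
        Wstack <- Wstack %*% Q
        ofs <- 0L
        for (m in seq_len(M)) {
          W[[m]] <- Wstack[ofs + seq_len(D[m]), , drop = FALSE]
          ofs <- ofs + D[m]
        }
        # carry the ARD labels through the (near-permutation) rotation
        p <- best_assignment(abs(Q), exact_limit = 4)
        alpha <- alpha[, order(p), drop = FALSE]
      }
      Z_sum <- Z_sum + Z
      for (m in seq_len(M)) W_sum[[m]] <- W_sum[[m]] + W[[m]]
      alpha_sum <- alpha_sum + alpha
      for (m in seq_len(M)) tau_sum[[m]] <- tau_sum[[m]] + tau[[m]]
      # per-draw variance explained (basis-aligned, sign-invariant)
      z2 <- colSums(Z^2)
      ve_draw_blocks <- vapply(W, function(w) z2 * colSums(w^2), numeric(K))
      ve_draw_blocks <- matrix(ve_draw_blocks, nrow = K)
      ve_sum <- ve_sum + rowSums(ve_draw_blocks) / total_ss
      veb_sum <- veb_sum + sweep(t(ve_draw_blocks), 1, block_ss, "/")
      ll <- 0
      for (m in seq_len(M)) {
        resid <- X[[m]] - Z %*% t(W[[m]])
        ll <- ll + 0.5 * N * sum(log(tau[[m]] / (2 * pi))) -
          0.5 * sum(colSums(resid^2) * tau[[m]])
      }
      ll_trace[kept] <- ll
    }
  }

  post <- structure(list(
    Z = Z_sum / kept,
    W = purrr::map(W_sum, ~ .x / kept),
    alpha = alpha_sum / kept,
    tau = purrr::map(tau_sum, ~ .x / kept),
    K = K, N = N, D = D,
    block_names = names(X),
    var_names = purrr::map(X, colnames),
    ll_trace = ll_trace,
    priors = priors, mcmc = mcmc,
    noise_model = noise,
    ve_threshold = ve_threshold,
    # posterior mean of the per-draw variance-explained statistic; using
    # the posterior-mean Z instead would shrink ve for weakly determined
    # scores
    ve = ve_sum / kept,
    ve_by_block = veb_sum / kept
  ), class = "pub_gfa")
  post$retained <- select_factors(post, ve_threshold)
  post
}

#' Per-factor variance explained
#'
#' Fraction of the total (standardized) sum of squares captured by each
#' factor: ve_k = ||Z_k||^2 ||W_k||^2 summed over blocks, divided by the
#' total squared norm of the data, evaluated at the scores/loadings stored
#' in `post`. Note that a fitted `pub_gfa` carries in `$ve` the posterior
#' mean of this statistic over kept draws, which is what retention uses;
#' evaluating the formula at posterior-mean scores (as this function does)
#' understates ve for weakly determined scores.
#'
#' @param post a `pub_gfa` fit.
#' @param data the `pub_grouped` data it was fit to.
#' @return list(ve = per-factor fractions, ve_by_block = block x factor
#'   matrix of fractions of each block's sum of squares).
#' @export
variance_explained <- function(post, data) {
  block_tot <- vapply(data$blocks, function(x) sum(x^2), 1)
  total <- sum(block_tot)
  z2 <- colSums(post$Z^2)
  contrib <- t(vapply(post$W, function(w) z2 * colSums(w^2), numeric(post$K)))
  contrib <- matrix(contrib, nrow = length(post$W))  # blocks x factors
  list(ve = colSums(contrib) / total,
       ve_by_block = contrib / block_tot)
}

#' Retain factors explaining more than a threshold share of variance
#'
#' @param post a `pub_gfa` fit with `ve` computed.
#' @param threshold retention threshold; factors with ve strictly greater
#'   are kept (default 0.10).
#' @return integer factor indices in descending variance-explained order
#'   (the first retained factor is LF1).
#' @export
select_factors <- function(post, threshold = 0.10) {
  keep <- which(post$ve > threshold)
  if (length(keep) == 0) {
    warn("no factor exceeds the variance-explained threshold")
    return(integer(0))
  }
  keep[order(post$ve[keep], decreasing = TRUE)]
}

#' @export
print.pub_gfa <- function(x, ...) {
  cat("Bayesian group factor analysis (Gibbs)\n")
  cat("  blocks:", paste0(x$block_names, " (", x$D, ")", collapse = ", "), "\n")
  cat("  N =", x$N, " K =", x$K, "\n")
  cat("  variance explained:",
      paste0(sprintf("%.1f%%", 100 * sort(x$ve, decreasing = TRUE)[seq_len(min(4, x$K))]),
             collapse = ", "), "...\n")
  cat("  retained factors (>", sprintf("%.0f%%", 100 * x$ve_threshold), "):",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none", "\n")
  invisible(x)
}
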