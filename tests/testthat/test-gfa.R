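test_that("standardization validates and is idempotent", {
  X <- list(a = matrix(rnorm(40), 20, 2), b = matrix(rnorm(20), 20, 1))
  g <- standardize_blocks(X)
  for (b in g$blocks) {
    expect_equal(colMeans(b), rep(0, ncol(b)), tolerance = 1e-12)
    expect_equal(apply(b, 2, sd), rep(1, ncol(b)), tolerance = 1e-8)
  }
  g2 <- standardize_blocks(g$blocks)
  expect_equal(g2$blocks, g$blocks, tolerance = 1e-12)
  # constant column
  Xc <- list(a = cbind(rnorm(20), rep(2, 20)))
  expect_error(standardize_blocks(Xc), "zero-variance")
  # log flag on nonpositive variable
  Xl <- list(a = cbind(c(-1, rexp(19))))
  expect_error(standardize_blocks(Xl, log_flags = list(a = TRUE)),
               "nonpositive")
  expect_error(standardize_blocks(list(matrix(1:4, 2))), "named")
  Xm <- list(a = matrix(c(1, NA, 3, 4), 2))
  expect_error(standardize_blocks(Xm), "complete")
})

test_that("the sampler is reproducible bit-for-bit under a fixed seed", {
  pg <- generate_planted_groups(80, c(4, 3), 2, snr = 10, seed = 1)
  g <- standardize_blocks(pg$data)
  f1 <- fit_gfa(g, mcmc = mcmc_fast(7))
  f2 <- fit_gfa(g, mcmc = mcmc_fast(7))
  expect_identical(f1$Z, f2$Z)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$ve, f2$ve)
  f3 <- fit_gfa(g, mcmc = mcmc_fast(8))
  expect_false(identical(f1$Z, f3$Z))
})

test_that("planted two-factor structure is recovered with high congruence", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)  # group-sparse truth
  pg <- generate_planted_groups(500, c(5, 3), 2, active_mask = mask,
                                snr = 10, seed = 11)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = gfa_mcmc(3000, 1500, 5, 11))
  expect_equal(length(fit$retained), 2)
  L <- do.call(rbind, fit$W)[, fit$retained, drop = FALSE]
  Lt <- do.call(rbind, pg$truth$W_true) / unlist(g$scale)
  for (j in 1:2) {
    cong <- max(abs(apply(L, 2, tucker_congruence, w2 = Lt[, j])))
    expect_gte(cong, 0.9)
  }
})

test_that("ARD shuts off inactive block-factor combinations", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pg <- generate_planted_groups(500, c(5, 3), 2, active_mask = mask,
                                snr = 10, seed = 12)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = gfa_mcmc(3000, 1500, 5, 12))
  ret <- fit$retained
  expect_equal(length(ret), 2)
  # factor 1 is active in both blocks; factor 2 only in the first block
  Lt <- do.call(rbind, pg$truth$W_true) / unlist(g$scale)
  L <- do.call(rbind, fit$W)[, ret, drop = FALSE]
  shared_idx <- ret[which.max(abs(apply(L, 2, tucker_congruence,
                                        w2 = Lt[, 1])))]
  solo_idx <- setdiff(ret, shared_idx)
  norm_inactive <- sqrt(sum(fit$W[[2]][, solo_idx]^2))
  norm_active <- sqrt(sum(fit$W[[2]][, shared_idx]^2))
  expect_lte(norm_inactive / norm_active, 0.1)
})

test_that("a noise-free rank-1 problem keeps exactly one factor", {
  pg <- generate_planted_groups(200, c(4, 3), 1, snr = 1e6, seed = 13)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, K = 4, mcmc = mcmc_fast(13))
  expect_equal(length(fit$retained), 1)
  expect_gt(fit$ve[fit$retained], 0.9)
})

test_that("variance explained behaves analytically", {
  pg <- generate_planted_groups(100, c(3, 2), 2, snr = 10, seed = 14)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = mcmc_fast(14))
  # zero loadings give zero ve
  z <- fit
  z$W <- purrr::map(z$W, ~ .x * 0)
  expect_equal(variance_explained(z, g)$ve, rep(0, fit$K))
  # sign flip leaves ve unchanged
  fl <- fit
  fl$W <- purrr::map(fl$W, function(w) { w[, 1] <- -w[, 1]; w })
  fl$Z[, 1] <- -fl$Z[, 1]
  expect_equal(variance_explained(fl, g)$ve, variance_explained(fit, g)$ve)
})

test_that("factor retention thresholds and ordering are respected", {
  fake <- fake_gfa(list(b1 = matrix(rnorm(12), 3, 4)))
  fake$ve <- c(0.31, 0.16, 0.05, 0.03)
  expect_equal(select_factors(fake, 0.10), c(1L, 2L))
  fake$ve <- c(0.16, 0.31, 0.05, 0.03)
  expect_equal(select_factors(fake, 0.10), c(2L, 1L))  # LF1 = largest
  expect_equal(select_factors(fake, 0), c(2L, 1L, 3L, 4L))
  fake$ve <- c(0.04, 0.02, 0.05, 0.03)
  expect_warning(out <- select_factors(fake, 0.10), "no factor")
  expect_length(out, 0)
})

test_that("reconstruction error decreases with retained-factor count", {
  pg <- generate_planted_groups(300, c(5, 3), 3, snr = 5, seed = 15)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = mcmc_fast(15))
  Xall <- do.call(cbind, g$blocks)
  Wall <- do.call(rbind, fit$W)
  ord <- order(fit$ve, decreasing = TRUE)
  mse <- vapply(1:3, function(k) {
    idx <- ord[seq_len(k)]
    mean((Xall - fit$Z[, idx, drop = FALSE] %*%
            t(Wall[, idx, drop = FALSE]))^2)
  }, 1)
  expect_true(all(diff(mse) < 0))
})

test_that("block order is exchangeable up to labels", {
  pg <- generate_planted_groups(150, c(4, 2), 2, snr = 10, seed = 16)
  g1 <- standardize_blocks(pg$data)
  g2 <- standardize_blocks(rev(pg$data))
  f1 <- fit_gfa(g1, mcmc = mcmc_fast(16))
  f2 <- fit_gfa(g2, mcmc = mcmc_fast(16))
  expect_equal(sort(100 * f1$ve), sort(100 * f2$ve), tolerance = 2)
  expect_equal(f1$block_names, rev(f2$block_names))
})

test_that("configuration guards fire", {
  pg <- generate_planted_groups(10, c(3, 2), 1, snr = 10, seed = 17)
  g <- standardize_blocks(pg$data)
  expect_error(fit_gfa(g, K = 20, mcmc = mcmc_fast(1)), "at least K rows")
  expect_error(gfa_priors(ard_shape = 0), "> 0")
  expect_error(gfa_mcmc(n_iter = 100, burn_in = 200), "burn_in")
})

test_that("tidy, glance and autoplot expose the fit in broom style", {
  pg <- generate_planted_groups(120, c(4, 3), 2, snr = 10, seed = 18)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = mcmc_fast(18))
  td <- tidy(fit)
  expect_true(all(c("block", "variable", "factor", "loading", "ve") %in%
                    names(td)))
  expect_equal(nrow(td), 7 * length(fit$retained))
  gl <- glance(fit)
  expect_equal(gl$n, 120)
  expect_equal(gl$n_retained, length(fit$retained))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("per-variable noise precisions are supported behind a flag", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pg <- generate_planted_groups(300, c(5, 3), 2, active_mask = mask,
                                snr = 10, seed = 21)
  g <- standardize_blocks(pg$data)
  fit <- fit_gfa(g, mcmc = gfa_mcmc(2000, 1000, 5, 21), noise = "variable")
  expect_equal(fit$noise_model, "variable")
  expect_equal(lengths(fit$tau), c(group1 = 5L, group2 = 3L),
               ignore_attr = TRUE)
  expect_equal(length(fit$retained), 2)
  # block mode ties the precisions within a block
  fitb <- fit_gfa(g, mcmc = gfa_mcmc(1000, 500, 5, 21))
  expect_true(all(vapply(fitb$tau, function(t) diff(range(t)) == 0, TRUE)))
})
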