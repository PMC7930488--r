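test_that("Tucker congruence has its defining properties", {
  w <- rnorm(6)
  expect_equal(tucker_congruence(w, w), 1)
  expect_equal(tucker_congruence(w, -w), -1)
  expect_equal(tucker_congruence(w, 3 * w), 1)
  set.seed(1)
  phis <- replicate(50, tucker_congruence(rnorm(8), rnorm(8)))
  expect_true(all(phis >= -1 & phis <= 1))
})

test_that("factor matching recovers permutations and signs on built cases", {
  set.seed(2)
  W1 <- matrix(rnorm(16), 8, 2)
  run1 <- fake_gfa(list(b = W1), retained = 1:2)
  # duplicated run: identity permutation, +1 signs
  al <- match_factors(list(run1, run1))
  expect_equal(al$permutations[2, ], 1:2)
  expect_equal(al$signs[2, ], c(1, 1))
  # swapped and sign-flipped run is unscrambled
  W2 <- W1[, c(2, 1)]; W2[, 1] <- -W2[, 1]
  run2 <- fake_gfa(list(b = W2), retained = 1:2)
  al2 <- match_factors(list(run1, run2))
  expect_equal(al2$permutations[2, ], c(2L, 1L))
  expect_equal(al2$signs[2, ], c(1, -1))
  expect_equal(al2$stack[2, , ], W1, ignore_attr = TRUE)
  # unrelated random loadings flag a low match score
  run3 <- fake_gfa(list(b = matrix(rnorm(16), 8, 2)), retained = 1:2)
  expect_warning(match_factors(list(run1, run3)), "low factor-match")
})

test_that("matching an already-aligned stack is idempotent", {
  set.seed(3)
  W1 <- matrix(rnorm(20), 10, 2)
  runs <- list(fake_gfa(list(b = W1)), fake_gfa(list(b = W1 + 0.01)))
  al1 <- match_factors(runs)
  aligned_runs <- purrr::map(seq_along(runs), function(r) {
    fake_gfa(list(b = al1$stack[r, , ]))
  })
  al2 <- match_factors(aligned_runs)
  expect_equal(al2$stack, al1$stack)
  expect_equal(al2$permutations[2, ], 1:2)
})

test_that("loading summaries collapse correctly across runs", {
  W <- matrix(seq(-1, 1, length.out = 8), 4, 2)
  runs <- list(fake_gfa(list(b = W)), fake_gfa(list(b = W)))
  sm <- summarize_loadings(match_factors(runs))
  expect_equal(sm$median, c(W[, 1], W[, 2]))
  expect_equal(sm$lower, sm$upper)   # zero-width intervals
  # symmetric +/- pair: after sign alignment the median is |x|
  W2 <- -W
  sm2 <- summarize_loadings(match_factors(list(fake_gfa(list(b = W)),
                                               fake_gfa(list(b = W2)))))
  expect_equal(sm2$median, c(W[, 1], W[, 2]))
})

test_that("replicate runs are seeded independently and reproducibly", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pg <- generate_planted_groups(300, c(4, 2), 2, active_mask = mask,
                                snr = 10, seed = 4)
  g <- standardize_blocks(pg$data)
  runs <- replicate_gfa(g, n_rep = 2, base_seed = 5,
                        mcmc = gfa_mcmc(3000, 1500, 5))
  expect_length(runs, 2)
  expect_false(identical(runs[[1]]$Z, runs[[2]]$Z))
  runs2 <- replicate_gfa(g, n_rep = 1, base_seed = 5,
                         mcmc = gfa_mcmc(3000, 1500, 5))
  expect_identical(runs[[1]]$Z, runs2[[1]]$Z)
  expect_true(all(vapply(runs, function(f) length(f$retained), 1L) == 2))
})

test_that("split halves replicate a strongly planted factor structure", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pg <- generate_planted_groups(2000, c(5, 3), 2, active_mask = mask,
                                snr = 10, seed = 6)
  g <- standardize_blocks(pg$data)
  sh <- split_half(g, seed = 6, mcmc = gfa_mcmc(3000, 1500, 5))
  expect_equal(nrow(sh), 2)
  expect_true(all(sh$congruence >= 0.9))
  expect_true(all(sh$replicated))
  # odd N: halves differ by one, no error
  pg2 <- generate_planted_groups(151, c(4, 2), 1, snr = 10, seed = 7)
  g2 <- standardize_blocks(pg2$data)
  sh2 <- split_half(g2, seed = 7, mcmc = mcmc_fast())
  expect_equal(nrow(sh2), 1)
})

test_that("noise covariate extensions leave the base loadings intact", {
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pg <- generate_planted_groups(400, c(5, 3), 2, active_mask = mask,
                                snr = 10, seed = 8)
  g <- standardize_blocks(pg$data)
  set.seed(9)
  ext <- list(noise = matrix(rnorm(400 * 2), 400, 2))
  rep <- covariate_extension(g, ext, mcmc = gfa_mcmc(3000, 1500, 5))
  expect_equal(unique(rep$model), c("base", "noise"))
  expect_true(all(rep$congruence[rep$model == "noise"] >= 0.9))
  # empty extension list reduces to the base report
  rep0 <- covariate_extension(g, list(), mcmc = mcmc_fast())
  expect_equal(unique(rep0$model), "base")
  expect_true(all(rep0$congruence == 1))
  # duplicating a block warns about collinearity
  expect_warning(
    covariate_extension(g, list(dup = g$blocks[[2]]), mcmc = mcmc_fast()),
    "collinear")
})

test_that("synchrony profiles classify the sign quadrants", {
  fake <- fake_gfa(list(b = matrix(rnorm(8), 4, 2)), retained = 1:2, N = 4)
  fake$Z <- matrix(c(1, 1, -1, -1, 1, -1, 1, -1), 4, 2)
  fake$ve <- c(0.3, 0.2)
  pr <- latent_profiles(fake)
  expect_equal(as.character(pr$synchrony),
               c("synchronous_high", "asynchronous_hormone_led",
                 "asynchronous_physical_led", "synchronous_low"))
  # degenerate all-zero scores warn
  fake0 <- fake; fake0$Z <- matrix(0, 4, 2)
  expect_warning(pr0 <- latent_profiles(fake0), "degenerate")
  expect_true(all(is.na(pr0$synchrony)))
  # fewer than two retained factors is an error
  fake1 <- fake; fake1$retained <- 1L
  expect_error(latent_profiles(fake1), "2 retained")
})

test_that("sociodemographic overlays aggregate scores by group", {
  pr <- tibble::tibble(child_id = sprintf("C%02d", 1:6),
                       lf1 = c(1, 2, 3, -1, -2, -3),
                       lf2 = c(1, 1, 1, -1, -1, -1),
                       synchrony = factor("synchronous_high"))
  class(pr) <- c("pub_profiles", class(pr))
  cohort <- tibble::tibble(child_id = sprintf("C%02d", 1:6),
                           sex = "F",
                           weight_status = rep(c("healthy", "obese"), each = 3))
  ov <- sociodemographic_overlay(pr, cohort, "weight_status")
  expect_equal(nrow(ov), 2)
  expect_equal(ov$lf1_mean[ov$group == "healthy"], 2)
  expect_equal(ov$lf1_mean[ov$group == "obese"], -2)
  # empty group logged and omitted
  cohort2 <- dplyr::bind_rows(cohort,
                              tibble::tibble(child_id = "C99", sex = "F",
                                             weight_status = "underweight"))
  expect_message(ov2 <- sociodemographic_overlay(pr, cohort2, "weight_status"),
                 "underweight")
  expect_equal(nrow(ov2), 2)
})
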