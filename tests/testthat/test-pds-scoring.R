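test_that("raw response tokens are coded with missing subtypes preserved", {
  expect_identical(pds_code_item(c("1", "3", "4")), c(1L, 3L, 4L))
  expect_identical(pds_code_item(c("I don't know", "Refuse to answer", NA, "")),
                   rep(NA_integer_, 4))
  expect_identical(pds_missing_subtype(c("I don't know", "Refuse to answer",
                                         NA, "2")),
                   c("idk", "refuse", "blank", NA))
  expect_error(pds_code_item("maybe"), "unrecognized")
  expect_identical(pds_code_menarche(c("yes", "no", "I don't know")),
                   c(4L, 1L, NA_integer_))
  expect_error(pds_code_menarche("sometimes"), "unrecognized")
})

test_that("average PDS applies the more-than-one-missing exclusion", {
  # female: items 2,2,2,2 + menarche no (coded 1) -> (2+2+2+2+1)/5 = 1.8
  f <- c(height = 2L, body_hair = 2L, skin = 2L, breast = 2L)
  expect_equal(pds_average(f, "F", menarche = 1L)$value, 1.8)
  # male with one idk item: mean of remaining four
  m <- c(height = 1L, body_hair = 1L, skin = 1L, facial_hair = 1L,
         voice = NA_integer_)
  a <- pds_average(m, "M")
  expect_equal(a$value, 1)
  expect_equal(a$n_missing, 1L)
  # two missing -> undefined with reason
  m2 <- c(height = 1L, body_hair = 1L, skin = NA_integer_,
          facial_hair = NA_integer_, voice = 1L)
  a2 <- pds_average(m2, "M")
  expect_true(is.na(a2$value))
  expect_equal(a2$reason, "too_many_missing")
})

test_that("gonadal and adrenal sub-scores exclude on any missing constituent", {
  f <- c(height = 2L, body_hair = 3L, skin = 2L, breast = 3L)
  expect_equal(pds_gonadal(f, "F", menarche = 1L), 2)
  m <- c(height = 4L, body_hair = 2L, skin = NA_integer_, facial_hair = 4L,
         voice = 4L)
  expect_equal(pds_gonadal(m, "M"), 4)
  expect_true(is.na(pds_adrenal(m, "M")))
  expect_equal(pds_adrenal(c(body_hair = 2L, skin = 2L), "M"), 2)
  # menarche missing kills the female gonadal score
  expect_true(is.na(pds_gonadal(f, "F", menarche = NA_integer_)))
})

test_that("puberty category matches the quoted cut-offs at the corners", {
  m_pre <- pds_category("M", body_hair = 1, voice = 1, facial_hair = 1)
  expect_equal(m_pre$category_sum, 3L)
  expect_equal(as.character(m_pre$category), "prepubertal")
  m_post <- pds_category("M", body_hair = 4, voice = 4, facial_hair = 4)
  expect_equal(m_post$category_sum, 12L)
  expect_equal(as.character(m_post$category), "post")
  f_post <- pds_category("F", body_hair = 4, breast = 4, menarche = 4)
  expect_equal(f_post$category_sum, 8L)
  expect_equal(as.character(f_post$category), "post")
  f_pre <- pds_category("F", body_hair = 1, breast = 1, menarche = 1)
  expect_equal(f_pre$category_sum, 2L)
  expect_equal(as.character(f_pre$category), "prepubertal")
  # escalation: sum 5 containing a 3-point response is midpubertal
  expect_equal(as.character(pds_category("M", 1, 1, 3)$category), "mid")
  # menarche forces late even at the smallest sum
  expect_equal(as.character(pds_category("F", body_hair = 1, breast = 1,
                                         menarche = 4)$category), "late")
  # missing constituents -> undefined
  expect_true(is.na(pds_category("M", 1, NA, 1)$category))
  expect_true(is.na(pds_category("F", body_hair = 2, breast = 2,
                                 menarche = NA)$category))
})

test_that("category agrees with the exhaustive lookup oracle everywhere", {
  grid_m <- expand.grid(bh = 1:4, vo = 1:4, fh = 1:4)
  got <- pds_category("M", grid_m$bh, grid_m$vo, grid_m$fh)
  want <- mapply(oracle_male_category, grid_m$bh, grid_m$vo, grid_m$fh)
  expect_identical(as.character(got$category), unname(want))

  grid_f <- expand.grid(bh = 1:4, br = 1:4, men = c(FALSE, TRUE))
  got_f <- pds_category("F", body_hair = grid_f$bh, breast = grid_f$br,
                        menarche = ifelse(grid_f$men, 4L, 1L))
  want_f <- mapply(oracle_female_category, grid_f$bh, grid_f$br, grid_f$men)
  expect_identical(as.character(got_f$category), unname(want_f))
})

test_that("category is monotone under any single-item increase", {
  lev <- pds_category_levels <- c("prepubertal", "early", "mid", "late", "post")
  rank_m <- function(bh, vo, fh) {
    match(as.character(pds_category("M", bh, vo, fh)$category), lev)
  }
  grid <- expand.grid(bh = 1:4, vo = 1:4, fh = 1:4)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$bh < 4) expect_gte(rank_m(g$bh + 1, g$vo, g$fh), rank_m(g$bh, g$vo, g$fh))
    if (g$vo < 4) expect_gte(rank_m(g$bh, g$vo + 1, g$fh), rank_m(g$bh, g$vo, g$fh))
    if (g$fh < 4) expect_gte(rank_m(g$bh, g$vo, g$fh + 1), rank_m(g$bh, g$vo, g$fh))
  }
  rank_f <- function(bh, br, men) {
    match(as.character(pds_category("F", body_hair = bh, breast = br,
                                    menarche = men)$category), lev)
  }
  grid_f <- expand.grid(bh = 1:4, br = 1:4, men = c(1L, 4L))
  for (i in seq_len(nrow(grid_f))) {
    g <- grid_f[i, ]
    if (g$bh < 4) expect_gte(rank_f(g$bh + 1, g$br, g$men), rank_f(g$bh, g$br, g$men))
    if (g$br < 4) expect_gte(rank_f(g$bh, g$br + 1, g$men), rank_f(g$bh, g$br, g$men))
    if (g$men == 1L) expect_gte(rank_f(g$bh, g$br, 4L), rank_f(g$bh, g$br, 1L))
  }
})

test_that("table-level scoring propagates missing and respects reporters", {
  co <- toy_cohort(4)
  co$y_height[1] <- NA; co$y_body_hair[1] <- NA; co$y_skin[1] <- NA
  co$y_facial_hair[1] <- NA; co$y_voice[1] <- NA
  sy <- score_pds(co, "youth")
  expect_true(all(is.na(sy[1, c("average_pds", "gonadal", "adrenal",
                                "category_sum")])))
  # identical caregiver and youth responses -> identical summaries
  sc <- score_pds(co, "caregiver")
  sy2 <- score_pds(co, "youth")
  expect_equal(sc[2:4, c("average_pds", "gonadal", "adrenal", "category_sum")],
               sy2[2:4, c("average_pds", "gonadal", "adrenal", "category_sum")])
  # all-1 responses, no menarche -> every category prepubertal
  co1 <- toy_cohort(4)
  for (cn in grep("^cg_", names(co1), value = TRUE)) {
    co1[[cn]][!is.na(co1[[cn]])] <- ifelse(cn == "cg_menarche", "no", "1")
  }
  s1 <- score_pds(co1, "caregiver")
  expect_true(all(s1$category == "prepubertal"))
  # schema error names the missing columns
  expect_error(score_pds(dplyr::select(co, -"cg_height"), "caregiver"),
               "cg_height")
})
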