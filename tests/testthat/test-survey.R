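test_that("item catalog matches the instrument's structure", {
  cat_df <- sc_item_catalog()
  expect_equal(nrow(cat_df), 13L)
  expect_equal(sum(cat_df$dimension == "cognitive"), 9L)
  expect_equal(sum(cat_df$dimension == "bonding"), 4L)
  counts <- table(cat_df$subdomain)
  expect_equal(as.integer(counts[c("trust", "reciprocity", "social_norms",
                                   "participation", "membership")]),
               c(1L, 4L, 4L, 3L, 1L))
  expect_true(all(cat_df$calib_mean > 1 & cat_df$calib_mean < 4))
  expect_true(all(cat_df$calib_sd > 0))
})

test_that("standardization centers and scales each item (n-1 denominator)", {
  d <- tiny_respondents(n = 2)  # responses (1, 3) on every item
  z <- standardize_items(d)
  # hand oracle: x = (1,3), mean 2, sample sd sqrt(2) -> z = -/+ 1/sqrt(2)
  expect_equal(unname(z[, "trust_honest"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  d4 <- tiny_respondents(n = 50)
  d4[] <- lapply(d4, function(col) col)  # keep structure
  set.seed(7)
  for (it in sc_item_catalog()$item_id)
    d4[[it]] <- sample(1:4, 50, replace = TRUE)
  z4 <- standardize_items(d4)
  expect_true(all(abs(colMeans(z4)) < 1e-12))
  expect_true(all(abs(apply(z4, 2, sd) - 1) < 1e-12))
})

test_that("degenerate and incomplete inputs raise informative errors", {
  d <- tiny_respondents(n = 4)
  d$trust_honest <- 2L
  expect_error(standardize_items(d), "degenerate.*trust_honest")
  d2 <- tiny_respondents(n = 4)
  d2$memb_org <- NULL
  expect_error(standardize_items(d2), "missing item.*memb_org")
  expect_error(standardize_items(tiny_respondents(n = 1)), "at least two")
})

test_that("indices are means of z-scores; aggregate = cognitive + bonding", {
  set.seed(11)
  d <- tiny_respondents(n = 40)
  for (it in sc_item_catalog()$item_id) d[[it]] <- sample(1:4, 40, replace = TRUE)
  scored <- score_survey(d)
  expect_equal(scored$sc_aggregate, scored$sc_cognitive + scored$sc_bonding,
               tolerance = 1e-12)
  expect_equal(mean(scored$sc_cognitive), 0, tolerance = 1e-12)
  expect_equal(mean(scored$sc_bonding), 0, tolerance = 1e-12)

  z <- standardize_items(d)
  cat_df <- sc_item_catalog()
  expect_equal(scored$sc_cognitive,
               rowMeans(z[, cat_df$item_id[cat_df$dimension == "cognitive"]]),
               tolerance = 1e-12)
})

test_that("indices are invariant to adding a constant to all raw scores", {
  set.seed(13)
  d <- tiny_respondents(n = 30)
  for (it in sc_item_catalog()$item_id) d[[it]] <- sample(1:3, 30, replace = TRUE)
  shifted <- d
  for (it in sc_item_catalog()$item_id) shifted[[it]] <- shifted[[it]] + 1L
  expect_equal(score_survey(d)$sc_cognitive, score_survey(shifted)$sc_cognitive,
               tolerance = 1e-12)
})

test_that("reverse coding flips exactly the negatively keyed item", {
  set.seed(17)
  d <- tiny_respondents(n = 30)
  for (it in sc_item_catalog()$item_id) d[[it]] <- sample(1:4, 30, replace = TRUE)
  z_plain <- standardize_items(d, sc_item_catalog())
  z_rev <- standardize_items(d, sc_item_catalog(reverse_negative_items = TRUE))
  expect_equal(z_rev[, "recip_advantage"], -z_plain[, "recip_advantage"],
               tolerance = 1e-12)
  expect_equal(z_rev[, "trust_honest"], z_plain[, "trust_honest"], tolerance = 1e-12)
})

test_that("group index averages members and rejects wrong sizes", {
  m <- data.frame(sc_cognitive = c(0.2, 0.2, 0.2, 0.7, 0.2),
                  sc_bonding = c(1, -1, 0, 0, 0))
  gi <- group_index(m)
  expect_equal(gi$sc_cognitive, 0.3)
  expect_equal(gi$sc_bonding, 0)
  expect_equal(gi$sc_aggregate, 0.3)
  same <- data.frame(sc_cognitive = rep(0.4, 5), sc_bonding = rep(-0.1, 5))
  expect_equal(group_index(same)$sc_cognitive, 0.4)
  expect_error(group_index(m[1:4, ]), "invalid group")
})

test_that("determinants regression recovers the configured family-size loading", {
  cfg <- cohort_config(n = 2000L, seed = 5)
  d <- score_survey(generate_respondents(cfg))
  det <- sc_determinants(d)
  b_fam <- det$fits$sc_cognitive$coefficients["family_size", "Estimate"]
  expect_lt(abs(b_fam - 0.263), 0.05)
  # bonding R^2 lands in the plausible band at the study's n with defaults
  r2 <- sapply(1:10, function(s) {
    ds <- score_survey(generate_respondents(cohort_config(n = 210L, seed = 500 + s)))
    sc_determinants(ds)$fits$sc_bonding$r_squared
  })
  expect_gt(mean(r2), 0.1)
  expect_lt(mean(r2), 0.4)
})

test_that("with zero loadings, demographic slopes are null in most replicates", {
  cfg0 <- function(seed) cohort_config(
    n = 210L, seed = seed,
    loadings_cognitive = c(log_income = 0, family_size = 0),
    loadings_bonding = c(schooling = 0, landholding = 0, family_size = 0, female = 0))
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    d <- score_survey(generate_respondents(cfg0(1000L + s)))
    det <- sc_determinants(d)
    for (out in names(det$fits)) {
      co <- det$fits[[out]]$coefficients
      co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
      hits <- hits + sum(abs(co[, "Estimate"]) <= 2 * co[, "Std. Error"])
      total <- total + nrow(co)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("determinants regression validates its inputs", {
  d <- score_survey(generate_respondents(cohort_config(n = 50L, seed = 3)))
  expect_error(sc_determinants(d[1:10, ]), "at least 20")
  d3 <- d; d3$landholding <- 2 * d3$age + 1  # exact collinearity
  expect_error(sc_determinants(d3), "rank deficient|collinear")
})
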