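# minimal hand-built round records: 2 groups, 1 voting session each + one
# excluded shuffling session
mini_records <- function() {
  base <- expand.grid(round = 1:3, member = 1:5, group_id = c("gA", "gB"),
                      stringsAsFactors = FALSE)
  base$respondent_id <- paste0(base$group_id, "_m", base$member)
  base$session <- 3L
  base$scenario <- ifelse(base$group_id == "gA", "voting_shuffling",
                          "voting_shuffling_reputation")
  base$sequence <- 1L
  base$group_target <- 18L - 2L * base$round
  base$extraction <- base$group_target - ifelse(base$group_id == "gB", 3L, 1L)
  base$prior_wounds <- 0L
  base$payoff <- 0
  base$sc_cognitive <- 0.1 * base$member - 0.3
  base$sc_bonding <- 0.05 * base$member - 0.15
  base$sc_cognitive_grp <- ifelse(base$group_id == "gA", 0.2, -0.2)
  base$sc_bonding_grp <- 0
  base$analysis_excluded <- FALSE
  excl <- base[base$round == 1 & base$session == 3, ]
  excl$session <- 1L; excl$scenario <- "shuffling"
  excl$analysis_excluded <- TRUE; excl$group_target <- NA
  rbind(base, excl)
}

test_that("panel construction yields the right shapes at all four levels", {
  rec <- mini_records()
  gr <- build_panel(rec, "group_round")
  expect_equal(nrow(gr), 2L * 3L)                # 2 groups x 1 session x 3 rounds
  expect_equal(sum(gr$period2) + sum(gr$period3), nrow(gr) - sum(gr$round == 1))
  gs <- build_panel(rec, "group_session")
  expect_equal(nrow(gs), 2L)
  expect_equal(sort(gs$target), sort(tapply(gr$target, gr$group_id, sum)),
               ignore_attr = TRUE)               # session outcome = round sum
  ir <- build_panel(rec, "individual_round")
  expect_equal(nrow(ir), 2L * 5L * 3L)
  expect_true(all(c("target", "extraction") %in% names(ir)))
  is <- build_panel(rec, "individual_session")
  expect_equal(nrow(is), 10L)
  # excluded sessions never appear
  expect_false(any(build_panel(rec, "individual_round")$session == 1L))
  expect_error(build_panel(rec[rec$analysis_excluded, ], "group_round"),
               "empty panel")
})

test_that("session-level outcomes can switch from sums to means", {
  rec <- mini_records()
  gs_sum <- build_panel(rec, "group_session", session_stat = "sum")
  gs_mean <- build_panel(rec, "group_session", session_stat = "mean")
  expect_equal(gs_sum$target, 3 * gs_mean$target)
})

test_that("the random-intercept fit identifies a noiseless continuous structure exactly", {
  coh <- small_cohort(n = 60L, seed = 9)
  gc0 <- game_config(seed = 10, sd_group_target = 0, sd_idio_target = 0,
                     sd_group_extraction = 0, sd_idio_extraction = 0,
                     discretize = FALSE)
  rec <- simulate_experiment(coh, gc0, sessions = 3:6, envelope = FALSE)
  fx <- fit_panel_re(default_formula("individual_round"),
                     build_panel(rec, "individual_round"))
  xc <- gc0$extraction_coefs
  expect_equal(unname(coef(fx)["target"]), unname(xc["group_target"]), tolerance = 1e-8)
  expect_equal(unname(coef(fx)["reputation"]), unname(xc["reputation"]), tolerance = 1e-8)
  expect_equal(unname(coef(fx)["(Intercept)"]), unname(xc["intercept"]), tolerance = 1e-8)
})

test_that("FGLS and ML variance components give nearly identical fixed effects", {
  coh <- small_cohort(n = 60L, seed = 12)
  rec <- simulate_experiment(coh, game_config(seed = 14), sessions = 3:6)
  panel <- build_panel(rec, "individual_round")
  f <- default_formula("individual_round")
  fg <- fit_panel_re(f, panel, method = "fgls")
  ml <- fit_panel_re(f, panel, method = "ml")
  expect_lt(max(abs(coef(fg) - coef(ml))), 0.05)
  expect_lt(abs(fg$sigma_u - ml$sigma_u), 0.5)
  expect_gt(fg$sigma_u, 0)
})

test_that("group clustering widens inference for group-constant regressors", {
  coh <- small_cohort(n = 210L, seed = 16)
  rec <- simulate_experiment(coh, game_config(seed = 18), sessions = 3:6)
  panel <- build_panel(rec, "group_round")
  f <- default_formula("group_round")
  fit <- fit_panel_re(f, panel)
  naive <- summary(lm(f, data = panel))$coefficients
  # pooled-OLS classical SEs understate uncertainty for the social-capital
  # indices, which vary only between groups
  expect_gt(unname(fit$se["sc_cognitive"]), naive["sc_cognitive", "Std. Error"])
  expect_gt(unname(fit$se["sc_bonding"]), naive["sc_bonding", "Std. Error"])
})

test_that("configured period shifts are covered by 2 clustered SEs in most replicates", {
  hits <- 0L
  n_reps <- 20L
  reps <- recovery_study(n_reps, seed = 2024, what = "target", keep_se = TRUE)
  for (nm in c("target.period2", "target.period3")) {
    truth <- if (nm == "target.period2") -2.431 else -5.299
    hits <- hits + sum(abs(reps[[nm]] - truth) <= 2 * reps[[paste0(nm, ".se")]])
  }
  expect_gte(hits / (2L * n_reps), 0.9)
})

test_that("fit accessors, printing and validation behave", {
  coh <- small_cohort(n = 30L, seed = 19)
  rec <- simulate_experiment(coh, game_config(seed = 20), sessions = 3:6)
  panel <- build_panel(rec, "group_round")
  fit <- fit_panel_re(default_formula("group_round"), panel)
  expect_equal(length(coef(fit)), ncol(vcov(fit)))
  expect_equal(nobs(fit), nrow(panel))
  expect_output(print(fit), "Random-intercept")
  expect_output(print(summary(fit)), "clustered at group level")
  panel$dup <- panel$sc_cognitive
  expect_error(fit_panel_re(target ~ sc_cognitive + dup, panel), "collinear")
  expect_error(fit_panel_re(default_formula("group_round"), panel, group = "nope"),
               "no such group")
})

test_that("the gap test is directional, validated, and degenerate-safe", {
  rec <- mini_records()
  # gB (reputation) has gap 3, gA (private) has gap 1, both constant
  gt <- gap_test(rec)
  expect_true(is.infinite(gt$statistic) && gt$statistic > 0)
  # identical gap distributions => t ~ 0
  rec2 <- mini_records()
  rec2$extraction <- rec2$group_target - rep(c(1L, 2L, 1L, 2L, 1L),
                                             length.out = nrow(rec2))
  expect_lt(abs(gap_test(rec2)$statistic), 1e-8)
  one <- mini_records()
  one <- one[one$scenario != "voting_shuffling_reputation", ]
  expect_error(gap_test(one), "invalid comparison")
})

test_that("round summaries carry the 10-wound benchmark and drop absent scenarios", {
  rec <- mini_records()
  s <- summarize_rounds(rec)
  expect_true(all(s$benchmark == 10))
  expect_equal(nrow(s), 6L)  # 2 scenarios x 3 rounds
  only_vs <- rec[rec$scenario != "voting_shuffling_reputation", ]
  s2 <- summarize_rounds(only_vs)
  expect_false("voting_shuffling_reputation" %in% s2$scenario)
  # zero-noise calibrated run: round-1 mean target is 17 at zero social capital
  coh <- small_cohort(n = 30L, seed = 25)
  coh$respondents$sc_cognitive_grp <- 0
  coh$respondents$sc_bonding_grp <- 0
  rec0 <- simulate_experiment(coh, game_config(seed = 26, sd_group_target = 0,
                                               sd_idio_target = 0), sessions = 3:6)
  s0 <- summarize_rounds(rec0)
  expect_true(all(s0$mean_target[s0$round == 1] == 17))
})
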