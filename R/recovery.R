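#' Monte Carlo parameter-recovery study
#'
#' Repeatedly (i) generates a fresh cohort, (ii) simulates the experiment from
#' the calibrated target/extraction structures, and (iii) re-estimates the
#' round-level equations with [fit_panel_re()], returning the per-replicate
#' estimates. Used to check that the estimation pipeline recovers the
#' configured coefficients (the published values as the data-generating truth)
#' and, with the social-capital coefficients zeroed, that the null is covered.
#'
#' Only the voting sessions are simulated: the structural sessions 1-2 never
#' enter the analysis panel.
#'
#' @param n_reps number of replicates.
#' @param seed master seed; replicate seeds are derived from it.
#' @param cohort_cfg a [cohort_config()] (its seed field is overridden per
#'   replicate).
#' @param game_cfg a [game_config()] (ditto).
#' @param what `"both"`, `"target"` (group-round equation only, faster) or
#'   `"extraction"`.
#' @param method estimator passed to [fit_panel_re()].
#' @param keep_se also return the cluster-robust SEs (needed for coverage
#'   checks).
#' @param envelope passed to [simulate_experiment()]. The default `FALSE`
#'   simulates from the bare linear structures (the process the estimator
#'   assumes, and the recovery question being asked); `TRUE` adds the physical
#'   card-envelope limit, whose round-3 censoring attenuates the
#'   extraction-equation coefficients.
#' @return A data frame with one row per replicate; columns
#'   `target.<coef>` and/or `extraction.<coef>` (and `.se` twins when
#'   `keep_se`).
#' @export
recovery_study <- function(n_reps, seed = 1L,
                           cohort_cfg = cohort_config(),
                           game_cfg = game_config(),
                           what = c("both", "target", "extraction"),
                           method = "fgls", keep_se = FALSE, envelope = FALSE) {
  what <- match.arg(what)
  seeds <- derive_seeds(seed, 2L * n_reps)
  f_t <- default_formula("group_round")
  f_x <- default_formula("individual_round")
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cc <- cohort_cfg; cc$seed <- seeds[2L * i - 1L]
    gc <- game_cfg; gc$seed <- seeds[2L * i]
    coh <- generate_cohort(cc)
    rec <- simulate_experiment(coh, gc, sessions = 3:6, envelope = envelope)
    out <- list()
    if (what != "extraction") {
      ft <- fit_panel_re(f_t, build_panel(rec, "group_round"), method = method)
      out <- c(out, setNames(as.list(coef(ft)), paste0("target.", names(coef(ft)))))
      if (keep_se)
        out <- c(out, setNames(as.list(ft$se), paste0("target.", names(ft$se), ".se")))
    }
    if (what != "target") {
      fx <- fit_panel_re(f_x, build_panel(rec, "individual_round"), method = method)
      out <- c(out, setNames(as.list(coef(fx)), paste0("extraction.", names(coef(fx)))))
      if (keep_se)
        out <- c(out, setNames(as.list(fx$se), paste0("extraction.", names(fx$se), ".se")))
    }
    rows[[i]] <- as.data.frame(out, check.names = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize a recovery study against the configured truth
#'
#' @param reps output of [recovery_study()].
#' @param truth named vector of true values, names as in `reps` columns.
#' @return Data frame with `truth`, `mean_estimate`, `mc_se` (Monte Carlo
#'   standard error of the mean estimate) and `bias` per coefficient.
#' @export
recovery_summary <- function(reps, truth) {
  miss <- setdiff(names(truth), names(reps))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  est <- vapply(names(truth), function(nm) mean(reps[[nm]]), numeric(1))
  mcse <- vapply(names(truth), function(nm) sd(reps[[nm]]) / sqrt(nrow(reps)), numeric(1))
  data.frame(coefficient = names(truth), truth = unname(truth),
             mean_estimate = unname(est), mc_se = unname(mcse),
             bias = unname(est - truth), row.names = NULL)
}
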