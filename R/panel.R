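#' Build an analysis panel from round records
#'
#' Drops the structural (non-analysed) shuffling sessions, then arranges the
#' voting-session records at one of four levels:
#'
#' * `"group_round"`: one row per group x session x round, outcome `target`.
#' * `"group_session"`: one row per group x session, outcome = session **sum**
#'   of round targets (the session total reads as extraction over the tree's
#'   lifetime; switch to means with `session_stat = "mean"`).
#' * `"individual_round"`: one row per member-round, outcome `extraction`,
#'   with the round's `target` as a regressor.
#' * `"individual_session"`: one row per member x session, outcome = session
#'   sum of extraction, with the session target total as regressor.
#'
#' Round dummies `period2`, `period3` reference round 1; session dummies
#' (`session4` ... by calendar session) reference the first voting session.
#' `sc_cognitive` / `sc_bonding` are the group indices at group level and the
#' individual indices at individual level. `reputation` flags the
#' public-disclosure scenario.
#'
#' @param records round records from [simulate_experiment()].
#' @param level panel level, see above.
#' @param session_stat `"sum"` (default) or `"mean"` for session outcomes.
#' @return A data frame with attribute `"level"`.
#' @export
build_panel <- function(records,
                        level = c("group_round", "group_session",
                                  "individual_round", "individual_session"),
                        session_stat = c("sum", "mean")) {
  level <- match.arg(level)
  session_stat <- match.arg(session_stat)
  v <- records[!records$analysis_excluded &
                 records$scenario != "shuffling", , drop = FALSE]
  if (nrow(v) == 0L) stop("empty panel: no voting-session records", call. = FALSE)
  v$reputation <- as.numeric(v$scenario == "voting_shuffling_reputation")
  stat_fun <- if (session_stat == "sum") sum else mean

  if (level %in% c("group_round", "group_session")) {
    key <- c("group_id", "session")
    g <- v[!duplicated(v[, c(key, "round")]), , drop = FALSE]
    g$sc_cognitive <- g$sc_cognitive_grp
    g$sc_bonding <- g$sc_bonding_grp
    if (level == "group_round") {
      out <- g[, c("group_id", "session", "round", "reputation",
                   "sc_cognitive", "sc_bonding", "group_target")]
      names(out)[names(out) == "group_target"] <- "target"
      out$period2 <- as.numeric(out$round == 2L)
      out$period3 <- as.numeric(out$round == 3L)
    } else {
      agg <- aggregate(group_target ~ group_id + session + reputation +
                         sc_cognitive + sc_bonding, data = g, FUN = stat_fun)
      names(agg)[names(agg) == "group_target"] <- "target"
      out <- agg
    }
  } else {
    v$sc_cognitive <- v$sc_cognitive  # individual-level indices as-is
    if (level == "individual_round") {
      out <- v[, c("group_id", "respondent_id", "session", "round", "reputation",
                   "sc_cognitive", "sc_bonding", "group_target", "extraction")]
      names(out)[names(out) == "group_target"] <- "target"
      out$period2 <- as.numeric(out$round == 2L)
      out$period3 <- as.numeric(out$round == 3L)
    } else {
      out <- aggregate(cbind(extraction, group_target) ~
                         group_id + respondent_id + session + reputation +
                         sc_cognitive + sc_bonding, data = v, FUN = stat_fun)
      names(out)[names(out) == "group_target"] <- "target"
    }
  }
  if (grepl("session$", level)) {
    ref <- min(out$session)
    for (s in sort(unique(out$session))) {
      if (s == ref) next
      out[[paste0("session", s)]] <- as.numeric(out$session == s)
    }
  }
  out <- out[order(out$group_id, out$session,
                   if ("round" %in% names(out)) out$round else out$session), ]
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Default regression formula for a panel level
#'
#' Round-level specifications include period dummies and social-capital x
#' period interactions; session-level ones use calendar-session dummies.
#' Individual-level specifications add the group target (adherence slope).
#' `interactions = TRUE` adds the social-capital x reputation terms.
#'
#' @param level panel level as in [build_panel()].
#' @param panel the built panel (needed to name the session dummies).
#' @param interactions include social-capital x reputation interactions.
#' @return A formula.
#' @export
default_formula <- function(level, panel = NULL, interactions = FALSE) {
  base <- c("reputation", "sc_cognitive", "sc_bonding")
  if (grepl("round$", level)) {
    base <- c(base, "period2", "period3",
              "sc_cognitive:period2", "sc_cognitive:period3",
              "sc_bonding:period2", "sc_bonding:period3")
  } else {
    sdum <- if (!is.null(panel)) grep("^session[0-9]+$", names(panel), value = TRUE)
            else character(0)
    base <- c(base, sdum)
  }
  if (interactions) base <- c(base, "sc_cognitive:reputation", "sc_bonding:reputation")
  lhs <- if (grepl("^group", level)) "target" else "extraction"
  if (grepl("^individual", level)) base <- c("target", base)
  stats::reformulate(base, response = lhs)
}

#' Random-intercept panel regression with group-clustered errors
#'
#' Fits a linear model with a group-level random intercept and reports
#' cluster-robust (CR1, clustered by group) standard errors, the convention of
#' the study's regression tables. Two variance-component estimators are
#' offered: `"fgls"` (Swamy-Arora feasible GLS: within and between residual
#' variances, then quasi-demeaning) and `"ml"` (maximum likelihood via
#' [lme4::lmer()], with the GLS step and the clustered sandwich computed from
#' the ML variance components). Inference uses t statistics on
#' `n_groups - 1` degrees of freedom.
#'
#' @param formula model formula in the panel's columns (see
#'   [default_formula()]).
#' @param data panel data frame from [build_panel()].
#' @param group name of the cluster/random-intercept column (default
#'   `"group_id"`).
#' @param method `"fgls"` or `"ml"`.
#' @return An object of class `"re_fit"` with `coefficients`, `se`
#'   (cluster-robust), `se_classical`, `vcov`, `sigma_u` (random-intercept
#'   SD), `sigma_e`, `r_squared` (squared correlation of outcome and fixed
#'   linear predictor), `n`, `n_groups`.
#' @export
fit_panel_re <- function(formula, data, group = "group_id",
                         method = c("fgls", "ml")) {
  method <- match.arg(method)
  if (!group %in% names(data)) stop("no such group column: ", group, call. = FALSE)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  g <- factor(data[[group]][match(rownames(mf), rownames(data))])
  n <- length(y); k <- ncol(X); G <- nlevels(g)
  if (G < 2L) stop("need at least two groups", call. = FALSE)
  if (qr(X)$rank < k)
    stop("collinear regressors: design matrix is rank deficient", call. = FALSE)

  Tg <- tabulate(g)
  if (method == "fgls") {
    # within-group residual variance
    yw <- y - ave(y, g)
    Xw <- X - apply(X, 2L, ave, g)
    keep <- apply(Xw, 2L, function(col) sd(col) > 1e-10)
    kw <- sum(keep)
    if (kw > 0L) {
      fw <- lm.fit(Xw[, keep, drop = FALSE], yw)
      rss_w <- sum(fw$residuals^2)
    } else rss_w <- sum(yw^2)
    sigma_e2 <- max(rss_w / max(n - G - kw, 1L), 1e-10)
    # between regression on group means
    ym <- tapply(y, g, mean)
    Xm <- apply(X, 2L, tapply, g, mean)
    qb <- qr(Xm)
    kb <- qb$rank
    rss_b <- sum(qr.resid(qb, ym)^2)
    sigma_b2 <- rss_b / max(G - kb, 1L)
    Tbar <- G / sum(1 / Tg)      # harmonic mean group size
    sigma_u2 <- max(0, sigma_b2 - sigma_e2 / Tbar)
  } else {
    Xdf <- as.data.frame(X[, -1, drop = FALSE])
    names(Xdf) <- colnames(X)[-1]
    dd <- cbind(data.frame(.y = y), Xdf, data.frame(.g = g))
    lf <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(Xdf)), collapse = "+"),
                                  "+ (1|.g)"))
    fit_ml <- lme4::lmer(lf, data = dd, REML = FALSE,
                         control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- lme4::VarCorr(fit_ml)
    sigma_u2 <- as.numeric(vc$.g)
    sigma_e2 <- stats::sigma(fit_ml)^2
  }

  # GLS via quasi-demeaning with group-specific theta
  theta_g <- 1 - sqrt(sigma_e2 / (sigma_e2 + Tg * sigma_u2))
  th <- theta_g[as.integer(g)]
  ys <- y - th * ave(y, g)
  Xs <- X - th * apply(X, 2L, ave, g)
  qs <- qr(Xs)
  beta <- qr.coef(qs, ys)
  e <- ys - Xs %*% beta
  XtX_inv <- chol2inv(qr.R(qs))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  # cluster-robust CR1 sandwich on the transformed data
  Xe <- rowsum((Xs * as.numeric(e)), g)
  meat <- crossprod(Xe)
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  V_cl <- adj * XtX_inv %*% meat %*% XtX_inv
  se_cl <- sqrt(diag(V_cl))
  s2 <- sum(e^2) / (n - k)
  se_classical <- sqrt(diag(s2 * XtX_inv))
  fitted_fix <- as.numeric(X %*% beta)
  r2 <- if (sd(fitted_fix) > 0) cor(y, fitted_fix)^2 else 0

  structure(list(coefficients = setNames(as.numeric(beta), colnames(X)),
                 se = setNames(se_cl, colnames(X)),
                 se_classical = setNames(se_classical, colnames(X)),
                 vcov = V_cl, sigma_u = sqrt(sigma_u2), sigma_e = sqrt(sigma_e2),
                 r_squared = r2, n = n, n_groups = G, df = G - 1L,
                 method = method, formula = formula, call = match.call()),
            class = "re_fit")
}

#' @export
coef.re_fit <- function(object, ...) object$coefficients

#' @export
vcov.re_fit <- function(object, ...) object$vcov

#' @export
nobs.re_fit <- function(object, ...) object$n

#' @export
print.re_fit <- function(x, ...) {
  cat(sprintf("Random-intercept panel fit (%s), %d obs in %d groups\n",
              x$method, x$n, x$n_groups))
  cat(sprintf("  sigma_u = %.3f, sigma_e = %.3f, overall R^2 = %.3f\n",
              x$sigma_u, x$sigma_e, x$r_squared))
  print(round(rbind(estimate = x$coefficients, `cluster se` = x$se), 4))
  invisible(x)
}

#' @export
summary.re_fit <- function(object, ...) {
  tval <- object$coefficients / object$se
  pval <- 2 * pt(-abs(tval), df = object$df)
  stars <- ifelse(pval < 0.01, "***", ifelse(pval < 0.05, "**",
            ifelse(pval < 0.1, "*", "")))
  tab <- data.frame(estimate = object$coefficients, se_cluster = object$se,
                    t = tval, p = pval, sig = stars)
  structure(list(table = tab, fit = object), class = "summary.re_fit")
}

#' @export
print.summary.re_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("Random-intercept panel fit (%s)\n", f$method))
  cat(sprintf("  %d obs, %d groups; sigma_u %.3f, sigma_e %.3f, overall R^2 %.3f\n",
              f$n, f$n_groups, f$sigma_u, f$sigma_e, f$r_squared))
  cat("  Robust standard errors clustered at group level; stars: *** 1%, ** 5%, * 10%\n\n")
  tab <- x$table
  tab$estimate <- round(tab$estimate, 4); tab$se_cluster <- round(tab$se_cluster, 4)
  tab$t <- round(tab$t, 2); tab$p <- signif(tab$p, 3)
  print(tab)
  invisible(x)
}

#' Extraction-target gap test between disclosure scenarios
#'
#' Welch two-sample t test of the per-record gap `target - extraction` between
#' the public-disclosure (reputation) scenario and the private one. A positive
#' statistic means the gap is wider under public disclosure.
#'
#' @param records round records from [simulate_experiment()].
#' @return An object of class `"htest"` with the reputation-minus-private
#'   ordering; errors if only one scenario is present, and flags infinite
#'   statistics when both gap distributions are degenerate.
#' @export
gap_test <- function(records) {
  v <- records[!records$analysis_excluded & records$scenario != "shuffling", ]
  scen <- unique(v$scenario)
  if (!all(c("voting_shuffling", "voting_shuffling_reputation") %in% scen))
    stop("invalid comparison: need both voting scenarios", call. = FALSE)
  gap <- v$group_target - v$extraction
  g_rep <- gap[v$scenario == "voting_shuffling_reputation"]
  g_vs <- gap[v$scenario == "voting_shuffling"]
  if (var(g_rep) + var(g_vs) == 0) {
    stat <- if (mean(g_rep) == mean(g_vs)) 0 else Inf * sign(mean(g_rep) - mean(g_vs))
    out <- list(statistic = c(t = stat), p.value = if (is.finite(stat)) 1 else 0,
                estimate = c(`mean gap (reputation)` = mean(g_rep),
                             `mean gap (private)` = mean(g_vs)),
                method = "Welch two-sample gap test (degenerate variance)",
                data.name = "target - extraction by scenario")
    class(out) <- "htest"
    return(out)
  }
  t.test(g_rep, g_vs)
}

#' Per-round summary of targets and extraction
#'
#' Means of the group target and individual extraction per scenario and round,
#' with the long-term integer-optimal benchmark as a reference column.
#'
#' @param records round records from [simulate_experiment()].
#' @param params tapping-model parameters used for the benchmark column.
#' @return Data frame: `scenario`, `round`, `mean_target`, `mean_extraction`,
#'   `benchmark`.
#' @export
summarize_rounds <- function(records, params = extraction_params()) {
  v <- records[!records$analysis_excluded & records$scenario != "shuffling", ]
  if (nrow(v) == 0L) stop("no voting-session records to summarize", call. = FALSE)
  bench <- optimal_integer_plan(params, constant = TRUE)$wounds_per_period
  out <- aggregate(cbind(mean_target = group_target, mean_extraction = extraction) ~
                     scenario + round, data = v, FUN = mean)
  out$benchmark <- bench[out$round]
  out[order(out$scenario, out$round), ]
}
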