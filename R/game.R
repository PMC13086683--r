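#' Configuration of the extraction-game simulator
#'
#' Two simulation modes share the same protocol (six sessions of three rounds,
#' groups of five, 40-card tree envelopes, random tree reallocation after every
#' round, trees reset at session boundaries):
#'
#' * `"calibrated"` draws the group target and the individual extraction
#'   directly from the linear data-generating structures of the target-setting
#'   and extraction equations, with a group random intercept and idiosyncratic
#'   noise, then rounds half-up and clamps to `[0, 40]` and to the cards
#'   remaining on the assigned tree. The default coefficients are the
#'   published round-level estimates (parsimonious specification with the
#'   reputation main effect): see `target_coefs` and `extraction_coefs`.
#' * `"mechanistic"` builds the target from explicit agents: each member
#'   proposes the myopic benchmark for the tree in hand adjusted by their own
#'   social capital, and the consensus is the rounded median of proposals;
#'   extraction blends the target with the myopic benchmark.
#'
#' Noise defaults: the group random-effect SD is 2.0 for both equations; the
#' idiosyncratic SDs are tuning constants calibrated so the fitted overall
#' R-squared of the two equations lands near the published 0.42 (targets) and
#' 0.64 (extraction) — they are documented settings, not estimates.
#'
#' @param params tapping-model parameters, [extraction_params()].
#' @param mode `"calibrated"` or `"mechanistic"`.
#' @param target_coefs,extraction_coefs named coefficient vectors of the two
#'   linear structures (see defaults for the recognized names).
#' @param sd_group_target,sd_idio_target group random-effect and idiosyncratic
#'   SDs of the target equation.
#' @param sd_group_extraction,sd_idio_extraction the same for the extraction
#'   equation.
#' @param shuffle_noise_sd SD of the integer noise around the myopic path in
#'   the structural (non-analysed) sessions 1-2.
#' @param mech mechanistic-mode settings: `sc_gain_cognitive`,
#'   `sc_gain_bonding` (wounds per z-score added to proposals),
#'   `target_weight` (weight of the target in extraction) and
#'   `reputation_restraint` (wounds subtracted under public disclosure).
#' @param discretize round targets and extractions half-up to integers (the
#'   card game's decision scale). Turn off only for identification checks:
#'   with all noise SDs at zero a *rounded* target is an exact integer
#'   function of the social-capital indices and the round, so the adherence
#'   slope degenerates into quantization error; the continuous path recovers
#'   the data-generating coefficients to machine precision instead.
#' @param seed integer seed.
#' @return A list of class `"game_config"`.
#' @export
game_config <- function(params = extraction_params(),
                        mode = c("calibrated", "mechanistic"),
                        target_coefs = c(intercept = 17.407, reputation = -0.026,
                                         cognitive = 0.624, bonding = -0.028,
                                         period2 = -2.431, period3 = -5.299,
                                         cognitive_p2 = -0.168, cognitive_p3 = -0.194,
                                         bonding_p2 = -0.905, bonding_p3 = -1.137,
                                         cognitive_rep = 0, bonding_rep = 0),
                        extraction_coefs = c(intercept = 12.358, group_target = 0.199,
                                             reputation = -0.920,
                                             cognitive = 0.103, bonding = 0.038,
                                             period2 = -2.962, period3 = -6.143,
                                             cognitive_p2 = -0.195, cognitive_p3 = -0.178,
                                             bonding_p2 = -0.009, bonding_p3 = 0,
                                             cognitive_rep = 0, bonding_rep = 0),
                        sd_group_target = 2.0, sd_idio_target = 1.5,
                        sd_group_extraction = 2.0, sd_idio_extraction = 1.9,
                        shuffle_noise_sd = 2.0,
                        mech = list(sc_gain_cognitive = 1.0, sc_gain_bonding = 1.0,
                                    target_weight = 0.2, reputation_restraint = 0.92),
                        discretize = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "extraction_params"),
            sd_group_target >= 0, sd_idio_target >= 0,
            sd_group_extraction >= 0, sd_idio_extraction >= 0)
  tc <- .complete_coefs(target_coefs, .target_coef_names)
  ec <- .complete_coefs(extraction_coefs, .extraction_coef_names)
  structure(list(params = params, mode = mode,
                 target_coefs = tc, extraction_coefs = ec,
                 sd_group_target = sd_group_target, sd_idio_target = sd_idio_target,
                 sd_group_extraction = sd_group_extraction,
                 sd_idio_extraction = sd_idio_extraction,
                 shuffle_noise_sd = shuffle_noise_sd, mech = mech,
                 discretize = discretize, seed = seed),
            class = "game_config")
}

.target_coef_names <- c("intercept", "reputation", "cognitive", "bonding",
                        "period2", "period3", "cognitive_p2", "cognitive_p3",
                        "bonding_p2", "bonding_p3", "cognitive_rep", "bonding_rep")
.extraction_coef_names <- c(.target_coef_names, "group_target")

.complete_coefs <- function(x, names_needed) {
  unknown <- setdiff(names(x), names_needed)
  if (length(unknown)) stop("unknown coefficient(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  out <- setNames(numeric(length(names_needed)), names_needed)
  out[names(x)] <- x
  out
}

# linear predictor shared by both equations; rnd in 1..3, rep in {0,1}
.game_lp <- function(co, rnd, rep, sc_cog, sc_bond, target = NULL) {
  p2 <- as.numeric(rnd == 2L); p3 <- as.numeric(rnd == 3L)
  lp <- co["intercept"] + co["reputation"] * rep +
    co["cognitive"] * sc_cog + co["bonding"] * sc_bond +
    co["period2"] * p2 + co["period3"] * p3 +
    co["cognitive_p2"] * sc_cog * p2 + co["cognitive_p3"] * sc_cog * p3 +
    co["bonding_p2"] * sc_bond * p2 + co["bonding_p3"] * sc_bond * p3 +
    co["cognitive_rep"] * sc_cog * rep + co["bonding_rep"] * sc_bond * rep
  if (!is.null(target)) lp <- lp + co["group_target"] * target
  unname(lp)
}

#' Set the group extraction target for one round
#'
#' Calibrated mode: rounds (half-up) and clamps to `[0, card_cap]` the linear
#' predictor of the target equation plus the supplied group random effect and
#' idiosyncratic draw. Mechanistic mode: each member proposes the myopic
#' benchmark for their current tree adjusted by their own social capital, and
#' the consensus is the rounded median of the five proposals (a robust,
#' order-free stand-in for the unanimity stage).
#'
#' @param round round within the session (1..3).
#' @param scenario `"voting_shuffling"` or `"voting_shuffling_reputation"`.
#' @param sc_cognitive,sc_bonding group-level indices (calibrated mode) or
#'   length-5 member indices (mechanistic mode).
#' @param config a [game_config()].
#' @param u_group group random-effect draw (calibrated mode).
#' @param eps idiosyncratic draw (calibrated mode).
#' @param prior_wounds length-5 wounds on each member's current tree
#'   (mechanistic mode).
#' @return Integer target in `[0, card_cap]`.
#' @export
set_group_target <- function(round, scenario, sc_cognitive, sc_bonding,
                             config = game_config(), u_group = 0, eps = 0,
                             prior_wounds = NULL) {
  stopifnot(round %in% 1:3)
  rep_flag <- as.numeric(scenario == "voting_shuffling_reputation")
  cap <- config$params$card_cap
  if (config$mode == "calibrated") {
    lp <- clamp(.game_lp(config$target_coefs, round, rep_flag,
                         sc_cognitive, sc_bonding) + u_group + eps, 0, cap)
    return(if (isTRUE(config$discretize)) as.integer(round_half_up(lp)) else lp)
  }
  if (is.null(prior_wounds)) prior_wounds <- numeric(length(sc_cognitive))
  bench <- myopic_extraction(config$params, prior_wounds)
  prop <- round_half_up(clamp(bench +
                                config$mech$sc_gain_cognitive * sc_cognitive +
                                config$mech$sc_gain_bonding * sc_bonding, 0, cap))
  as.integer(round_half_up(median(prop)))
}

#' One member's extraction decision
#'
#' Calibrated mode: rounds (half-up) and clamps the extraction-equation linear
#' predictor (which includes the group target) plus noise to
#' `[0, min(card_cap, remaining)]`. Mechanistic mode: a convex blend of the
#' group target and the myopic benchmark, minus a restraint term under public
#' disclosure.
#'
#' @inheritParams set_group_target
#' @param target the group target for this round.
#' @param remaining cards remaining on the member's tree.
#' @param sc_cognitive,sc_bonding the member's individual indices (vectorized).
#' @return Integer wounds in `[0, remaining]`.
#' @export
individual_extraction <- function(round, scenario, target, sc_cognitive, sc_bonding,
                                  remaining, config = game_config(),
                                  u_group = 0, eps = 0) {
  stopifnot(all(target >= 0), all(target <= config$params$card_cap))
  rep_flag <- as.numeric(scenario == "voting_shuffling_reputation")
  if (config$mode == "calibrated") {
    lp <- .game_lp(config$extraction_coefs, round, rep_flag,
                   sc_cognitive, sc_bonding, target = target)
    q <- lp + u_group + eps
  } else {
    prior <- config$params$card_cap - remaining
    bench <- myopic_extraction(config$params, prior)
    w <- config$mech$target_weight
    q <- w * target + (1 - w) * bench - config$mech$reputation_restraint * rep_flag
  }
  q <- clamp(q, 0, pmin(config$params$card_cap, remaining))
  if (isTRUE(config$discretize)) as.integer(round_half_up(q)) else q
}

#' Shuffle tree envelopes within a group
#'
#' Uniform random permutation of the member-to-tree assignment; cumulative
#' wounds travel with the tree, harvest envelopes stay with the member.
#'
#' @param assignment integer vector mapping members to tree indices.
#' @return Permuted assignment.
#' @export
shuffle_trees <- function(assignment) {
  assignment[sample.int(length(assignment))]
}

#' Simulate the framed field experiment
#'
#' Runs every group of the cohort through six sessions of three rounds. Trees
#' reset to zero wounds (40 cards) at each session start. Sessions 1-2 are
#' plain shuffling: members follow the myopic path with integer noise; these
#' rows are flagged `analysis_excluded` and carry no target. Sessions 3-6
#' follow the cohort's sequence matrix: a group target is set (calibrated or
#' mechanistic, see [game_config()]), the five members extract simultaneously,
#' payoffs are computed with the tapping model, and tree envelopes are
#' reshuffled for the next round.
#'
#' @param cohort a `"cpr_cohort"` from [generate_cohort()].
#' @param config a [game_config()].
#' @param sessions sessions to simulate (default all six).
#' @param envelope with the default `TRUE`, extraction is physically limited to
#'   the cards remaining on the assigned tree (the card game as played; card
#'   conservation holds exactly). With `FALSE` the simulator draws from the
#'   bare linear regression structures, clamping extraction only to the
#'   `[0, card_cap]` integer range: this is the data-generating process the
#'   panel estimator assumes, used by Monte Carlo recovery studies. Because
#'   the published coefficients imply mean session extraction close to the
#'   full envelope, the physical limit censors part of round 3 and attenuates
#'   the extraction-equation coefficients; see the methods vignette.
#' @return A data frame of round records: `group_id`, `respondent_id`,
#'   `sequence`, `session`, `scenario`, `round`, `group_target`, `extraction`,
#'   `prior_wounds`, `payoff`, `sc_cognitive`, `sc_bonding`,
#'   `sc_cognitive_grp`, `sc_bonding_grp`, `analysis_excluded`.
#' @export
simulate_experiment <- function(cohort, config = game_config(), sessions = 1:6,
                                envelope = TRUE) {
  stopifnot(inherits(cohort, "cpr_cohort"), inherits(config, "game_config"))
  d <- cohort$respondents
  if (!all(c("sc_cognitive", "sc_bonding", "sc_cognitive_grp", "sc_bonding_grp") %in% names(d)))
    stop("missing-index error: cohort lacks social-capital indices", call. = FALSE)
  set.seed(config$seed)
  params <- config$params
  cap <- params$card_cap
  gs <- cohort$config$group_size
  gids <- unique(d$group_id)
  n_rows <- length(gids) * length(sessions) * 3L * gs
  # preallocated columns (filled block-wise; a data.frame per round is too slow)
  col_chr <- function() character(n_rows)
  col_int <- function() integer(n_rows)
  col_num <- function() numeric(n_rows)
  R <- list(group_id = col_chr(), respondent_id = col_chr(), sequence = col_int(),
            session = col_int(), scenario = col_chr(), round = col_int(),
            group_target = col_num(), extraction = col_num(),
            prior_wounds = col_num(), payoff = col_num(),
            sc_cognitive = col_num(), sc_bonding = col_num(),
            sc_cognitive_grp = col_num(), sc_bonding_grp = col_num(),
            analysis_excluded = logical(n_rows))
  pos <- 0L

  for (g in gids) {
    mem <- d[d$group_id == g, ]
    seq_id <- mem$sequence[1L]
    u_t <- rnorm(1L, 0, config$sd_group_target)
    u_x <- rnorm(1L, 0, config$sd_group_extraction)
    for (s in sessions) {
      scenario <- cohort$seq_matrix[s, seq_id]
      wounds <- numeric(gs)          # per tree, reset each session
      assignment <- seq_len(gs)      # member m holds tree assignment[m]
      for (r in 1:3) {
        prior <- wounds[assignment]
        remaining <- if (envelope) cap - prior else rep(cap, gs)
        if (scenario == "shuffling") {
          target <- NA_real_
          q_des <- myopic_extraction(params, prior) +
            rnorm(gs, 0, config$shuffle_noise_sd)
          q <- as.integer(round_half_up(clamp(q_des, 0, remaining)))
        } else {
          if (config$mode == "calibrated") {
            target <- set_group_target(r, scenario,
                                       mem$sc_cognitive_grp[1L], mem$sc_bonding_grp[1L],
                                       config, u_group = u_t,
                                       eps = rnorm(1L, 0, config$sd_idio_target))
          } else {
            target <- set_group_target(r, scenario, mem$sc_cognitive, mem$sc_bonding,
                                       config, prior_wounds = prior)
          }
          q <- individual_extraction(r, scenario, target,
                                     mem$sc_cognitive, mem$sc_bonding,
                                     remaining, config, u_group = u_x,
                                     eps = rnorm(gs, 0, config$sd_idio_extraction))
        }
        pay <- if (envelope) period_payoff(params, q, prior) else
          params$price * params$prod_coeff * q *
            tree_health(params, prior + q) - params$unit_cost * q
        i <- pos + seq_len(gs)
        R$group_id[i] <- g; R$respondent_id[i] <- mem$respondent_id
        R$sequence[i] <- seq_id; R$session[i] <- s; R$scenario[i] <- scenario
        R$round[i] <- r; R$group_target[i] <- target
        R$extraction[i] <- q; R$prior_wounds[i] <- prior
        R$payoff[i] <- pay
        R$sc_cognitive[i] <- mem$sc_cognitive; R$sc_bonding[i] <- mem$sc_bonding
        R$sc_cognitive_grp[i] <- mem$sc_cognitive_grp[1L]
        R$sc_bonding_grp[i] <- mem$sc_bonding_grp[1L]
        R$analysis_excluded[i] <- scenario == "shuffling"
        pos <- pos + gs
        wounds[assignment] <- wounds[assignment] + q
        assignment <- shuffle_trees(assignment)
      }
    }
  }
  res <- as.data.frame(R, stringsAsFactors = FALSE)
  stopifnot(pos == n_rows)
  res
}
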