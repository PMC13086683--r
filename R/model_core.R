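#' Parameters of the frankincense tapping model
#'
#' Bundles the constants of the harvest/health/payoff model. The harvest from a
#' tree tapped with `q` wounds in a period is `prod_coeff * q * V`, where the
#' tree's health `V = initial_health - decline_rate * Q` falls linearly in the
#' cumulative wound count `Q` (counted up to and including the current period).
#' Wounding costs `unit_cost` tokens per wound, and resin sells at `price`
#' tokens per harvest unit, so the period payoff is quadratic in `q` with
#' diminishing returns.
#'
#' Defaults are the experiment's calibration: price 5 tokens, production
#' coefficient 0.7, initial health 21, health decline 0.5 per wound, harvest
#' cost 0.5 per wound, three periods per tree lifetime, and a physical cap of
#' 40 wounds (cards) per tree.
#'
#' @param price tokens per harvest unit (> 0).
#' @param prod_coeff dimensionless production coefficient of wounding (> 0).
#' @param initial_health health of an untapped tree, in health units (> 0).
#' @param decline_rate health lost per cumulative wound (>= 0).
#' @param unit_cost tokens of effort per wound (>= 0).
#' @param horizon periods in a tree's productive lifetime (integer >= 1).
#' @param card_cap maximum cumulative wounds per tree (positive integer).
#' @return An object of class `"extraction_params"` (a named list).
#' @examples
#' p <- extraction_params()
#' tree_health(p, 21)
#' optimal_integer_plan(p)
#' @export
extraction_params <- function(price = 5, prod_coeff = 0.7, initial_health = 21,
                              decline_rate = 0.5, unit_cost = 0.5,
                              horizon = 3L, card_cap = 40L) {
  stopifnot(
    is.numeric(price), length(price) == 1L, price >= 0,
    is.numeric(prod_coeff), length(prod_coeff) == 1L, prod_coeff > 0,
    is.numeric(initial_health), length(initial_health) == 1L, initial_health > 0,
    is.numeric(decline_rate), length(decline_rate) == 1L, decline_rate >= 0,
    is.numeric(unit_cost), length(unit_cost) == 1L, unit_cost >= 0,
    is.numeric(horizon), length(horizon) == 1L, horizon >= 1, horizon == as.integer(horizon),
    is.numeric(card_cap), length(card_cap) == 1L, card_cap >= 1, card_cap == as.integer(card_cap)
  )
  structure(
    list(price = price, prod_coeff = prod_coeff, initial_health = initial_health,
         decline_rate = decline_rate, unit_cost = unit_cost,
         horizon = as.integer(horizon), card_cap = as.integer(card_cap)),
    class = "extraction_params"
  )
}

#' @export
print.extraction_params <- function(x, ...) {
  cat("Frankincense tapping model parameters\n")
  cat(sprintf("  price (P)            %g tokens/unit\n", x$price))
  cat(sprintf("  prod. coeff (zeta)   %g\n", x$prod_coeff))
  cat(sprintf("  initial health       %g\n", x$initial_health))
  cat(sprintf("  decline per wound    %g\n", x$decline_rate))
  cat(sprintf("  unit cost (c)        %g tokens/wound\n", x$unit_cost))
  cat(sprintf("  horizon              %d periods\n", x$horizon))
  cat(sprintf("  card cap             %d wounds/tree\n", x$card_cap))
  invisible(x)
}

#' Tree health after cumulative wounding
#'
#' Health is `initial_health - decline_rate * cumulative_wounds`. It can go
#' negative only when `cumulative_wounds` exceeds what the card cap permits.
#'
#' @param params an [extraction_params()] object.
#' @param cumulative_wounds non-negative wound count(s) (vectorized).
#' @return Health in health units.
#' @export
tree_health <- function(params, cumulative_wounds) {
  stopifnot(inherits(params, "extraction_params"))
  if (any(cumulative_wounds < 0)) stop("cumulative_wounds must be non-negative", call. = FALSE)
  params$initial_health - params$decline_rate * cumulative_wounds
}

#' Single-period extraction payoff
#'
#' Payoff from applying `wounds` new wounds to a tree that already carries
#' `prior_wounds`: `price * prod_coeff * wounds * health_after - unit_cost *
#' wounds`, where `health_after` is the tree health at the cumulative count
#' *including* the current period's wounds.
#'
#' @inheritParams tree_health
#' @param wounds wounds applied this period (>= 0, vectorized).
#' @param prior_wounds cumulative wounds before this period (>= 0).
#' @return Payoff in tokens.
#' @export
period_payoff <- function(params, wounds, prior_wounds = 0) {
  stopifnot(inherits(params, "extraction_params"))
  if (any(wounds < 0) || any(prior_wounds < 0))
    stop("wounds and prior_wounds must be non-negative", call. = FALSE)
  if (any(prior_wounds + wounds > params$card_cap))
    stop("infeasible extraction: cumulative wounds exceed the card cap", call. = FALSE)
  h <- tree_health(params, prior_wounds + wounds)
  params$price * params$prod_coeff * wounds * h - params$unit_cost * wounds
}

#' Lifetime payoff of an extraction plan
#'
#' Sums [period_payoff()] over the horizon with accumulating wounds.
#'
#' @inheritParams tree_health
#' @param plan numeric vector of per-period wounds, length `params$horizon`.
#' @return Total payoff in tokens.
#' @export
lifetime_payoff <- function(params, plan) {
  stopifnot(inherits(params, "extraction_params"))
  if (length(plan) != params$horizon)
    stop("plan length must equal the horizon", call. = FALSE)
  if (any(plan < 0)) stop("wounds must be non-negative", call. = FALSE)
  if (sum(plan) > params$card_cap)
    stop("infeasible extraction: plan exceeds the card cap", call. = FALSE)
  total <- 0
  q_prev <- 0
  for (q in plan) {
    total <- total + period_payoff(params, q, q_prev)
    q_prev <- q_prev + q
  }
  total
}

#' Is profitable extraction feasible?
#'
#' Extraction levels are strictly positive only when the marginal revenue of
#' the first wound on a fresh tree exceeds its cost:
#' `price * prod_coeff * initial_health > unit_cost`.
#'
#' @inheritParams tree_health
#' @return Logical.
#' @export
feasibility_condition <- function(params) {
  stopifnot(inherits(params, "extraction_params"))
  params$price * params$prod_coeff * params$initial_health > params$unit_cost
}

#' Optimal constant extraction under long-term tenure
#'
#' Under long-term property rights (no tree reallocation) the lifetime-payoff
#' maximizing plan applies the same number of wounds each period. The
#' first-order condition gives `q* = (P z a - c) / ((T + 1) b P z)` (for the
#' default three-period horizon, `(P z a - c) / (4 b P z)`), truncated at the
#' card cap (equal split of the cap) and at zero when profitable extraction is
#' infeasible.
#'
#' @inheritParams tree_health
#' @return A numeric scalar with attribute `boundary` (`TRUE` when the
#'   zero/cap boundary binds rather than the interior first-order condition).
#' @export
optimal_constant_extraction <- function(params) {
  stopifnot(inherits(params, "extraction_params"))
  if (!feasibility_condition(params) || params$decline_rate == 0) {
    if (params$decline_rate == 0 && feasibility_condition(params)) {
      # no health penalty: cap binds
      q <- params$card_cap / params$horizon
      return(structure(q, boundary = TRUE))
    }
    return(structure(0, boundary = TRUE))
  }
  Pz <- params$price * params$prod_coeff
  q <- (Pz * params$initial_health - params$unit_cost) /
    ((params$horizon + 1) * params$decline_rate * Pz)
  cap_q <- params$card_cap / params$horizon
  if (q > cap_q) return(structure(cap_q, boundary = TRUE))
  structure(max(0, q), boundary = FALSE)
}

#' Optimal integer extraction plan (exhaustive search)
#'
#' Enumerates integer plans over the horizon (total wounds up to the card cap)
#' and returns the lifetime-payoff maximizer. The lifetime payoff depends on a
#' plan only through its total `S` and sum of squares (it equals
#' `(P z a - c) S - (P z b / 2)(S^2 + sum(q^2))`), so the free optimum splits
#' its total as evenly as integers allow.
#'
#' With `constant = TRUE` the search is restricted to constant plans (the same
#' wound count every period) — the integer analogue of the constant continuous
#' optimum and the game's per-round benchmark. With the default experimental
#' parameters the constant optimum is 10 wounds per round (payoff 1140); the
#' unrestricted integer optimum is the uneven split 10, 10, 11 (payoff
#' 1141.25), a granularity effect of the integer grid around the continuous
#' per-period optimum 73/7.
#'
#' Payoff ties are broken towards fewer total wounds, then lexicographically.
#'
#' @inheritParams tree_health
#' @param constant restrict the search to constant (equal-per-period) plans.
#' @return A list of class `"extraction_plan"`: `wounds_per_period`,
#'   `total_payoff`, `total_wounds`, `regime`.
#' @export
optimal_integer_plan <- function(params, constant = FALSE) {
  stopifnot(inherits(params, "extraction_params"))
  if (params$horizon > 4L && !constant)
    stop("exhaustive search supported for horizons up to 4", call. = FALSE)
  plans <- if (constant) {
    qmax <- params$card_cap %/% params$horizon
    matrix(rep(0:qmax, params$horizon), ncol = params$horizon)
  } else {
    .enumerate_plans(params$horizon, params$card_cap)
  }
  pay <- .plan_payoffs(params, plans)
  best <- max(pay)
  cand <- which(pay >= best - 1e-9)
  if (length(cand) > 1L) {
    tot <- rowSums(plans[cand, , drop = FALSE])
    cand <- cand[order(tot, apply(plans[cand, , drop = FALSE], 1L, paste, collapse = ","))]
  }
  idx <- cand[1L]
  structure(list(wounds_per_period = as.integer(plans[idx, ]),
                 total_payoff = pay[idx],
                 total_wounds = sum(plans[idx, ]),
                 regime = if (constant) "long_term_integer_constant"
                          else "long_term_integer"),
            class = "extraction_plan")
}

# all integer plans with sum <= cap, as a matrix with `horizon` columns
.enumerate_plans <- function(horizon, cap) {
  grids <- rep(list(0:cap), horizon)
  plans <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  plans[rowSums(plans) <= cap, , drop = FALSE]
}

# vectorized lifetime payoff over plan rows
.plan_payoffs <- function(params, plans) {
  Pz <- params$price * params$prod_coeff
  cum <- 0
  pay <- numeric(nrow(plans))
  for (t in seq_len(ncol(plans))) {
    q <- plans[, t]
    cum <- cum + q
    h <- params$initial_health - params$decline_rate * cum
    pay <- pay + Pz * q * h - params$unit_cost * q
  }
  pay
}

#' @export
print.extraction_plan <- function(x, ...) {
  cat(sprintf("Extraction plan (%s)\n", x$regime))
  cat("  wounds per period:", paste(round(x$wounds_per_period, 4), collapse = ", "), "\n")
  cat(sprintf("  total wounds: %g   total payoff: %g tokens\n",
              x$total_wounds, x$total_payoff))
  invisible(x)
}

#' Myopic single-period extraction
#'
#' Under short-term tenure a harvester maximizes the one-period payoff from
#' the tree in hand. The first-order condition gives
#' `q = (P z (a - b Qprev) - c) / (2 b P z)`, floored at zero.
#' The card cap is *not* applied here; see [myopic_path()] for a path that
#' respects remaining cards.
#'
#' @inheritParams tree_health
#' @param prior_wounds cumulative wounds already on the tree (>= 0, vectorized).
#' @return Continuous wound level(s).
#' @export
myopic_extraction <- function(params, prior_wounds = 0) {
  stopifnot(inherits(params, "extraction_params"))
  if (any(prior_wounds < 0)) stop("prior_wounds must be non-negative", call. = FALSE)
  Pz <- params$price * params$prod_coeff
  if (params$decline_rate == 0) {
    # payoff linear in q: corner solution (capped later by remaining cards)
    pos <- Pz * params$initial_health > params$unit_cost
    return(rep(if (pos) Inf else 0, length(prior_wounds)))
  }
  q <- (Pz * (params$initial_health - params$decline_rate * prior_wounds) - params$unit_cost) /
    (2 * params$decline_rate * Pz)
  pmax(0, q)
}

#' Myopic extraction path over the horizon
#'
#' Iterates [myopic_extraction()] across the lifetime of one tree, accumulating
#' wounds, clamping each period at the remaining cards. In continuous mode each
#' interior step is exactly half the previous one (the first-order-condition
#' recursion halves the marginal surplus every period); in integer mode each
#' period takes the feasible integer argmax of the one-period payoff (ties
#' broken towards fewer wounds).
#'
#' @inheritParams tree_health
#' @param integer logical; enumerate integers instead of the continuous rule.
#' @return An `"extraction_plan"` with `regime = "myopic_continuous"` or
#'   `"myopic_integer"`.
#' @export
myopic_path <- function(params, integer = FALSE) {
  stopifnot(inherits(params, "extraction_params"))
  q_prev <- 0
  plan <- numeric(params$horizon)
  for (t in seq_len(params$horizon)) {
    remaining <- params$card_cap - q_prev
    if (integer) {
      qs <- 0:floor(remaining)
      pay <- params$price * params$prod_coeff * qs *
        (params$initial_health - params$decline_rate * (q_prev + qs)) -
        params$unit_cost * qs
      q <- qs[which.max(pay)] # which.max takes the first (smallest) maximizer
    } else {
      q <- min(myopic_extraction(params, q_prev), remaining)
    }
    plan[t] <- q
    q_prev <- q_prev + q
  }
  structure(list(wounds_per_period = plan,
                 total_payoff = lifetime_payoff(params, plan),
                 total_wounds = sum(plan),
                 regime = if (integer) "myopic_integer" else "myopic_continuous"),
            class = "extraction_plan")
}
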