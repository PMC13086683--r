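test_that("tree health and period payoff match hand-computed values", {
  p <- default_params()
  expect_equal(tree_health(p, 0), 21)
  expect_equal(tree_health(p, 42), 0)
  expect_equal(tree_health(p, 21), 10.5)
  expect_error(tree_health(p, -1), "non-negative")

  # 5 * 0.7 * 10 * (21 - 0.5*10) - 0.5*10
  expect_equal(period_payoff(p, 10, 0), 555)
  expect_equal(period_payoff(p, 0, 17), 0)
  expect_equal(period_payoff(p, 21, 0), 761.25)
  expect_error(period_payoff(p, 30, 20), "infeasible")

  expect_equal(lifetime_payoff(p, c(10, 10, 10)), 1140)
  expect_equal(lifetime_payoff(p, c(0, 0, 0)), 0)
  expect_equal(lifetime_payoff(p, c(21, 10, 5)), 998.75)
  expect_error(lifetime_payoff(p, c(10, 10)), "horizon")
  expect_error(lifetime_payoff(p, c(20, 20, 10)), "infeasible")
})

test_that("feasibility condition is a strict threshold on P*z*a vs c", {
  expect_true(feasibility_condition(default_params()))  # 73.5 > 0.5
  expect_false(feasibility_condition(extraction_params(price = 0.001)))
  # exact boundary: P*z*a == c
  expect_false(feasibility_condition(
    extraction_params(price = 1, prod_coeff = 0.5, initial_health = 1, unit_cost = 0.5)))
})

test_that("constant-plan optimum agrees with a dense grid-search oracle", {
  p <- default_params()
  q_star <- as.numeric(optimal_constant_extraction(p))
  expect_equal(q_star, 73 / 7, tolerance = 1e-12)

  # oracle: grid over equal plans, quadratic refinement around the argmax
  const_payoff <- function(q, p) {
    Pz <- p$price * p$prod_coeff
    3 * Pz * p$initial_health * q - Pz * p$decline_rate * q^2 * 6 - 3 * p$unit_cost * q
  }
  grid_argmax <- function(p) {
    qs <- seq(0, p$card_cap / 3, by = 1e-3)
    f <- const_payoff(qs, p)
    i <- which.max(f)
    i <- min(max(i, 2L), length(qs) - 1L)
    # exact vertex of the quadratic through the three neighbouring points
    qs[i] + 0.5e-3 * (f[i - 1] - f[i + 1]) / (f[i - 1] - 2 * f[i] + f[i + 1])
  }
  expect_equal(q_star, grid_argmax(p), tolerance = 1e-6)

  p2 <- extraction_params(decline_rate = 1.0)
  expect_equal(as.numeric(optimal_constant_extraction(p2)), 36.5 / 7, tolerance = 1e-12)
  expect_equal(as.numeric(optimal_constant_extraction(p2)), grid_argmax(p2),
               tolerance = 1e-6)

  # boundary: zero extraction when marginal revenue never exceeds cost
  p0 <- extraction_params(price = 1, prod_coeff = 0.5, initial_health = 1,
                          unit_cost = 0.5)
  q0 <- optimal_constant_extraction(p0)
  expect_equal(as.numeric(q0), 0)
  expect_true(attr(q0, "boundary"))
})

test_that("integer plans: constant benchmark is 10/round, free optimum splits 31", {
  p <- default_params()
  const <- optimal_integer_plan(p, constant = TRUE)
  expect_identical(const$wounds_per_period, c(10L, 10L, 10L))
  expect_equal(const$total_payoff, 1140)

  free <- optimal_integer_plan(p)
  # the payoff depends only on (sum, sum of squares): the free optimum takes
  # total 31 split as evenly as possible; lexicographic tie-break
  expect_identical(sort(free$wounds_per_period), c(10L, 10L, 11L))
  expect_equal(free$total_payoff, 1141.25)
  expect_equal(free$total_payoff, lifetime_payoff(p, free$wounds_per_period))

  h1 <- optimal_integer_plan(extraction_params(horizon = 1L))
  expect_identical(h1$wounds_per_period, 21L)
  expect_equal(h1$total_payoff, 761.25)

  zero <- optimal_integer_plan(extraction_params(price = 0.0001))
  expect_identical(zero$wounds_per_period, c(0L, 0L, 0L))
  expect_equal(zero$total_payoff, 0)
})

test_that("myopic rule matches the single-period grid oracle and its recursion", {
  p <- default_params()
  expect_equal(myopic_extraction(p, 0), 73 / 3.5, tolerance = 1e-12)
  # marginal revenue equals marginal cost => zero
  q_prev_zero <- (p$initial_health - p$unit_cost / (p$price * p$prod_coeff)) /
    p$decline_rate
  expect_equal(myopic_extraction(p, q_prev_zero), 0)
  expect_equal(myopic_extraction(p, 73 / 3.5), 73 / 7, tolerance = 1e-12)

  # grid oracle for the single-period argmax at two tree states
  for (q_prev in c(0, 12.5)) {
    qs <- seq(0, 40, by = 1e-3)
    f <- p$price * p$prod_coeff * qs *
      (p$initial_health - p$decline_rate * (q_prev + qs)) - p$unit_cost * qs
    expect_equal(myopic_extraction(p, q_prev), qs[which.max(f)], tolerance = 1e-3)
  }
})

test_that("myopic path halves each period, declines, and over-extracts vs optimum", {
  p <- default_params()
  cont <- myopic_path(p)
  expect_equal(cont$wounds_per_period, c(73 / 3.5, 73 / 7, 73 / 14), tolerance = 1e-9)
  int <- myopic_path(p, integer = TRUE)
  expect_identical(as.integer(int$wounds_per_period), c(21L, 10L, 5L))
  expect_equal(int$total_payoff, 998.75)

  # exact halving and strict decline for arbitrary feasible parameters
  set.seed(101)
  for (i in 1:25) {
    pr <- random_params()
    path <- myopic_path(pr)$wounds_per_period
    pos <- path > 1e-8
    if (sum(pos) >= 2) {
      for (t in which(pos[-length(path)])) {
        expect_equal(path[t + 1], path[t] / 2, tolerance = 1e-9)
      }
      expect_true(all(diff(path[pos]) < 0))
    }
  }

  # regime ordering: short-term tenure cuts more and earns less
  free <- optimal_integer_plan(p)
  expect_gte(int$total_wounds, free$total_wounds)
  expect_gte(cont$total_wounds, free$total_wounds)
  expect_lte(int$total_payoff, free$total_payoff)
  expect_lte(cont$total_payoff, free$total_payoff)

  infeasible <- extraction_params(price = 0.001)
  expect_equal(myopic_path(infeasible)$wounds_per_period, c(0, 0, 0))
})

test_that("default parameters keep payoffs non-negative and health above the floor", {
  p <- default_params()
  expect_true(all(tree_health(p, 0:40) >= 1))
  for (q_prev in seq(0, 39, by = 1)) {
    q <- 1:(40 - q_prev)
    expect_true(all(period_payoff(p, q, q_prev) > 0))
    expect_equal(period_payoff(p, 0, q_prev), 0)
  }
})
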