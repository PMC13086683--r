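# Shared fixtures, built in code.

default_params <- function() extraction_params()

# Random feasible model parameters for property loops (cap made non-binding so
# interior first-order conditions apply).
random_params <- function() {
  repeat {
    p <- extraction_params(price = runif(1, 0.5, 10),
                           prod_coeff = runif(1, 0.1, 2),
                           initial_health = runif(1, 5, 40),
                           decline_rate = runif(1, 0.1, 2),
                           unit_cost = runif(1, 0, 2),
                           horizon = 3L, card_cap = 10000L)
    if (feasibility_condition(p)) return(p)
  }
}

# A tiny deterministic respondent table covering every catalog item with
# non-degenerate variation: respondent A answers `lo`, B answers `hi`,
# the rest alternate.
tiny_respondents <- function(n = 4, lo = 1L, hi = 3L) {
  items <- sc_item_catalog()$item_id
  d <- as.data.frame(setNames(lapply(items, function(i)
    rep(c(lo, hi), length.out = n)), items))
  d$respondent_id <- sprintf("r%02d", seq_len(n))
  d
}

# Small scored cohort + simulation used by several panel tests.
small_cohort <- function(n = 60L, seed = 42L) {
  generate_cohort(cohort_config(n = n, seed = seed))
}
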