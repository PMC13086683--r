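#' Configuration of the synthetic harvester cohort
#'
#' Collects the demographic targets, item calibration and latent-structure
#' parameters the respondent generator aims at. Defaults reproduce the study
#' population: 210 harvesters in groups of five over seven treatment
#' sequences; 54% female, mean age 38, mean schooling 2.8 years, mean
#' adult-equivalent family size 5.4 (adults + 0.5 x children), mean annual
#' income Birr 46,980 (log-normal; only the mean is published, so a
#' right-skewed positive shape is assumed).
#'
#' The latent structure drives the Likert items: each social-capital dimension
#' has a latent factor that is a linear combination of demographics (loadings
#' default to the published determinants-table magnitudes: log income and
#' family size for the cognitive dimension; schooling, landholding (negative),
#' family size and the female indicator for bonding) plus independent noise.
#' The generator calibrates the noise so that, for the cognitive dimension,
#' the configured loadings hold on the *index* scale (an OLS of the cognitive
#' index on demographics recovers them in expectation). The bonding loadings
#' are too large to hold exactly on the mean-of-z-scores index scale, so their
#' signal is shrunk proportionally until the demographic part carries
#' `bonding_signal_share` of the factor variance (default 0.5, which puts the
#' bonding index R-squared near the published 0.28); signs and ratios are
#' preserved.
#'
#' @param n number of respondents (default 210).
#' @param group_size members per experimental group (default 5).
#' @param n_sequences number of treatment sequences (default 7).
#' @param seed integer seed for all draws.
#' @param female_share Bernoulli probability of the female indicator.
#' @param age_mean,age_sd gamma-distributed age (years), rounded, floored at 18.
#' @param schooling_mean,schooling_sd gamma-distributed schooling years, rounded.
#' @param adults_base,adults_rate,children_rate family composition: adults =
#'   `adults_base` + Poisson(`adults_rate`), children = Poisson(`children_rate`);
#'   family size = adults + 0.5 children. Defaults give mean 5.4.
#' @param income_mean,income_sdlog log-normal annual income (Birr).
#' @param landholding_mean,landholding_sd gamma-distributed landholding.
#' @param class_probs probabilities of social classes 1 (poor), 2 (middle),
#'   3 (rich); default centers 87% on the middle class.
#' @param loadings_cognitive,loadings_bonding named numeric vectors of
#'   demographic loadings on the two latent factors (see Details).
#' @param item_loading correlation of each item's latent with its dimension
#'   factor (default 0.7).
#' @param bonding_signal_share share of the bonding factor variance carried by
#'   demographics when exact index-scale loadings are infeasible.
#' @param catalog item catalog, see [sc_item_catalog()].
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 210L, group_size = 5L, n_sequences = 7L,
                          seed = 1L,
                          female_share = 0.54,
                          age_mean = 38, age_sd = 12,
                          schooling_mean = 2.8, schooling_sd = 3,
                          adults_base = 2L, adults_rate = 1.4, children_rate = 4,
                          income_mean = 46980, income_sdlog = 0.6,
                          landholding_mean = 1.5, landholding_sd = 1,
                          class_probs = c(0.08, 0.87, 0.05),
                          loadings_cognitive = c(log_income = 0.117, family_size = 0.263),
                          loadings_bonding = c(schooling = 0.070, landholding = -0.070,
                                               family_size = 0.116, female = 1.789),
                          item_loading = 0.7,
                          bonding_signal_share = 0.5,
                          catalog = sc_item_catalog()) {
  stopifnot(n >= group_size, group_size >= 1,
            female_share >= 0, female_share <= 1,
            item_loading > 0, item_loading < 1,
            bonding_signal_share > 0, bonding_signal_share < 1,
            abs(sum(class_probs) - 1) < 1e-8)
  if (any(catalog$calib_mean <= 1 | catalog$calib_mean >= 4))
    stop("calibration error: item mean outside (1, 4)", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

# ---- Likert discretization ---------------------------------------------------
# Category probabilities of a normal(a, b) discretized to 1..4 by rounding-style
# bins; a is solved so the categorical mean matches exactly, b grid-searched to
# approach the calibration SD.
.discretized_probs <- function(a, b) {
  cuts <- c(1.5, 2.5, 3.5)
  p <- diff(c(0, pnorm((cuts - a) / b), 1))
  pmax(p, 0)
}

.item_prob_cache <- new.env(parent = emptyenv())

.fit_item_probs <- function(m, s) {
  key <- sprintf("%.6f|%.6f", m, s)
  hit <- .item_prob_cache[[key]]
  if (!is.null(hit)) return(hit)
  mean_for <- function(a, b) sum(1:4 * .discretized_probs(a, b))
  best <- NULL
  for (b in seq(0.05, 3, by = 0.05)) {
    # mean is increasing in a; solve mean(a, b) = m
    a <- tryCatch(stats::uniroot(function(a) mean_for(a, b) - m,
                                 lower = -20, upper = 25, tol = 1e-10)$root,
                  error = function(e) NA_real_)
    if (is.na(a)) next
    p <- .discretized_probs(a, b)
    sd_cat <- sqrt(sum((1:4)^2 * p) - sum(1:4 * p)^2)
    err <- abs(sd_cat - s)
    if (is.null(best) || err < best$err) best <- list(a = a, b = b, p = p, err = err)
  }
  if (is.null(best)) stop("calibration error: cannot match item mean ", m, call. = FALSE)
  .item_prob_cache[[key]] <- best$p
  best$p
}

# slope of a z-scored discretized item on its (unit-variance) latent factor:
# cov(category, latent) telescopes to the sum of the normal density at the
# interior cutpoints; dividing by the categorical SD gives the z-scale slope.
.item_slope <- function(p, rho) {
  cum <- cumsum(p)[1:3]
  cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
  cuts <- qnorm(cum)
  phisum <- sum(dnorm(cuts))
  m <- sum(1:4 * p)
  s_cat <- sqrt(sum((1:4)^2 * p) - m^2)
  rho * phisum / s_cat
}

# ---- respondent generation ---------------------------------------------------

#' Generate synthetic survey respondents
#'
#' Draws demographics from the configured distributions, builds the two latent
#' social-capital factors from demographics plus noise, and discretizes
#' per-item latents into 1-4 responses whose marginal moments approximate the
#' item calibration (the categorical mean is matched exactly in expectation;
#' the SD as closely as a discretized normal allows).
#'
#' @param config a [cohort_config()].
#' @return Data frame with one row per respondent: `respondent_id`, `female`,
#'   `age`, `schooling`, `landholding`, `social_class`, `income`,
#'   `family_size`, and one integer column per catalog item.
#' @export
generate_respondents <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  cat_df <- config$catalog

  shape_a <- (config$age_mean / config$age_sd)^2
  shape_s <- (config$schooling_mean / config$schooling_sd)^2
  shape_l <- (config$landholding_mean / config$landholding_sd)^2

  d <- data.frame(
    respondent_id = sprintf("r%04d", seq_len(n)),
    female = rbinom(n, 1L, config$female_share),
    age = pmax(18, round(rgamma(n, shape_a, shape_a / config$age_mean))),
    schooling = round(rgamma(n, shape_s, shape_s / config$schooling_mean)),
    landholding = rgamma(n, shape_l, shape_l / config$landholding_mean),
    social_class = sample.int(3L, n, replace = TRUE, prob = config$class_probs),
    income = rlnorm(n, log(config$income_mean) - config$income_sdlog^2 / 2,
                    config$income_sdlog),
    family_size = (config$adults_base + rpois(n, config$adults_rate)) +
      0.5 * rpois(n, config$children_rate),
    stringsAsFactors = FALSE
  )
  d$log_income <- log(d$income)

  # per-item discretization and z-scale slopes
  probs <- lapply(seq_len(nrow(cat_df)),
                  function(i) .fit_item_probs(cat_df$calib_mean[i], cat_df$calib_sd[i]))
  slopes <- vapply(probs, .item_slope, numeric(1), rho = config$item_loading)
  kappa <- c(cognitive = mean(slopes[cat_df$dimension == "cognitive"]),
             bonding = mean(slopes[cat_df$dimension == "bonding"]))

  factor_of <- function(loadings, kap, share) {
    D <- as.matrix(d[, names(loadings), drop = FALSE]) %*% loadings
    Dc <- D - mean(D)
    vD <- mean(Dc^2)
    if (vD < kap^2 * 0.999) {
      scl <- 1                     # exact index-scale loadings feasible
    } else {
      scl <- sqrt(share * kap^2 / vD)  # proportional shrinkage
      Dc <- Dc * scl
      vD <- vD * scl^2
    }
    sig_e <- sqrt(max(kap^2 - vD, 1e-12))
    list(F = as.numeric(Dc + rnorm(n, 0, sig_e)) / kap, scale = scl)
  }
  fc <- factor_of(config$loadings_cognitive, kappa["cognitive"], config$bonding_signal_share)
  fb <- factor_of(config$loadings_bonding, kappa["bonding"], config$bonding_signal_share)

  rho <- config$item_loading
  for (i in seq_len(nrow(cat_df))) {
    f <- if (cat_df$dimension[i] == "cognitive") fc$F else fb$F
    x <- rho * f + sqrt(1 - rho^2) * rnorm(n)
    cuts <- qnorm(pmin(pmax(cumsum(probs[[i]])[1:3], 1e-12), 1 - 1e-12))
    d[[cat_df$item_id[i]]] <- 1L + findInterval(x, cuts)
  }
  # degeneracy guard: an item with calibration mean near a scale end (the
  # volunteer item, mean 3.99) can come out constant in a finite sample, which
  # would make z-standardization impossible; nudge one random respondent one
  # category towards the middle (mean shift 1/n, well inside sampling noise).
  for (i in seq_len(nrow(cat_df))) {
    col <- cat_df$item_id[i]
    if (length(unique(d[[col]])) == 1L) {
      j <- sample.int(n, 1L)
      d[[col]][j] <- d[[col]][j] + if (d[[col]][j] >= 3L) -1L else 1L
    }
  }
  d$log_income <- NULL
  attr(d, "factor_scales") <- c(cognitive = fc$scale, bonding = fb$scale)
  d
}

#' Randomly partition respondents into groups of five
#'
#' @param respondents respondent data frame.
#' @param config a [cohort_config()] (supplies group size and seed).
#' @return The respondent table with a `group_id` column appended.
#' @export
form_groups <- function(respondents, config = cohort_config()) {
  n <- nrow(respondents)
  gs <- config$group_size
  if (n %% gs != 0L)
    stop("invalid cohort: ", n, " respondents cannot form groups of ", gs, call. = FALSE)
  set.seed(config$seed + 1L)
  perm <- sample.int(n)
  gid <- integer(n)
  gid[perm] <- rep(seq_len(n %/% gs), each = gs)
  respondents$group_id <- sprintf("g%03d", gid)
  respondents
}

#' Assign groups to treatment sequences
#'
#' Near-balanced seeded random assignment: sequence sizes differ by at most
#' one group.
#'
#' @param groups character vector of distinct group ids.
#' @param n_sequences number of sequences (columns of the sequence matrix).
#' @param seed integer seed.
#' @return Named integer vector: sequence per group id.
#' @export
assign_sequences <- function(groups, n_sequences = 7L, seed = 1L) {
  set.seed(seed + 2L)
  seqs <- rep(seq_len(n_sequences), length.out = length(groups))
  setNames(sample(seqs), groups)
}

#' The default treatment-sequence matrix
#'
#' Six sessions by seven sequences. Sessions 1-2 are always plain shuffling
#' (their data are structural only, excluded from analysis); sessions 3-6 are
#' voting scenarios, with the reputation (public-disclosure) condition
#' occurring in consecutive session pairs: sessions 3-4 for sequences 3-4 and
#' sessions 5-6 for sequence 5. The printed source table is typographically
#' ambiguous, so the matrix ships as an editable JSON file
#' (`extdata/sequence_matrix.json`) and any matrix passing
#' [validate_sequence_matrix()] can be substituted.
#'
#' @param path optional path to a JSON file with a `scenarios` field.
#' @return A 6 x n character matrix (sessions x sequences).
#' @export
default_sequence_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sequence_matrix.json", package = "boswellia")
  m <- do.call(rbind, jsonlite::fromJSON(path, simplifyMatrix = FALSE)$scenarios)
  mode(m) <- "character"
  validate_sequence_matrix(m)
  m
}

#' Validate a treatment-sequence matrix
#'
#' Checks the protocol's structural constraints: six sessions, known scenario
#' labels, sessions 1-2 plain shuffling, and reputation sessions occurring in
#' consecutive pairs within each sequence.
#'
#' @param m character matrix, sessions (rows) by sequences (columns).
#' @return The matrix, invisibly; errors on violation.
#' @export
validate_sequence_matrix <- function(m) {
  ok_labels <- c("shuffling", "voting_shuffling", "voting_shuffling_reputation")
  if (nrow(m) != 6L) stop("sequence matrix must have 6 session rows", call. = FALSE)
  if (!all(m %in% ok_labels))
    stop("unknown scenario label(s): ", paste(setdiff(m, ok_labels), collapse = ", "),
         call. = FALSE)
  if (!all(m[1:2, ] == "shuffling"))
    stop("sessions 1-2 must be plain shuffling in every sequence", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    rep_rows <- which(m[, j] == "voting_shuffling_reputation")
    if (length(rep_rows) %% 2L != 0L ||
        (length(rep_rows) > 0 && any(diff(rep_rows) != 1L)))
      stop("reputation sessions must occur in consecutive pairs (sequence ", j, ")",
           call. = FALSE)
  }
  invisible(m)
}

#' Generate a complete, scored, grouped cohort
#'
#' Runs the whole synthetic-cohort stage: respondents, social-capital scoring,
#' group formation, group-level indices and sequence assignment.
#'
#' @param config a [cohort_config()].
#' @param seq_matrix sequence matrix, default [default_sequence_matrix()].
#' @return A list of class `"cpr_cohort"`: `respondents` (scored, with
#'   `group_id`, `sequence`, and group-level `sc_cognitive_grp`,
#'   `sc_bonding_grp` columns), `seq_matrix`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            seq_matrix = default_sequence_matrix()) {
  validate_sequence_matrix(seq_matrix)
  if (ncol(seq_matrix) < config$n_sequences)
    stop("sequence matrix has fewer columns than n_sequences", call. = FALSE)
  d <- generate_respondents(config)
  d <- score_survey(d, config$catalog)
  d <- form_groups(d, config)
  gids <- sort(unique(d$group_id))
  gidx <- do.call(rbind, lapply(gids, function(g)
    group_index(d[d$group_id == g, ], config$group_size)))
  gidx$group_id <- gids
  names(gidx)[1:3] <- c("sc_cognitive_grp", "sc_bonding_grp", "sc_aggregate_grp")
  d <- merge(d, gidx, by = "group_id", sort = FALSE)
  seq_assign <- assign_sequences(gids, config$n_sequences, config$seed)
  d$sequence <- unname(seq_assign[d$group_id])
  d <- d[order(d$group_id, d$respondent_id), ]
  rownames(d) <- NULL
  structure(list(respondents = d, seq_matrix = seq_matrix, config = config),
            class = "cpr_cohort")
}

#' @export
print.cpr_cohort <- function(x, ...) {
  d <- x$respondents
  cat(sprintf("Synthetic harvester cohort: %d respondents, %d groups, %d sequences\n",
              nrow(d), length(unique(d$group_id)), x$config$n_sequences))
  cat(sprintf("  female share %.1f%%, mean age %.1f, mean schooling %.1f, mean family size %.2f\n",
              100 * mean(d$female), mean(d$age), mean(d$schooling), mean(d$family_size)))
  invisible(x)
}
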