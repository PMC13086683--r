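#' The social-capital item catalog
#'
#' Thirteen 1-4 Likert items measuring two dimensions of social capital among
#' frankincense harvesters: nine *cognitive* items (one trust, four
#' reciprocity, four social norms) and four *structural bonding* items (three
#' participation, one organizational membership). Each item carries the
#' published calibration mean and standard deviation on the 1-4 scale, which
#' the synthetic cohort generator targets.
#'
#' The negatively worded reciprocity item ("would try to take advantage of
#' you...") is by default scored as printed; set `reverse_negative_items =
#' TRUE` to flip it (`5 - response`) before standardization.
#'
#' @param reverse_negative_items logical; reverse-code the negatively keyed
#'   reciprocity item.
#' @return A data frame with columns `item_id`, `dimension`, `subdomain`,
#'   `text`, `calib_mean`, `calib_sd`, `reverse`.
#' @export
sc_item_catalog <- function(reverse_negative_items = FALSE) {
  path <- system.file("extdata", "sc_items.json", package = "boswellia")
  cat_df <- jsonlite::fromJSON(path)
  cat_df$reverse <- reverse_negative_items & cat_df$item_id == "recip_advantage"
  stopifnot(sum(cat_df$dimension == "cognitive") == 9L,
            sum(cat_df$dimension == "bonding") == 4L)
  cat_df
}

#' Z-standardize Likert item responses across respondents
#'
#' Centers each item at its sample mean and scales it to unit sample standard
#' deviation (denominator n-1), so that scores below zero mean below-average
#' social capital on that item.
#'
#' @param responses data frame or matrix of integer responses in 1..4, one row
#'   per respondent, columns named by `item_id`.
#' @param catalog item catalog from [sc_item_catalog()]; used to order and
#'   (optionally) reverse-code items.
#' @return A numeric matrix of z-scores with the catalog's items as columns.
#' @export
standardize_items <- function(responses, catalog = sc_item_catalog()) {
  missing_items <- setdiff(catalog$item_id, colnames(responses))
  if (length(missing_items))
    stop("incomplete responses: missing item(s) ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(as.data.frame(responses)[, catalog$item_id, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least two respondents to standardize", call. = FALSE)
  if (any(is.na(x)) || any(x < 1 | x > 4))
    stop("responses must be complete and in 1..4", call. = FALSE)
  rev_cols <- which(catalog$reverse)
  if (length(rev_cols)) x[, rev_cols] <- 5 - x[, rev_cols]
  sds <- apply(x, 2L, sd)
  degenerate <- sds == 0
  if (any(degenerate))
    stop("degenerate item (zero variance): ",
         paste(catalog$item_id[degenerate], collapse = ", "), call. = FALSE)
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Individual social-capital indices
#'
#' The cognitive (bonding) index is the unweighted mean of the respondent's
#' nine cognitive (four bonding) item z-scores; the aggregate index is the sum
#' of the two.
#'
#' @param z matrix of item z-scores from [standardize_items()].
#' @inheritParams standardize_items
#' @return Data frame with columns `sc_cognitive`, `sc_bonding`, `sc_aggregate`.
#' @export
individual_index <- function(z, catalog = sc_item_catalog()) {
  missing_items <- setdiff(catalog$item_id, colnames(z))
  if (length(missing_items))
    stop("incomplete responses: missing item(s) ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  cog <- rowMeans(z[, catalog$item_id[catalog$dimension == "cognitive"], drop = FALSE])
  bon <- rowMeans(z[, catalog$item_id[catalog$dimension == "bonding"], drop = FALSE])
  data.frame(sc_cognitive = cog, sc_bonding = bon, sc_aggregate = cog + bon)
}

#' Score a respondent table
#'
#' Convenience wrapper: standardizes the item columns of a respondent data
#' frame and appends `sc_cognitive`, `sc_bonding`, `sc_aggregate` columns.
#'
#' @param respondents data frame with one row per respondent containing the
#'   catalog's item columns (plus any demographics, which are passed through).
#' @inheritParams standardize_items
#' @return The input data frame with three index columns appended.
#' @export
score_survey <- function(respondents, catalog = sc_item_catalog()) {
  z <- standardize_items(respondents, catalog)
  idx <- individual_index(z, catalog)
  respondents$sc_cognitive <- idx$sc_cognitive
  respondents$sc_bonding <- idx$sc_bonding
  respondents$sc_aggregate <- idx$sc_aggregate
  respondents
}

#' Group-level social-capital index
#'
#' Group cognitive and bonding indices are the mean of the five members'
#' individual indices (scale-comparable to the individual indices and
#' invariant to group size); the aggregate is the sum of the two dimensions.
#'
#' @param members data frame with columns `sc_cognitive` and `sc_bonding`,
#'   one row per group member.
#' @param group_size required number of members (the experiment uses 5).
#' @return One-row data frame `sc_cognitive`, `sc_bonding`, `sc_aggregate`.
#' @export
group_index <- function(members, group_size = 5L) {
  if (nrow(members) != group_size)
    stop("invalid group: expected ", group_size, " members, got ", nrow(members),
         call. = FALSE)
  cog <- mean(members$sc_cognitive)
  bon <- mean(members$sc_bonding)
  data.frame(sc_cognitive = cog, sc_bonding = bon, sc_aggregate = cog + bon)
}

#' Determinants of social capital (OLS)
#'
#' Regresses each social-capital index on the respondent's demographics (age,
#' schooling, landholding, social class, log income, adult-equivalent family
#' size, female indicator) by ordinary least squares with conventional
#' standard errors, mirroring the survey's determinants table.
#'
#' @param respondents scored respondent table (see [score_survey()]) with
#'   demographic columns `age`, `schooling`, `landholding`, `social_class`,
#'   `income`, `family_size`, `female`.
#' @param outcomes character vector of index columns to model.
#' @return A list of class `"sc_determinants"`: one `lm`-derived coefficient
#'   table per outcome plus `r_squared` and `n`.
#' @export
sc_determinants <- function(respondents,
                            outcomes = c("sc_cognitive", "sc_bonding")) {
  covars <- c("age", "schooling", "landholding", "social_class",
              "log_income", "family_size", "female")
  respondents$log_income <- log(respondents$income)
  need <- c(outcomes, covars)
  if (!all(need %in% names(respondents)))
    stop("missing columns: ", paste(setdiff(need, names(respondents)), collapse = ", "),
         call. = FALSE)
  keep <- complete.cases(respondents[, need])
  d <- respondents[keep, , drop = FALSE]
  if (nrow(d) < 20L) stop("need at least 20 complete respondents", call. = FALSE)
  X <- model.matrix(~ age + schooling + landholding + social_class +
                      log_income + family_size + female, data = d)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates: design matrix is rank deficient", call. = FALSE)
  fits <- lapply(outcomes, function(y) {
    fit <- lm(stats::reformulate(c("age", "schooling", "landholding", "social_class",
                                   "log_income", "family_size", "female"), response = y),
              data = d)
    s <- summary(fit)
    list(coefficients = s$coefficients, r_squared = s$r.squared)
  })
  names(fits) <- outcomes
  structure(list(fits = fits, n = nrow(d)), class = "sc_determinants")
}

#' @export
print.sc_determinants <- function(x, ...) {
  cat(sprintf("Determinants of social-capital indices (OLS, n = %d)\n", x$n))
  for (nm in names(x$fits)) {
    cat("\n==", nm, sprintf(" (R^2 = %.3f)\n", x$fits[[nm]]$r_squared))
    printCoefmat(x$fits[[nm]]$coefficients, digits = 3, signif.stars = TRUE)
  }
  invisible(x)
}
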