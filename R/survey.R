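#' @title Survey-weighted estimation with bootstrap replicate weights
#'
#' @description
#' Covariate derivation and design-based inference for the WG-group
#' analyses: weighted least-squares means (population marginal means over
#' the weighted observed covariate distribution), ordinal linear-trend
#' tests, Rao-Scott-style corrected chi-squared tests for categorical
#' outcomes, Bonferroni thresholds, and Tukey-Kramer pairwise contrasts.
#'
#' Variance estimation re-fits every estimator under each bootstrap
#' replicate-weight vector; the replicate variance is the mean squared
#' deviation of replicate estimates around the full-sample estimate
#' (scale 1/B, as appropriate for rescaled-bootstrap weights), with B - 1
#' degrees of freedom for Wald tests.
#'
#' @name survey_estimation
NULL

# mean-squared-deviation replicate SE (scale 1/B)
replicate_se <- function(est_full, est_reps) {
  if (is.null(dim(est_reps))) est_reps <- matrix(est_reps, ncol = 1)
  sqrt(colMeans((est_reps - rep(est_full, each = nrow(est_reps)))^2))
}

#' Weighted empirical quantiles (inverse-CDF)
#'
#' Smallest observed value whose cumulative weight reaches `p` of the total.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (default equal).
#' @param probs Probabilities in (0, 1].
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = NULL, probs) {
  if (is.null(w)) w <- rep(1, length(x))
  o <- order(x)
  cw <- cumsum(w[o])
  total <- cw[length(cw)]
  vapply(probs, function(p) x[o][which(cw >= p * total)[1]], numeric(1))
}

# covariates -------------------------------------------------------------------

#' Low-income status from household size and income
#'
#' Census-style thresholds: 1 person at or below 19,999; 2-3 persons
#' 39,999; 4 or more persons 59,999 (CAD, all sources).
#'
#' @param household_size Integer(s) >= 1.
#' @param income Total household income(s) >= 0.
#' @return Logical vector.
#' @export
#' @examples
#' derive_low_income(1, 19999) # TRUE
#' derive_low_income(3, 40000) # FALSE
derive_low_income <- function(household_size, income) {
  if (any(!is.finite(income) | income < 0)) {
    validation_error("household income must be >= 0")
  }
  if (any(!is.finite(household_size) | household_size < 1)) {
    validation_error("household_size must be >= 1")
  }
  threshold <- ifelse(household_size <= 1, 19999,
                      ifelse(household_size <= 3, 39999, 59999))
  income <= threshold
}

#' Overweight/obesity status
#'
#' Adults (age >= 19): BMI >= 25 kg/m2. Children: BMI z-score percentile
#' >= 75.
#'
#' @param age_years Age(s) in years.
#' @param bmi BMI for adults (NA for children).
#' @param bmi_z_pctile BMI z-score percentile for children (NA for adults).
#' @return Logical vector.
#' @export
derive_overweight <- function(age_years, bmi = NULL, bmi_z_pctile = NULL) {
  n <- length(age_years)
  if (is.null(bmi)) bmi <- rep(NA_real_, n)
  if (is.null(bmi_z_pctile)) bmi_z_pctile <- rep(NA_real_, n)
  adult <- age_years >= 19
  if (any(adult & is.na(bmi)) || any(!adult & is.na(bmi_z_pctile))) {
    validation_error("adults need bmi and children need bmi_z_pctile")
  }
  ifelse(adult, bmi >= 25, bmi_z_pctile >= 75)
}

#' Categorize energy intake by weighted quantiles
#'
#' Energy enters the adjustment models as a categorical covariate (to absorb
#' a possibly non-linear energy pattern); levels are weighted quantile bins
#' (default quintiles) of the supplied energy values.
#'
#' @param energy Energy intakes (kcal).
#' @param weights Sampling weights (default equal).
#' @param n_levels Number of categories (default 5).
#' @return Factor with levels `Q1..Qn` (fewer if quantiles tie).
#' @export
derive_energy_cat <- function(energy, weights = NULL, n_levels = 5) {
  probs <- seq_len(n_levels - 1) / n_levels
  q <- weighted_quantile(energy, weights, probs)
  breaks <- unique(c(-Inf, q, Inf))
  if (length(breaks) < n_levels + 1) {
    warning("tied energy quantiles; fewer categories than requested", call. = FALSE)
  }
  cut(energy, breaks = breaks, labels = paste0("Q", seq_len(length(breaks) - 1)),
      include.lowest = TRUE)
}

#' Names of the adjustment covariates
#' @return Character vector of the covariate columns built by
#'   [build_covariates()].
#' @export
covariate_columns <- function() {
  c("energy_cat", "age_years", "gender", "overweight_obese", "low_income",
    "supplement_use")
}

#' Assemble the adjustment covariate set
#'
#' Energy category (weighted quantiles within age stratum), continuous age,
#' gender, overweight/obesity, low income and supplement use. Participants
#' with any missing covariate are dropped listwise with a message.
#'
#' @param participants Validated participant table.
#' @param profiles Intake profiles supplying `energy_kcal`.
#' @param n_energy_levels Energy categories per stratum (default 5).
#' @return A data.frame `participant_id`, `stratum`, and
#'   [covariate_columns()].
#' @export
build_covariates <- function(participants, profiles, n_energy_levels = 5) {
  m <- match(participants$participant_id, profiles$participant_id)
  if (any(is.na(m))) {
    integrity_error("every participant needs an intake profile for covariates")
  }
  energy <- profiles$energy_kcal[m]
  stratum <- ifelse(participants$age_years >= 19, "adult", "child")
  energy_cat <- factor(rep(NA_character_, nrow(participants)),
                       levels = paste0("Q", seq_len(n_energy_levels)))
  for (s in unique(stratum)) {
    idx <- stratum == s
    energy_cat[idx] <- derive_energy_cat(energy[idx], participants$weight[idx],
                                         n_energy_levels)
  }
  out <- data.frame(
    participant_id = participants$participant_id,
    stratum = stratum,
    energy_cat = energy_cat,
    age_years = participants$age_years,
    gender = factor(participants$gender, levels = c("female", "male")),
    overweight_obese = derive_overweight(participants$age_years,
                                         participants$bmi,
                                         participants$bmi_z_pctile),
    low_income = derive_low_income(participants$household_size,
                                   participants$household_income),
    supplement_use = as.logical(participants$supplement_use),
    stringsAsFactors = FALSE
  )
  keep <- stats::complete.cases(out[covariate_columns()])
  if (any(!keep)) {
    message(sprintf("dropping %d participant(s) with missing covariates", sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  out
}

# linear models ----------------------------------------------------------------

# build a model matrix for outcome ~ group + covariates, with rank check
lsmeans_design <- function(group, covariates, n) {
  df <- data.frame(.group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.logical(v)) v <- factor(v)
      df[[nm]] <- v
    }
  }
  X <- stats::model.matrix(~ ., df)
  r <- qr(X)
  if (r$rank < ncol(X)) {
    aliased <- colnames(X)[r$pivot[(r$rank + 1):ncol(X)]]
    gs_stop("grainscore_estimation_error", sprintf(
      "design matrix is rank deficient; aliased term(s): %s",
      paste(aliased, collapse = ", ")
    ))
  }
  list(df = df, X = X)
}

fit_wls <- function(X, y, w) {
  stats::lm.wfit(X, y, w)$coefficients
}

#' Survey-weighted least-squares means by group
#'
#' Fits a weighted linear regression of the outcome on group indicators plus
#' covariates and reports, for each group, the model prediction averaged
#' over the weighted observed covariate distribution (the population
#' marginal mean). With replicate weights, standard errors come from
#' re-estimating the whole quantity (including the reference distribution)
#' under each replicate; without them, classical weighted-OLS standard
#' errors are used as a model-based fallback.
#'
#' @param outcome Numeric outcome vector.
#' @param group Group labels (factor or coercible; unused levels dropped).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param weights Sampling weights (default equal).
#' @param repweights Optional replicate-weight matrix (rows = observations).
#' @return An object of class `wg_lsmeans`: estimates, SEs, per-group n,
#'   replicate estimates, and the fitted coefficients.
#' @export
weighted_lsmeans <- function(outcome, group, covariates = NULL, weights = NULL,
                             repweights = NULL) {
  # unordered factor throughout so the fit and the prediction grids share
  # treatment contrasts (ordered factors would get polynomial contrasts)
  lev0 <- if (is.factor(group)) levels(group) else sort(unique(as.character(group)))
  group <- droplevels(factor(as.character(group), levels = lev0))
  n <- length(outcome)
  if (is.null(weights)) weights <- rep(1, n)
  if (nlevels(group) < 2) {
    gs_stop("grainscore_estimation_error", "at least 2 nonempty groups required")
  }
  d <- lsmeans_design(group, covariates, n)
  beta <- fit_wls(d$X, outcome, weights)

  lev <- levels(group)
  # per-group design matrices with everyone assigned to group g
  Xg <- lapply(lev, function(g) {
    dg <- d$df
    dg$.group <- factor(rep(g, n), levels = lev)
    stats::model.matrix(~ ., dg)
  })
  lsmean_at <- function(b, w) {
    vapply(Xg, function(X) sum((colSums(X * w) / sum(w)) * b), numeric(1))
  }
  est <- lsmean_at(beta, weights)
  names(est) <- lev

  n_per_group <- as.integer(table(group)[lev])
  if (!is.null(repweights)) {
    B <- ncol(repweights)
    reps <- t(vapply(seq_len(B), function(b) {
      lsmean_at(fit_wls(d$X, outcome, repweights[, b]), repweights[, b])
    }, numeric(length(lev))))
    colnames(reps) <- lev
    se <- replicate_se(est, reps)
    df_resid <- B - 1
  } else {
    fit <- stats::lm.wfit(d$X, outcome, weights)
    rss <- sum(weights * fit$residuals^2)
    df_resid <- n - ncol(d$X)
    sigma2 <- rss / df_resid
    XtWXi <- chol2inv(chol(crossprod(d$X * sqrt(weights))))
    L <- do.call(rbind, lapply(Xg, function(X) colSums(X * weights) / sum(weights)))
    se <- sqrt(diag(L %*% (sigma2 * XtWXi) %*% t(L)))
    reps <- NULL
  }
  names(se) <- lev
  structure(list(
    groups = lev, estimate = est, se = se, n_per_group = n_per_group,
    rep_estimates = reps, beta = beta, df = df_resid
  ), class = "wg_lsmeans")
}

#' @export
print.wg_lsmeans <- function(x, ...) {
  cat("Survey-weighted least-squares means\n")
  print(data.frame(group = x$groups, lsmean = x$estimate, se = x$se,
                   n = x$n_per_group, row.names = NULL))
  invisible(x)
}

#' Ordinal linear-trend test across WG groups
#'
#' Replaces the group factor by ordinal scores (default 0..K-1), fits the
#' weighted covariate-adjusted regression, and tests the score slope with a
#' two-sided Wald test using the replicate-weight SE (df = B - 1).
#'
#' @inheritParams weighted_lsmeans
#' @param scores Numeric scores per group level (default `0:(K-1)`).
#' @return List: `slope`, `se`, `statistic`, `df`, `p.value`.
#' @export
linear_trend_test <- function(outcome, group, covariates = NULL, weights = NULL,
                              repweights = NULL, scores = NULL) {
  lev0 <- if (is.factor(group)) levels(group) else sort(unique(as.character(group)))
  group <- droplevels(factor(as.character(group), levels = lev0))
  if (is.null(scores)) scores <- seq_len(nlevels(group)) - 1
  score <- scores[as.integer(group)]
  if (length(unique(score)) < 2) {
    gs_stop("grainscore_test_error", "trend test undefined: < 2 distinct group scores")
  }
  if (length(unique(outcome)) == 1) { # constant outcome: flat trend by definition
    return(list(slope = 0, se = 0, statistic = 0, df = NA_integer_, p.value = 1))
  }
  n <- length(outcome)
  if (is.null(weights)) weights <- rep(1, n)
  df <- data.frame(.score = score)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.logical(v)) v <- factor(v)
      df[[nm]] <- v
    }
  }
  X <- stats::model.matrix(~ ., df)
  if (qr(X)$rank < ncol(X)) {
    gs_stop("grainscore_estimation_error", "trend design matrix is rank deficient")
  }
  slope <- fit_wls(X, outcome, weights)[[".score"]]
  if (!is.null(repweights)) {
    B <- ncol(repweights)
    rep_slopes <- vapply(seq_len(B), function(b) {
      fit_wls(X, outcome, repweights[, b])[[".score"]]
    }, numeric(1))
    se <- replicate_se(slope, rep_slopes)
    dfree <- B - 1
  } else {
    fit <- stats::lm.wfit(X, outcome, weights)
    sigma2 <- sum(weights * fit$residuals^2) / (n - ncol(X))
    XtWXi <- chol2inv(chol(crossprod(X * sqrt(weights))))
    se <- sqrt(sigma2 * XtWXi[".score" == colnames(X), ".score" == colnames(X)])
    dfree <- n - ncol(X)
  }
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
    tstat <- if (slope == 0) 0 else Inf
  } else {
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), df = dfree)
  }
  list(slope = slope, se = se, statistic = tstat, df = dfree, p.value = p)
}

#' Design-corrected chi-squared test for a categorical outcome
#'
#' Pearson chi-squared on the weighted contingency table (scaled to the
#' sample size, so it reduces to the classical statistic under equal
#' weights), divided by a first-order design-effect correction estimated
#' from the replicate weights (Rao-Scott style).
#'
#' @param x Categorical variable (factor or coercible).
#' @param group Group labels.
#' @param weights Sampling weights (default equal).
#' @param repweights Optional replicate-weight matrix.
#' @return List: `statistic` (uncorrected), `deff`, `adjusted_statistic`,
#'   `df`, `p.value`.
#' @export
weighted_chi2 <- function(x, group, weights = NULL, repweights = NULL) {
  x <- droplevels(factor(x)); group <- droplevels(factor(group))
  n <- length(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (nlevels(x) < 2 || nlevels(group) < 2) {
    gs_stop("grainscore_test_error",
            "chi-squared test undefined: need >= 2 levels and >= 2 groups")
  }
  wtab <- function(w) {
    t <- tapply(w, list(x, group), sum, default = 0)
    t / sum(t)
  }
  p_hat <- wtab(weights)
  zero_r <- rowSums(p_hat) == 0; zero_c <- colSums(p_hat) == 0
  if (any(zero_r) || any(zero_c)) {
    warning("collapsing zero-weight rows/columns in contingency table", call. = FALSE)
    p_hat <- p_hat[!zero_r, !zero_c, drop = FALSE]
  }
  if (any(dim(p_hat) < 2)) {
    gs_stop("grainscore_test_error", "chi-squared test undefined after collapsing")
  }
  expected <- outer(rowSums(p_hat), colSums(p_hat))
  X2 <- n * sum((p_hat - expected)^2 / expected)
  dfree <- (nrow(p_hat) - 1) * (ncol(p_hat) - 1)

  deff <- 1
  if (!is.null(repweights)) {
    B <- ncol(repweights)
    rep_p <- vapply(seq_len(B), function(b) {
      pb <- wtab(repweights[, b])
      as.vector(pb[!zero_r, !zero_c])
    }, numeric(length(p_hat)))
    v_rep <- rowMeans((rep_p - as.vector(p_hat))^2)
    v_srs <- as.vector(p_hat) * (1 - as.vector(p_hat)) / n
    ok <- v_srs > 0
    if (any(ok)) deff <- max(mean(v_rep[ok] / v_srs[ok]), .Machine$double.eps)
  }
  X2_adj <- X2 / deff
  list(
    statistic = X2, deff = deff, adjusted_statistic = X2_adj, df = dfree,
    p.value = stats::pchisq(X2_adj, dfree, lower.tail = FALSE)
  )
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 22) # 0.002272727...
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) validation_error("alpha must lie in (0, 1)")
  if (m < 1) validation_error("m must be >= 1")
  alpha / m
}

#' Tukey-Kramer pairwise contrasts of LS-means
#'
#' All pairwise LS-mean differences from a [weighted_lsmeans()] fit, with
#' studentized-range adjusted p-values (q = sqrt(2) |diff| / SE(diff),
#' compared to the studentized range with K means and the fit's df). SEs of
#' differences come from the stored replicate estimates.
#'
#' @param fit A `wg_lsmeans` object (fitted with replicate weights for
#'   design-based SEs).
#' @return A data.frame: `group_a`, `group_b`, `difference`, `se`, `p_adj`,
#'   one row per unordered pair (difference = a - b).
#' @export
tukey_kramer <- function(fit) {
  stopifnot(inherits(fit, "wg_lsmeans"))
  lev <- fit$groups
  K <- length(lev)
  pairs <- utils::combn(K, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- fit$estimate[a] - fit$estimate[b]
    if (!is.null(fit$rep_estimates)) {
      se <- replicate_se(diff, fit$rep_estimates[, a] - fit$rep_estimates[, b])
    } else {
      se <- sqrt(fit$se[a]^2 + fit$se[b]^2) # model-based fallback, no covariance
    }
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
    } else {
      q <- sqrt(2) * abs(diff) / se
      p <- stats::ptukey(q, nmeans = K, df = fit$df, lower.tail = FALSE)
    }
    data.frame(group_a = lev[a], group_b = lev[b], difference = unname(diff),
               se = unname(se), p_adj = unname(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
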