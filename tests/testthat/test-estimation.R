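test_that("LS-means reduce to group means with equal weights and no covariates", {
  set.seed(21)
  g <- factor(rep(c("a", "b", "c", "d"), times = c(12, 9, 14, 10)))
  y <- stats::rnorm(length(g), mean = as.integer(g))
  fit <- weighted_lsmeans(y, g)
  expect_equal(fit$estimate, tapply(y, g, mean), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("LS-means equal unadjusted weighted means when covariates are balanced", {
  # identical covariate distribution in each group, orthogonal to group
  g <- factor(rep(c("a", "b"), each = 6))
  x <- rep(c(-1, 0, 1, -1, 0, 1), 2)
  f <- factor(rep(c("u", "v"), 6))
  set.seed(3)
  w <- rep(stats::runif(6, 0.5, 2), 2) # same weights pattern per group
  y <- 2 * (g == "b") + 0.7 * x + (f == "v") + c(0.1, -0.2, 0.05, 0, 0.2, -0.1,
                                                 0.1, -0.2, 0.05, 0, 0.2, -0.1)
  fit <- weighted_lsmeans(y, g, data.frame(x = x, f = f), w)
  raw <- vapply(levels(g), function(l) stats::weighted.mean(y[g == l], w[g == l]),
                numeric(1))
  expect_equal(fit$estimate, raw, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("weighted fits match an independent normal-equations solver", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(40:80, 1)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    while (nlevels(droplevels(g)) < 3) g <- factor(sample(letters[1:3], n, TRUE))
    x <- stats::rnorm(n)
    f <- factor(sample(c("u", "v"), n, replace = TRUE))
    w <- stats::runif(n, 0.2, 3)
    y <- stats::rnorm(n, as.integer(g) + x - (f == "v"))
    fit <- weighted_lsmeans(y, g, data.frame(x = x, f = f), w)

    # brute-force normal equations and weighted-average prediction rows
    X <- stats::model.matrix(~ g + x + f)
    beta <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
    for (lev in levels(g)) {
      Xg <- X
      Xg[, grep("^g", colnames(X))] <- 0
      if (lev != levels(g)[1]) Xg[, paste0("g", lev)] <- 1
      expect_equal(fit$estimate[[lev]],
                   sum((colSums(Xg * w) / sum(w)) * beta), tolerance = 1e-8)
    }
  }
})

test_that("rank-deficient designs raise an estimation error naming the alias", {
  g <- factor(rep(c("a", "b"), each = 5))
  x <- as.numeric(g == "b") # aliased with the group indicator
  expect_error(weighted_lsmeans(stats::rnorm(10), g, data.frame(x = x)),
               "aliased", class = "grainscore_estimation_error")
})

test_that("trend test handles degenerate and perfect trends", {
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  rw <- matrix(stats::runif(400, 0.5, 2), 40, 10)

  const <- rep(5, 40)
  tr <- linear_trend_test(const, g, repweights = rw)
  expect_equal(tr$slope, 0)
  expect_equal(tr$p.value, 1)

  perfect <- as.integer(g) - 1
  tr2 <- linear_trend_test(perfect, g, repweights = rw)
  expect_equal(tr2$slope, 1)
  expect_lt(tr2$p.value, 1e-12)

  expect_error(linear_trend_test(stats::rnorm(10), factor(rep("a", 10))),
               class = "grainscore_test_error")
})

test_that("trend slope equals the per-step difference when LS-means are linear", {
  g <- factor(rep(c("a", "b", "c", "d"), each = 8))
  set.seed(5)
  w <- stats::runif(32, 0.5, 2)
  y <- 3 * (as.integer(g) - 1) # noiseless: LS-means exactly linear in score
  tr <- linear_trend_test(y, g, weights = w)
  fit <- weighted_lsmeans(y, g, weights = w)
  expect_equal(tr$slope, unname(diff(fit$estimate))[1], tolerance = 1e-10)
  expect_equal(tr$slope, 3)
})

test_that("weighted chi-squared reduces to the classical Pearson statistic", {
  set.seed(12)
  x <- factor(sample(c("yes", "no"), 120, replace = TRUE))
  g <- factor(sample(c("g1", "g2", "g3"), 120, replace = TRUE))
  ours <- weighted_chi2(x, g)
  classical <- suppressWarnings(stats::chisq.test(table(x, g), correct = FALSE))
  expect_equal(ours$statistic, unname(classical$statistic), tolerance = 1e-8)
  expect_equal(ours$p.value, classical$p.value, tolerance = 1e-8)

  # identical distributions across groups: statistic 0, p 1
  x2 <- factor(rep(c("yes", "no"), 30))
  g2 <- factor(rep(c("g1", "g2"), each = 30))
  even <- weighted_chi2(x2, g2)
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)

  expect_error(weighted_chi2(factor(rep("one", 20)), g[1:20]),
               class = "grainscore_test_error")
})

test_that("design correction inflates or deflates the chi-squared statistic", {
  sim <- small_sim()
  p <- sim$sv$participants
  adult <- p$age_years >= 19
  grp <- droplevels(sim$asg$wg_group[match(p$participant_id[adult],
                                           sim$asg$participant_id)])
  res <- weighted_chi2(p$gender[adult], grp, p$weight[adult],
                       replicate_weight_matrix(p)[adult, ])
  expect_gt(res$deff, 0)
  expect_equal(res$adjusted_statistic, res$statistic / res$deff)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
})

test_that("Bonferroni thresholds reproduce the published cutoffs", {
  expect_equal(bonferroni_threshold(0.05, 22), 0.05 / 22)
  expect_equal(round(bonferroni_threshold(0.05, 22), 5), 0.00227)
  expect_equal(round(bonferroni_threshold(0.05, 24), 5), 0.00208)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 4), class = "grainscore_validation_error")
})

test_that("Tukey-Kramer contrasts are antisymmetric and match the classical test", {
  set.seed(31)
  g <- factor(rep(c("a", "b", "c", "d"), each = 15))
  y <- stats::rnorm(60, mean = c(0, 0.5, 1, 1.5)[as.integer(g)])

  fit <- weighted_lsmeans(y, g) # equal weights, model-based SEs
  tk <- tukey_kramer(fit)
  oracle <- stats::TukeyHSD(stats::aov(y ~ g))$g
  for (j in seq_len(nrow(tk))) {
    key <- paste0(tk$group_b[j], "-", tk$group_a[j])
    expect_equal(-tk$difference[j], oracle[key, "diff"], tolerance = 1e-8)
    expect_equal(tk$p_adj[j], oracle[key, "p adj"], tolerance = 1e-3)
  }

  # antisymmetry under relabelling: reverse the level order
  g2 <- factor(g, levels = rev(levels(g)))
  tk2 <- tukey_kramer(weighted_lsmeans(y, g2))
  for (j in seq_len(nrow(tk))) {
    m <- which(tk2$group_a == tk$group_b[j] & tk2$group_b == tk$group_a[j])
    expect_equal(tk2$difference[m], -tk$difference[j], tolerance = 1e-10)
  }

  # identical groups: zero difference, p = 1
  y0 <- rep(c(1, 2, 3), 8)
  g0 <- factor(rep(c("a", "b"), each = 12))
  rw0 <- matrix(rep(stats::runif(24, 0.5, 2), 8), 24, 8)
  fit0 <- weighted_lsmeans(y0, g0, weights = rep(1, 24),
                           repweights = matrix(1, 24, 8))
  tk0 <- tukey_kramer(fit0)
  expect_equal(tk0$difference, 0)
  expect_equal(tk0$p_adj, 1)
})

test_that("replicate-weight LS-mean SEs track the sampling variability", {
  sim <- small_sim()
  p <- sim$sv$participants
  adult <- p$age_years >= 19
  ids <- p$participant_id[adult]
  grp <- droplevels(sim$asg$wg_group[match(ids, sim$asg$participant_id)])
  m <- match(ids, sim$prof$participant_id)
  y <- sim$prof$nut_magnesium[m] * 2000 / sim$prof$energy_kcal[m]
  fit <- weighted_lsmeans(y, grp, weights = p$weight[adult],
                          repweights = replicate_weight_matrix(p)[adult, ])
  expect_true(all(fit$se > 0))
  # magnesium rises from non-consumers to high-WG (configured positive slope)
  expect_gt(fit$estimate[["high_wg"]], fit$estimate[["no_wg"]])
  tr <- linear_trend_test(y, grp, weights = p$weight[adult],
                          repweights = replicate_weight_matrix(p)[adult, ])
  expect_gt(tr$slope, 0)
  expect_lt(tr$p.value, 0.01)
})
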