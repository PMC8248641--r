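test_that("generation is deterministic in the seed and varies across seeds", {
  cfg <- sim_config(seed = 9, n_children = 60, n_adults = 60,
                    n_replicates = 8, n_psu = 8)
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1, c2)
  s1 <- generate_survey(cfg, c1)
  s2 <- generate_survey(cfg, c1)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$recalls, s2$recalls)

  cfg2 <- sim_config(seed = 10, n_children = 60, n_adults = 60,
                     n_replicates = 8, n_psu = 8)
  c3 <- generate_catalog(cfg2)
  nut_cols <- paste0("nut_", analysis_nutrients()$nutrient_id)
  expect_true(any(as.matrix(c1[nut_cols]) != as.matrix(c3[nut_cols])))
})

test_that("catalog covers all categories; WG foods span tiers and BNS sources", {
  cfg <- sim_config(seed = 5)
  catalog <- generate_catalog(cfg)
  expect_silent(validate_catalog(catalog))
  expect_true(all(cfg_categories() %in% catalog$cfg_group))
  wg <- catalog[catalog$cfg_group == "whole_grains", ]
  expect_setequal(unique(wg$cfg_tier), 1:4)
  expect_gte(length(unique(wg$bns_group)), 6)
  expect_true("whole grain and whole wheat bread" %in% wg$bns_group)
  expect_true("whole grain, oat, and high fibre breakfast cereal" %in% wg$bns_group)
})

test_that("one food per category yields exactly 12 foods when no gradients are configured", {
  cfg <- sim_config(seed = 2, n_foods_per_category = 1, nutrient_effect = NULL)
  catalog <- generate_catalog(cfg)
  expect_identical(nrow(catalog), 12L)
  expect_silent(validate_catalog(catalog))
  # gradients need room for the two gradient dishes
  expect_error(sim_config(seed = 2, n_foods_per_category = 2),
               class = "grainscore_validation_error")
})

test_that("consumer probability controls the zero-WG fraction", {
  cfg0 <- sim_config(seed = 3, n_children = 40, n_adults = 40,
                     prob_wg_consumer = c(child = 0, adult = 0),
                     n_replicates = 8, n_psu = 8)
  cat0 <- generate_catalog(cfg0)
  sv0 <- generate_survey(cfg0, cat0)
  expo0 <- compute_wg_exposure(sv0$recalls, cat0, sv0$participants$participant_id)
  expect_true(all(expo0$wg_grams == 0))

  cfg <- sim_config(seed = 17, n_children = 10, n_adults = 4000,
                    prob_wg_consumer = c(child = 0.5, adult = 0.5),
                    n_replicates = 8, n_psu = 20)
  catalog <- generate_catalog(cfg)
  sv <- generate_survey(cfg, catalog)
  expo <- compute_wg_exposure(sv$recalls, catalog, sv$participants$participant_id)
  adult <- sv$participants$age_years >= 19
  frac <- mean(expo$wg_grams[adult] == 0)
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
})

test_that("replicate weight columns are calibrated to the full-sample total", {
  sim <- small_sim()
  p <- sim$sv$participants
  rw <- replicate_weight_matrix(p)
  for (s in c("child", "adult")) {
    idx <- (p$age_years >= 19) == (s == "adult")
    tot <- sum(p$weight[idx])
    rel <- abs(colSums(rw[idx, , drop = FALSE]) / tot - 1)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("null nutrient gradients give OLS slopes within 2 SE of zero", {
  cfg <- sim_config(seed = 31, n_children = 10, n_adults = 2000,
                    nutrient_effect = stats::setNames(numeric(0), character(0)),
                    n_replicates = 8, n_psu = 20)
  catalog <- generate_catalog(cfg)
  sv <- generate_survey(cfg, catalog)
  prof <- build_intake_profiles(sv$recalls, catalog, sv$participants$participant_id)
  adult <- sv$participants$age_years >= 19
  wg <- sv$truth$wg_grams[adult]
  for (nm in c("fiber", "folic_acid", "sodium", "calcium")) {
    y <- (prof[[paste0("nut_", nm)]] * 2000 / prof$energy_kcal)[adult]
    cf <- summary(stats::lm(y ~ wg))$coefficients
    expect_lt(abs(cf[2, 1]) / cf[2, 2], 2, label = paste("slope z for", nm))
  }
})

test_that("configured gradients are recovered by OLS on generated data", {
  sim <- small_sim()
  prof <- sim$prof
  adult <- sim$sv$participants$age_years >= 19
  wg <- sim$sv$truth$wg_grams[adult]
  eff <- sim$cfg$nutrient_effect
  for (nm in c("fiber", "folic_acid", "magnesium")) {
    y <- (prof[[paste0("nut_", nm)]] * 2000 / prof$energy_kcal)[adult]
    cf <- summary(stats::lm(y ~ wg))$coefficients
    expect_lt(abs(cf[2, 1] - eff[[nm]]) / cf[2, 2], 2.5,
              label = paste("slope recovery for", nm))
  }
})
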