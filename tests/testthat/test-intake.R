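test_that("intake profiles are grams-times-density sums", {
  catalog <- toy_catalog()

  # no records: all-zero profile
  prof0 <- build_intake_profiles(toy_recalls(list("p9", "FR1", 0)), catalog,
                                 participant_ids = "px")
  expect_equal(prof0$energy_kcal, 0)
  expect_true(all(as.matrix(prof0[paste0("nut_", analysis_nutrients()$nutrient_id)]) == 0))
  expect_true(all(as.matrix(prof0[food_group_cells()]) == 0))

  # single food direct arithmetic: 100 g at fiber 0.05 g/g
  prof1 <- build_intake_profiles(toy_recalls(list("p1", "WG1", 100)), catalog)
  expect_equal(prof1$nut_fiber, 5)
  expect_equal(prof1$energy_kcal, 250)

  # two-food menu, hand-summed: 60 g WG1 + 50 g FR1
  prof2 <- build_intake_profiles(
    toy_recalls(list("p2", "WG1", 60), list("p2", "FR1", 50)), catalog)
  expect_equal(prof2$energy_kcal, 60 * 2.5 + 50 * 0.5)             # 175
  expect_equal(prof2$nut_fiber, 60 * 0.05 + 50 * 0.024)            # 4.2
  expect_equal(prof2$nut_carbohydrate, 60 * 0.45 + 50 * 0.14)      # 34
  expect_equal(prof2$nut_iron, 60 * 0.012)                         # 0.72
  expect_equal(prof2$nut_vitamin_c, 50 * 0.05)                     # 2.5
  # macro percent with 4/9/4 conversion
  expect_equal(prof2$pct_kcal_carbohydrate, 34 * 4 / 175 * 100)
  # food-group cells
  expect_equal(prof2$fg_whole_grains_t13, 60)
  expect_equal(prof2$fg_fruit_t13, 50)
  expect_equal(prof2$fg_total_t13, 110)
})

test_that("profiles are additive over record partitions", {
  sim <- small_sim()
  rec <- sim$sv$recalls
  ids <- sim$sv$participants$participant_id
  half <- seq_len(nrow(rec)) %% 2 == 0
  p_all <- build_intake_profiles(rec, sim$catalog, ids)
  p_a <- build_intake_profiles(rec[half, ], sim$catalog, ids)
  p_b <- build_intake_profiles(rec[!half, ], sim$catalog, ids)
  num <- setdiff(names(p_all), c("participant_id", "pct_kcal_carbohydrate",
                                 "pct_kcal_fat", "pct_kcal_protein"))
  for (col in num) {
    expect_equal(p_a[[col]] + p_b[[col]], p_all[[col]], tolerance = 1e-10,
                 info = col)
  }
})

test_that("food-group cell totals are consistent and match WG exposure", {
  sim <- small_sim()
  prof <- sim$prof
  t13 <- rowSums(prof[paste0("fg_", cfg_food_categories(), "_t13")])
  t4 <- rowSums(prof[paste0("fg_", cfg_food_categories(), "_t4")])
  expect_equal(prof$fg_total_t13, t13)
  expect_equal(prof$fg_total_t4, t4)
  expect_equal(prof$fg_total_non_cfg, prof$fg_discretionary + prof$fg_unclassified)
  expect_equal(prof$fg_whole_grains_t13 + prof$fg_whole_grains_t4,
               sim$expo$wg_grams, tolerance = 1e-10)
})

test_that("WG exposure follows the grain accounting conventions", {
  catalog <- toy_catalog()

  # 60 g WG bread (30 g serving) + 40 g refined pasta
  expo <- compute_wg_exposure(
    toy_recalls(list("p1", "WG1", 60), list("p1", "RG1", 40)), catalog)
  expect_equal(expo$wg_grams, 60)
  expect_equal(expo$wg_servings, 2)
  expect_equal(expo$total_grain_grams, 100)
  expect_equal(expo$pct_grain_from_wg, 60)

  # fruit only: no grains, 0 percent by convention
  expo2 <- compute_wg_exposure(toy_recalls(list("p2", "FR1", 120)), catalog)
  expect_equal(expo2$wg_grams, 0)
  expect_equal(expo2$pct_grain_from_wg, 0)

  # WG food without a serving size leaves servings undefined
  cat2 <- toy_catalog()
  cat2$grams_per_serving[cat2$food_code == "WG1"] <- NA
  expect_warning(
    expo3 <- compute_wg_exposure(toy_recalls(list("p3", "WG1", 60)), cat2),
    "serving"
  )
  expect_true(is.na(expo3$wg_servings))
  expect_equal(expo3$wg_grams, 60)
})

test_that("group percent of grain from WG is the mean of ratios", {
  catalog <- toy_catalog()
  rec <- toy_recalls(
    list("a", "WG1", 20), list("a", "RG1", 80),   # 20%
    list("b", "WG1", 40), list("b", "RG1", 60)    # 40%
  )
  expo <- compute_wg_exposure(rec, catalog, participant_ids = c("a", "b"))
  expect_equal(group_mean_pct_grain(expo), 30)

  # all in the no-WG group: 0 percent
  rec0 <- toy_recalls(list("a", "RG1", 80), list("b", "RG1", 10))
  expo0 <- compute_wg_exposure(rec0, catalog, participant_ids = c("a", "b"))
  expect_equal(group_mean_pct_grain(expo0), 0)

  # mean of ratios differs from ratio of means on an unbalanced toy set
  rec3 <- toy_recalls(
    list("a", "WG1", 10), list("a", "RG1", 90),   # 10% of 100 g
    list("b", "WG1", 50), list("b", "RG1", 50),   # 50% of 100 g
    list("c", "WG1", 300), list("c", "RG1", 100)  # 75% of 400 g
  )
  expo3 <- compute_wg_exposure(rec3, catalog, participant_ids = c("a", "b", "c"))
  mean_of_ratios <- group_mean_pct_grain(expo3)
  ratio_of_means <- 100 * sum(expo3$wg_grams) / sum(expo3$total_grain_grams)
  expect_equal(mean_of_ratios, (10 + 50 + 75) / 3)
  expect_equal(ratio_of_means, 100 * 360 / 600)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))

  expect_error(group_mean_pct_grain(expo3[0, ]),
               class = "grainscore_validation_error")
})
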