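toy_assignments <- function(ids, groups, age = 30) {
  data.frame(
    participant_id = ids,
    stratum = ifelse(rep_len(age, length(ids)) >= 19, "adult", "child"),
    wg_group = factor(groups, levels = wg_group_levels(), ordered = TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("a single WG food gives a one-row table covering 100 percent", {
  catalog <- toy_catalog()
  ids <- paste0("p", 1:8)
  rec <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(participant_id = ids[i], food_code = "WG1", grams = 10 * i,
               stringsAsFactors = FALSE)
  }))
  asg <- toy_assignments(ids, rep(c("low_wg", "mid_wg", "high_wg", "no_wg"), 2))
  parts <- toy_participants(ids)
  tab <- rank_wg_sources(rec, catalog, asg, parts, adjusted = FALSE)
  expect_true(all(tab$bns_group == "whole grain and whole wheat bread"))
  expect_true(all(tab$rank == 1))
  expect_equal(tab$pct_of_total_wg, rep(100, nrow(tab)))
})

test_that("rankings are invariant to catalog row order and break ties by label", {
  catalog <- toy_catalog()
  ids <- paste0("p", 1:9)
  # equal grams of the two WG foods -> tied means, alphabetical order
  rec <- do.call(rbind, lapply(ids, function(id) {
    data.frame(participant_id = id, food_code = c("WG1", "WG2"), grams = 30,
               stringsAsFactors = FALSE)
  }))
  asg <- toy_assignments(ids, rep(c("low_wg", "mid_wg", "high_wg"), 3))
  parts <- toy_participants(ids)
  t1 <- rank_wg_sources(rec, catalog, asg, parts, adjusted = FALSE)
  t2 <- rank_wg_sources(rec, catalog[rev(seq_len(nrow(catalog))), ], asg, parts,
                        adjusted = FALSE)
  expect_equal(t1, t2)
  first <- t1$bns_group[t1$rank == 1]
  expect_true(all(first == sort(unique(t1$bns_group))[1]))
})

test_that("a constructed dominant source ranks first with its configured share", {
  shares <- c(
    "whole grain, oat, and high fibre breakfast cereal" = 0.80,
    "whole grain and whole wheat bread" = 0.08,
    "rice" = 0.03,
    "rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla" = 0.03,
    "other breakfast cereal" = 0.02,
    "salty and high-fat snacks (including tortilla chips)" = 0.02,
    "cereal grains and flours" = 0.01,
    "pasta" = 0.01
  )
  cfg <- sim_config(seed = 77, n_children = 50, n_adults = 2000,
                    wg_source_shares = shares, n_replicates = 12, n_psu = 15)
  catalog <- generate_catalog(cfg)
  sv <- generate_survey(cfg, catalog)
  prof <- build_intake_profiles(sv$recalls, catalog, sv$participants$participant_id)
  expo <- compute_wg_exposure(sv$recalls, catalog, sv$participants$participant_id)
  asg <- assign_wg_groups(expo, sv$participants)
  cov <- build_covariates(sv$participants, prof)
  tab <- rank_wg_sources(sv$recalls, catalog, asg, sv$participants,
                         covariates = cov, adjusted = TRUE)
  adult_high <- tab[tab$stratum == "adult" & tab$wg_group == "high_wg", ]
  expect_equal(adult_high$bns_group[adult_high$rank == 1],
               "whole grain, oat, and high fibre breakfast cereal")
  # share of the dominant source among total WG grams, within 3 points of 80
  total_wg <- adult_high$top10_total_grams[1] / (adult_high$pct_of_total_wg[1] / 100)
  expect_lt(abs(100 * adult_high$mean_grams[1] / total_wg - 80), 3)
})

test_that("top-10 coverage is bounded by the total WG mean", {
  sim <- small_sim()
  cov <- build_covariates(sim$sv$participants, sim$prof)
  tab <- rank_wg_sources(sim$sv$recalls, sim$catalog, sim$asg,
                         sim$sv$participants, covariates = cov)
  per_table <- unique(tab[c("stratum", "wg_group", "top10_total_grams",
                            "pct_of_total_wg")])
  expect_true(all(per_table$pct_of_total_wg <= 100 + 1e-8))
  expect_true(all(per_table$pct_of_total_wg > 0))
  # subtotal equals the sum of the listed rows
  for (i in seq_len(nrow(per_table))) {
    rows <- tab[tab$stratum == per_table$stratum[i] &
                  tab$wg_group == per_table$wg_group[i], ]
    expect_equal(sum(rows$mean_grams), per_table$top10_total_grams[i],
                 tolerance = 1e-10)
  }
})
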