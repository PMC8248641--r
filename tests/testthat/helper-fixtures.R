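# small in-code fixtures shared across tests

# a catalog row with all nutrient columns zeroed unless given in `dens`
make_food <- function(code, cfg_group, tier = NA_integer_, bns = "misc",
                      wg = cfg_group == "whole_grains",
                      serving = NA_real_, energy = 1, dens = list()) {
  df <- data.frame(
    food_code = code, description = paste("food", code), cfg_group = cfg_group,
    cfg_tier = tier, bns_group = bns, is_whole_grain = wg,
    grams_per_serving = serving, energy_kcal_per_g = energy,
    stringsAsFactors = FALSE
  )
  for (nm in analysis_nutrients()$nutrient_id) {
    df[[paste0("nut_", nm)]] <- if (nm %in% names(dens)) dens[[nm]] else 0
  }
  df
}

# six-food toy catalog: WG bread + cereal, refined pasta, fruit, candy, dish
toy_catalog <- function() {
  rbind(
    make_food("WG1", "whole_grains", 2, "whole grain and whole wheat bread",
              serving = 30, energy = 2.5,
              dens = list(fiber = 0.05, carbohydrate = 0.45, iron = 0.012)),
    make_food("WG2", "whole_grains", 1,
              "whole grain, oat, and high fibre breakfast cereal",
              serving = 40, energy = 3.8,
              dens = list(fiber = 0.10, carbohydrate = 0.60, iron = 0.024)),
    make_food("RG1", "refined_grains", 1, "refined pasta", serving = 85,
              energy = 1.6, dens = list(carbohydrate = 0.30, protein = 0.05)),
    make_food("FR1", "fruit", 1, "apples", serving = 140, energy = 0.5,
              dens = list(carbohydrate = 0.14, fiber = 0.024, vitamin_c = 0.05)),
    make_food("DS1", "discretionary", NA, "confectionery", energy = 4,
              dens = list(total_sugar = 0.5, carbohydrate = 0.6)),
    make_food("UN1", "unclassified", NA, "mixed dishes", energy = 1.2,
              dens = list(protein = 0.08, sodium = 3, total_fat = 0.06))
  )
}

toy_recalls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(participant_id = r[[1]], food_code = r[[2]],
               grams = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

# participants with B replicate weights equal to the main weight (so
# replicate SEs are zero unless perturbed); adults unless age given
toy_participants <- function(ids, age = 30, weight = 1, B = 8) {
  n <- length(ids)
  age <- rep_len(age, n); weight <- rep_len(weight, n)
  df <- data.frame(
    participant_id = ids, age_years = age,
    gender = rep_len(c("female", "male"), n),
    household_size = 2, household_income = 50000,
    bmi = ifelse(age >= 19, 24, NA_real_),
    bmi_z_pctile = ifelse(age < 19, 50, NA_real_),
    supplement_use = FALSE, weight = weight,
    stringsAsFactors = FALSE
  )
  df[paste0("bsw_", seq_len(B))] <- weight
  df
}

# small simulated dataset reused by several test files (memoised)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_children = 350, n_adults = 350,
                        n_replicates = 16, n_psu = 15)
      catalog <- generate_catalog(cfg)
      sv <- generate_survey(cfg, catalog)
      prof <- build_intake_profiles(sv$recalls, catalog,
                                    sv$participants$participant_id)
      expo <- compute_wg_exposure(sv$recalls, catalog,
                                  sv$participants$participant_id)
      asg <- assign_wg_groups(expo, sv$participants)
      cache <<- list(cfg = cfg, catalog = catalog, sv = sv, prof = prof,
                     expo = expo, asg = asg)
    }
    cache
  }
})
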