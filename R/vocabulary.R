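#' Analysis vocabulary: nutrients, CFG categories, tier blocks
#'
#' The pipeline works with a fixed set of 22 analysis nutrients (plus energy),
#' 12 food-group categories aligned with the 2007 Canada Food Guide (CFG)
#' coding used in CCHS 2015, and two tier blocks (tiers 1-3 = at least
#' partially aligned with the food guide, tier 4 = not aligned).
#'
#' @name vocabulary
NULL

#' The 22 analysis nutrients and their reporting units
#'
#' Units follow CCHS 2015 reporting conventions. Catalog nutrient-density
#' columns are named `nut_<nutrient_id>` and hold amount per gram of food in
#' the unit listed here.
#'
#' @return A data.frame with columns `nutrient_id` and `unit`.
#' @export
#' @examples
#' analysis_nutrients()
analysis_nutrients <- function() {
  data.frame(
    nutrient_id = c(
      "carbohydrate", "fiber", "total_sugar", "total_fat", "saturated_fat",
      "protein", "vitamin_b12", "vitamin_b6", "vitamin_c", "folate",
      "folic_acid", "vitamin_d", "niacin", "vitamin_a", "riboflavin",
      "thiamin", "sodium", "potassium", "zinc", "calcium", "iron", "magnesium"
    ),
    unit = c(
      "g", "g", "g", "g", "g",
      "g", "ug", "ug", "mg", "ug",
      "ug", "ug", "mg", "ug_rae", "mg",
      "mg", "mg", "mg", "mg", "mg", "mg", "mg"
    ),
    stringsAsFactors = FALSE
  )
}

#' Food-group categories used by the analysis
#'
#' Twelve categories: ten CFG food categories (carrying a tier 1-4), plus
#' `discretionary` (foods the food guide flags as not recommended) and
#' `unclassified` (mixed dishes and other foods not assigned to a CFG group).
#'
#' @return Character vector of the 12 category ids, CFG categories first.
#' @export
cfg_categories <- function() {
  c(cfg_food_categories(), "discretionary", "unclassified")
}

#' The ten CFG food categories that carry a tier
#' @return Character vector of length 10.
#' @export
cfg_food_categories <- function() {
  c(
    "whole_grains", "refined_grains", "fruit", "vegetables",
    "dairy_alternatives", "meat_poultry", "processed_meats",
    "fish_shellfish", "legumes_nuts_seeds", "eggs"
  )
}

#' Food-group analysis cells of an intake profile
#'
#' Ten CFG categories crossed with tier blocks t13 (tiers 1-3) and t4
#' (tier 4), plus discretionary and unclassified grams: 22 stored cells.
#' Totals (tier 1-3, tier 4, non-CFG) are derived, not stored.
#'
#' @return Character vector of cell column names (`fg_<category>_<block>`).
#' @export
food_group_cells <- function() {
  cfg <- cfg_food_categories()
  c(
    paste0("fg_", rep(cfg, each = 2), "_", c("t13", "t4")),
    "fg_discretionary", "fg_unclassified"
  )
}

# kcal per gram of carbohydrate / fat / protein (Atwater factors)
atwater_factors <- function() c(carbohydrate = 4, fat = 9, protein = 4)

# internal: nut_ column name for a nutrient id
nut_col <- function(nutrient_id) paste0("nut_", nutrient_id)
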