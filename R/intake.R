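#' @title Per-participant intake aggregation
#'
#' @description
#' Turns long-format recall records plus a food catalog into one row per
#' participant: total energy, the 22 analysis nutrients (grams eaten times
#' density per gram, summed over foods), macronutrient percent of energy
#' (4/9/4 kcal per g), and grams by food-group analysis cell
#' ([food_group_cells()]).
#'
#' @name food_classification
NULL

#' Build per-participant intake profiles
#'
#' @param recalls Recall records (`participant_id`, `food_code`, `grams`).
#' @param catalog A validated catalog resolving every food code.
#' @param participant_ids Optional vector of ids to report (participants with
#'   no records get an all-zero profile). Defaults to the ids present in
#'   `recalls`.
#' @return A data.frame with one row per participant: `energy_kcal`,
#'   `nut_<id>` daily amounts, `pct_kcal_carbohydrate/fat/protein`
#'   (NA when energy is 0), and the `fg_*` food-group cells plus derived
#'   totals `fg_total_t13`, `fg_total_t4`, `fg_total_non_cfg`.
#' @export
build_intake_profiles <- function(recalls, catalog, participant_ids = NULL) {
  validate_recalls(recalls, catalog)
  if (is.null(participant_ids)) {
    participant_ids <- unique(recalls$participant_id)
  }
  pid <- factor(recalls$participant_id, levels = participant_ids)
  keep <- !is.na(pid)
  recalls <- recalls[keep, , drop = FALSE]
  pid <- pid[keep]
  ri <- match(recalls$food_code, catalog$food_code)

  nut_ids <- analysis_nutrients()$nutrient_id
  out <- data.frame(participant_id = participant_ids, stringsAsFactors = FALSE)

  sum_by <- function(x) {
    as.numeric(tapply(x, pid, sum, default = 0))
  }
  out$energy_kcal <- sum_by(recalls$grams * catalog$energy_kcal_per_g[ri])
  for (nm in nut_ids) {
    out[[nut_col(nm)]] <- sum_by(recalls$grams * catalog[[nut_col(nm)]][ri])
  }

  aw <- atwater_factors()
  pct <- function(amount, kcal_per_g) {
    ifelse(out$energy_kcal > 0, amount * kcal_per_g / out$energy_kcal * 100, NA_real_)
  }
  out$pct_kcal_carbohydrate <- pct(out$nut_carbohydrate, aw[["carbohydrate"]])
  out$pct_kcal_fat <- pct(out$nut_total_fat, aw[["fat"]])
  out$pct_kcal_protein <- pct(out$nut_protein, aw[["protein"]])

  grp <- catalog$cfg_group[ri]
  tier <- catalog$cfg_tier[ri]
  block <- ifelse(grp %in% cfg_food_categories(),
                  ifelse(tier <= 3, "t13", "t4"), NA)
  for (cat in cfg_food_categories()) {
    for (blk in c("t13", "t4")) {
      sel <- !is.na(block) & grp == cat & block == blk
      out[[paste0("fg_", cat, "_", blk)]] <- sum_by(recalls$grams * sel)
    }
  }
  out$fg_discretionary <- sum_by(recalls$grams * (grp == "discretionary"))
  out$fg_unclassified <- sum_by(recalls$grams * (grp == "unclassified"))

  t13_cols <- paste0("fg_", cfg_food_categories(), "_t13")
  t4_cols <- paste0("fg_", cfg_food_categories(), "_t4")
  out$fg_total_t13 <- rowSums(out[t13_cols])
  out$fg_total_t4 <- rowSums(out[t4_cols])
  out$fg_total_non_cfg <- out$fg_discretionary + out$fg_unclassified
  out
}

#' Compute per-participant whole-grain exposure
#'
#' WG grams are the summed grams of foods flagged whole grain; servings
#' divide each WG food's grams by its catalog serving size (NA for a
#' participant if any consumed WG food lacks one, with a warning); total
#' grain is whole plus refined grains, all tiers 1-4; percent of grain from
#' WG is 100 x WG / total grain, with 0 by convention for grain-free diets.
#'
#' @inheritParams build_intake_profiles
#' @return A data.frame: `participant_id`, `wg_grams`, `wg_servings`,
#'   `total_grain_grams`, `pct_grain_from_wg`.
#' @export
compute_wg_exposure <- function(recalls, catalog, participant_ids = NULL) {
  validate_recalls(recalls, catalog)
  if (is.null(participant_ids)) {
    participant_ids <- unique(recalls$participant_id)
  }
  pid <- factor(recalls$participant_id, levels = participant_ids)
  keep <- !is.na(pid)
  recalls <- recalls[keep, , drop = FALSE]
  pid <- pid[keep]
  ri <- match(recalls$food_code, catalog$food_code)

  is_wg <- catalog$is_whole_grain[ri]
  is_grain <- catalog$cfg_group[ri] %in% c("whole_grains", "refined_grains")

  wg_grams <- as.numeric(tapply(recalls$grams * is_wg, pid, sum, default = 0))
  grain <- as.numeric(tapply(recalls$grams * is_grain, pid, sum, default = 0))

  serv_each <- recalls$grams / catalog$grams_per_serving[ri]
  serv_each[!is_wg] <- 0
  # a consumed WG food without a serving size leaves servings undefined
  undef <- is_wg & recalls$grams > 0 & is.na(catalog$grams_per_serving[ri])
  servings <- as.numeric(tapply(ifelse(undef, NA_real_, serv_each), pid, sum, default = 0))
  if (any(is.na(servings))) {
    warning(sprintf(
      "%d participant(s) consumed a WG food with no serving size; servings set to NA",
      sum(is.na(servings))
    ), call. = FALSE)
  }

  pct <- ifelse(grain > 0, 100 * wg_grams / grain, 0)
  data.frame(
    participant_id = participant_ids,
    wg_grams = wg_grams, wg_servings = servings,
    total_grain_grams = grain, pct_grain_from_wg = pct,
    stringsAsFactors = FALSE
  )
}

#' Weighted group mean of percent-of-grain-from-WG
#'
#' The mean of per-participant ratios (not the ratio of mean WG to mean
#' grain). Participants with no grain intake contribute 0 percent.
#'
#' @param exposures Output of [compute_wg_exposure()] for one group.
#' @param weights Sampling weights aligned with `exposures` rows (default
#'   equal).
#' @return The weighted mean percent (scalar).
#' @export
group_mean_pct_grain <- function(exposures, weights = NULL) {
  if (nrow(exposures) == 0) {
    validation_error("group is empty: mean percent of grain from WG undefined")
  }
  if (is.null(weights)) weights <- rep(1, nrow(exposures))
  stats::weighted.mean(exposures$pct_grain_from_wg, weights)
}
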