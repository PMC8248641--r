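#' @title Reading and writing the analysis input tables
#'
#' @description
#' Four comma-separated UTF-8 tables with header rows drive an analysis run:
#'
#' * `catalog.csv` — one row per food code with its CFG category, tier,
#'   BNS food group, whole-grain flag, serving size and nutrient densities
#'   per gram (`nut_<nutrient_id>` columns, plus `energy_kcal_per_g`).
#' * `recalls.csv` — long-format 24-hr recall records
#'   (`participant_id`, `food_code`, `grams`).
#' * `participants.csv` — demographics, covariate inputs, the main sampling
#'   weight and bootstrap replicate weights (`bsw_1..bsw_B`).
#' * `dv.csv` — daily values for the NRF 9.3 nutrients
#'   (`nutrient_id`, `role`, `dv`, `unit`).
#'
#' Units are declared once in the DV table and assumed consistent with the
#' catalog densities; there is no unit-conversion layer. Nutrient-density
#' columns missing from a catalog file are treated as zero with a warning,
#' matching common practice for unassayed nutrients in food-composition
#' databases.
#'
#' @name catalog_io
NULL

# condition helpers -----------------------------------------------------------

gs_stop <- function(subclass, msg) {
  stop(structure(
    class = c(subclass, "grainscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

schema_error     <- function(msg) gs_stop("grainscore_schema_error", msg)
validation_error <- function(msg) gs_stop("grainscore_validation_error", msg)
integrity_error  <- function(msg) gs_stop("grainscore_integrity_error", msg)

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) schema_error(sprintf("%s file not found: %s", what, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    schema_error(sprintf(
      "%s file %s is missing required column(s): %s",
      what, path, paste(miss, collapse = ", ")
    ))
  }
  df
}

# catalog ----------------------------------------------------------------------

#' Read and validate a food catalog
#'
#' @param path Path to a catalog CSV (see [catalog_io]).
#' @return A validated catalog data.frame with one row per food code, all 22
#'   `nut_*` density columns present (missing ones filled with 0, with a
#'   warning) and `energy_kcal_per_g`.
#' @export
read_catalog <- function(path) {
  required <- c(
    "food_code", "description", "cfg_group", "cfg_tier", "bns_group",
    "is_whole_grain", "grams_per_serving", "energy_kcal_per_g"
  )
  df <- read_csv_checked(path, required, "catalog")
  nut_cols <- nut_col(analysis_nutrients()$nutrient_id)
  absent <- setdiff(nut_cols, names(df))
  if (length(absent) > 0) {
    warning(sprintf(
      "catalog %s lacks %d nutrient density column(s) (%s); treating as 0",
      path, length(absent), paste(absent, collapse = ", ")
    ), call. = FALSE)
    for (col in absent) df[[col]] <- 0
  }
  df$is_whole_grain <- as.logical(df$is_whole_grain)
  validate_catalog(df)
}

#' Validate a catalog data.frame
#'
#' Checks the structural invariants of a food catalog: unique food codes,
#' known CFG categories, tiers 1-4 present exactly for CFG food categories,
#' the whole-grain flag equal to membership in the `whole_grains` category,
#' non-negative densities and positive serving sizes.
#'
#' @param catalog A catalog data.frame.
#' @return The catalog, invisibly unchanged, for chaining.
#' @export
validate_catalog <- function(catalog) {
  dup <- catalog$food_code[duplicated(catalog$food_code)]
  if (length(dup) > 0) {
    integrity_error(sprintf(
      "duplicate food_code(s) in catalog: %s", paste(unique(dup), collapse = ", ")
    ))
  }
  bad_group <- !(catalog$cfg_group %in% cfg_categories())
  if (any(bad_group)) {
    validation_error(sprintf(
      "unknown cfg_group in row(s) %s: %s",
      paste(which(bad_group), collapse = ", "),
      paste(unique(catalog$cfg_group[bad_group]), collapse = ", ")
    ))
  }
  is_cfg <- catalog$cfg_group %in% cfg_food_categories()
  tier <- catalog$cfg_tier
  bad_tier <- is_cfg & (is.na(tier) | !(tier %in% 1:4))
  if (any(bad_tier)) {
    validation_error(sprintf(
      "cfg_tier must be an integer 1-4 for CFG food categories; bad row(s): %s",
      paste(which(bad_tier), collapse = ", ")
    ))
  }
  stray_tier <- !is_cfg & !is.na(tier)
  if (any(stray_tier)) {
    validation_error(sprintf(
      "cfg_tier must be absent for discretionary/unclassified foods; bad row(s): %s",
      paste(which(stray_tier), collapse = ", ")
    ))
  }
  wg_mismatch <- xor(isTRUE_v(catalog$is_whole_grain), catalog$cfg_group == "whole_grains")
  if (any(wg_mismatch)) {
    integrity_error(sprintf(
      "is_whole_grain must hold exactly for cfg_group = whole_grains; bad food_code(s): %s",
      paste(catalog$food_code[wg_mismatch], collapse = ", ")
    ))
  }
  dens_cols <- c("energy_kcal_per_g", intersect(nut_col(analysis_nutrients()$nutrient_id), names(catalog)))
  for (col in dens_cols) {
    v <- catalog[[col]]
    if (any(!is.finite(v) | v < 0)) {
      validation_error(sprintf("negative or non-finite values in %s", col))
    }
  }
  gps <- catalog$grams_per_serving
  if (any(!is.na(gps) & gps <= 0)) {
    validation_error("grams_per_serving must be > 0 where present")
  }
  invisible(catalog)
}

isTRUE_v <- function(x) !is.na(x) & x

#' Write a catalog to CSV
#' @param catalog A validated catalog data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, na = "")
  invisible(path)
}

# recalls ----------------------------------------------------------------------

#' Read 24-hr recall records and resolve them against a catalog
#'
#' @param path Path to a recalls CSV with columns `participant_id`,
#'   `food_code`, `grams`.
#' @param catalog A validated catalog; every `food_code` must resolve.
#' @return A data.frame of recall records (possibly zero rows).
#' @export
read_recalls <- function(path, catalog) {
  df <- read_csv_checked(path, c("participant_id", "food_code", "grams"), "recalls")
  validate_recalls(df, catalog)
}

#' Validate recall records against a catalog
#' @inheritParams read_recalls
#' @param recalls A recalls data.frame.
#' @return The records, invisibly unchanged.
#' @export
validate_recalls <- function(recalls, catalog) {
  unknown <- setdiff(recalls$food_code, catalog$food_code)
  if (length(unknown) > 0) {
    integrity_error(sprintf(
      "recall records cite food code(s) absent from the catalog: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(recalls) > 0 && any(!is.finite(recalls$grams) | recalls$grams < 0)) {
    validation_error("recall grams must be finite and >= 0")
  }
  invisible(recalls)
}

#' Write recall records to CSV
#' @param recalls A recalls data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recalls <- function(recalls, path) {
  utils::write.csv(recalls, path, row.names = FALSE, na = "")
  invisible(path)
}

# participants -----------------------------------------------------------------

#' Read and validate the participant table
#'
#' Requires demographics, the main sampling weight and at least 8 bootstrap
#' replicate-weight columns `bsw_1..bsw_B`. Adults (age >= 19) must carry
#' `bmi`, children (1-18) `bmi_z_pctile`; exactly one of the two per person.
#'
#' @param path Path to a participants CSV.
#' @return A validated participants data.frame.
#' @export
read_participants <- function(path) {
  required <- c(
    "participant_id", "age_years", "gender", "household_size",
    "household_income", "bmi", "bmi_z_pctile", "supplement_use", "weight"
  )
  df <- read_csv_checked(path, required, "participants")
  df$supplement_use <- as.logical(df$supplement_use)
  validate_participants(df)
}

#' Validate a participants data.frame
#' @param participants A participants data.frame.
#' @return The table, invisibly unchanged.
#' @export
validate_participants <- function(participants) {
  p <- participants
  if (any(duplicated(p$participant_id))) {
    integrity_error("duplicate participant_id in participant table")
  }
  if (any(!is.finite(p$age_years) | p$age_years < 1)) {
    validation_error("age_years must be >= 1")
  }
  if (!all(p$gender %in% c("female", "male"))) {
    validation_error("gender must be 'female' or 'male'")
  }
  if (any(!is.finite(p$household_size) | p$household_size < 1)) {
    validation_error("household_size must be an integer >= 1")
  }
  if (any(!is.finite(p$household_income) | p$household_income < 0)) {
    validation_error("household_income must be >= 0")
  }
  if (any(!is.finite(p$weight) | p$weight <= 0)) {
    validation_error("sampling weight must be > 0")
  }
  adult <- p$age_years >= 19
  bad_adult <- adult & (is.na(p$bmi) | !is.na(p$bmi_z_pctile))
  bad_child <- !adult & (is.na(p$bmi_z_pctile) | !is.na(p$bmi))
  if (any(bad_adult | bad_child)) {
    validation_error(sprintf(
      "exactly one of bmi (adults) / bmi_z_pctile (children) required; bad participant(s): %s",
      paste(p$participant_id[bad_adult | bad_child], collapse = ", ")
    ))
  }
  if (any(!is.na(p$bmi_z_pctile) & (p$bmi_z_pctile < 0 | p$bmi_z_pctile > 100))) {
    validation_error("bmi_z_pctile must lie in [0, 100]")
  }
  bsw <- replicate_weight_matrix(p)
  if (ncol(bsw) < 8) {
    validation_error("at least 8 replicate-weight columns bsw_1..bsw_B are required")
  }
  if (any(!is.finite(bsw) | bsw < 0)) {
    validation_error("replicate weights must be finite and >= 0")
  }
  invisible(p)
}

#' Extract the replicate-weight matrix from a participant table
#' @param participants A participants data.frame with `bsw_*` columns.
#' @return A numeric matrix, one column per replicate, in replicate order.
#' @export
replicate_weight_matrix <- function(participants) {
  cols <- grep("^bsw_[0-9]+$", names(participants), value = TRUE)
  cols <- cols[order(as.integer(sub("^bsw_", "", cols)))]
  as.matrix(participants[, cols, drop = FALSE])
}

#' Write a participant table to CSV
#' @param participants A participants data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, na = "")
  invisible(path)
}

# daily values -----------------------------------------------------------------

#' Read a daily-value (DV) table for the NRF 9.3 score
#'
#' @param path Path to a DV CSV with columns `nutrient_id`,
#'   `role` (`encourage`/`limit`), `dv`, `unit`.
#' @return A validated DV data.frame: 9 encourage rows then 3 limit rows.
#' @export
read_dv <- function(path) {
  df <- read_csv_checked(path, c("nutrient_id", "role", "dv", "unit"), "DV")
  validate_dv(df)
}

#' Validate a DV table
#' @param dv A DV data.frame.
#' @return The table (encourage rows first), invisibly.
#' @export
validate_dv <- function(dv) {
  if (!all(dv$role %in% c("encourage", "limit"))) {
    validation_error("DV role must be 'encourage' or 'limit'")
  }
  enc <- dv[dv$role == "encourage", ]
  lim <- dv[dv$role == "limit", ]
  if (nrow(enc) != 9 || nrow(lim) != 3) {
    validation_error(sprintf(
      "NRF 9.3 requires exactly 9 encourage and 3 limit nutrients (got %d/%d)",
      nrow(enc), nrow(lim)
    ))
  }
  if (length(intersect(enc$nutrient_id, lim$nutrient_id)) > 0) {
    validation_error("encourage and limit nutrient sets must be disjoint")
  }
  if (any(!is.finite(dv$dv) | dv$dv <= 0)) {
    validation_error("all daily values must be > 0")
  }
  invisible(rbind(enc, lim))
}

#' Reference daily-value table for the modified NRF 9.3
#'
#' Health-Canada-style daily values for the 9 nutrients to encourage (fiber,
#' protein, vitamin D, vitamin C, iron, calcium, potassium, vitamin A,
#' magnesium) and the 3 nutrients to limit (total sugar, sodium, saturated
#' fat). These are editable reference values shipped for convenience, not a
#' normative source; substitute your own `dv.csv` for regulatory work.
#'
#' @return A DV data.frame (see [read_dv]).
#' @export
#' @examples
#' default_dv_table()
default_dv_table <- function() {
  data.frame(
    nutrient_id = c(
      "fiber", "protein", "vitamin_d", "vitamin_c", "iron",
      "calcium", "potassium", "vitamin_a", "magnesium",
      "total_sugar", "sodium", "saturated_fat"
    ),
    role = c(rep("encourage", 9), rep("limit", 3)),
    dv = c(28, 50, 20, 90, 18, 1300, 4700, 900, 420, 100, 2300, 20),
    unit = c("g", "g", "ug", "mg", "mg", "mg", "mg", "ug_rae", "mg", "g", "mg", "g"),
    stringsAsFactors = FALSE
  )
}

#' Write a DV table to CSV
#' @param dv A DV data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dv <- function(dv, path) {
  utils::write.csv(dv, path, row.names = FALSE, na = "")
  invisible(path)
}
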