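#' @title Modified NRF 9.3 diet-quality score
#'
#' @description
#' The Nutrient Rich Food Index 9.3 adapted to the total diet: each of 9
#' nutrients to encourage contributes its percent of daily value per 2000
#' kcal of the diet, capped (default 100 percent) so a single nutrient
#' cannot dominate; each of 3 nutrients to limit subtracts its uncapped
#' percent of daily value per 2000 kcal. The score is the encourage subscore
#' minus the limit subscore, with a theoretical maximum of 900 when every
#' encourage nutrient meets its daily value and no limit nutrient is
#' consumed. Order of operations: energy-adjust, then percent of DV, then
#' cap — the only order under which the per-2000-kcal phrase and the cap are
#' simultaneously well defined per participant.
#'
#' @name nrf_score
NULL

#' Rescale a nutrient amount to an energy basis
#'
#' @param amount Nutrient amount(s) consumed.
#' @param energy Total energy (kcal) of the same diet; must be > 0.
#' @param basis Energy basis in kcal (default 2000).
#' @return `amount * basis / energy`.
#' @export
#' @examples
#' per2000kcal(10, 1000) # 20
per2000kcal <- function(amount, energy, basis = 2000) {
  if (any(!is.finite(energy) | energy <= 0)) {
    gs_stop("grainscore_scoring_error", "energy must be > 0 to energy-adjust intake")
  }
  amount * basis / energy
}

#' Compute the modified NRF 9.3 score
#'
#' @param profiles Intake profiles from [build_intake_profiles()] (or any
#'   data.frame with `participant_id`, `energy_kcal` and the `nut_*` columns
#'   the DV table names).
#' @param dv A DV table ([default_dv_table()] shape): 9 encourage + 3 limit
#'   nutrients with daily values.
#' @param cap Cap on each encourage contribution, percent (default 100).
#' @param basis Energy basis, kcal (default 2000).
#' @param detail If `TRUE`, attach the per-nutrient (capped encourage /
#'   uncapped limit) percent-DV matrix as attribute `"per_nutrient"`.
#' @return A data.frame `participant_id`, `encourage_subscore`,
#'   `limit_subscore`, `score`. Participants with zero energy are scored NA
#'   with a warning (they cannot be energy-adjusted).
#' @export
#' @examples
#' prof <- data.frame(participant_id = "a", energy_kcal = 2000,
#'                    nut_fiber = 28, nut_protein = 50, nut_vitamin_d = 20,
#'                    nut_vitamin_c = 90, nut_iron = 18, nut_calcium = 1300,
#'                    nut_potassium = 4700, nut_vitamin_a = 900,
#'                    nut_magnesium = 420, nut_total_sugar = 0,
#'                    nut_sodium = 0, nut_saturated_fat = 0)
#' nrf93(prof, default_dv_table())$score # 900
nrf93 <- function(profiles, dv = default_dv_table(), cap = 100, basis = 2000,
                  detail = FALSE) {
  dv <- validate_dv(dv)
  need <- nut_col(dv$nutrient_id)
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    gs_stop("grainscore_configuration_error", sprintf(
      "profiles lack nutrient column(s) required by the DV table: %s",
      paste(miss, collapse = ", ")
    ))
  }
  energy <- profiles$energy_kcal
  scorable <- is.finite(energy) & energy > 0
  if (any(!scorable)) {
    warning(sprintf(
      "%d participant(s) with zero energy cannot be scored; NRF set to NA",
      sum(!scorable)
    ), call. = FALSE)
  }
  enc <- dv[dv$role == "encourage", ]
  lim <- dv[dv$role == "limit", ]

  n <- nrow(profiles)
  enc_mat <- matrix(NA_real_, n, nrow(enc), dimnames = list(NULL, enc$nutrient_id))
  lim_mat <- matrix(NA_real_, n, nrow(lim), dimnames = list(NULL, lim$nutrient_id))
  for (j in seq_len(nrow(enc))) {
    amt <- profiles[[nut_col(enc$nutrient_id[j])]]
    enc_mat[scorable, j] <- pmin(
      100 * (amt[scorable] * basis / energy[scorable]) / enc$dv[j], cap
    )
  }
  for (j in seq_len(nrow(lim))) {
    amt <- profiles[[nut_col(lim$nutrient_id[j])]]
    lim_mat[scorable, j] <- 100 * (amt[scorable] * basis / energy[scorable]) / lim$dv[j]
  }

  out <- data.frame(
    participant_id = profiles$participant_id,
    encourage_subscore = rowSums(enc_mat),
    limit_subscore = rowSums(lim_mat),
    stringsAsFactors = FALSE
  )
  out$score <- out$encourage_subscore - out$limit_subscore
  if (detail) {
    attr(out, "per_nutrient") <- cbind(enc_mat, lim_mat)
  }
  out
}
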