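#' @title Published CCHS 2015 reference estimates
#'
#' @description
#' Small reference tables of published survey-weighted, covariate-adjusted
#' estimates from the CCHS 2015 - Nutrition whole-grain analysis: the
#' top-10 BNS food sources of whole grain per age stratum and WG intake
#' group, and adjusted group means for selected outcomes (folic acid,
#' discretionary foods). They serve as fixed inputs for consistency
#' arithmetic — column sums, group contrasts, coverage ratios — against the
#' same quantities this package computes on its own data.
#'
#' @name reference_tables
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "grainscore", mustWork = TRUE)
}

#' Published top-10 whole-grain sources by BNS group
#' @return Data.frame: `stratum`, `wg_group`, `rank`, `bns_group`,
#'   `mean_g` (adjusted mean grams/day), `se`.
#' @export
cchs_top_wg_sources <- function() {
  utils::read.csv(ref_path("cchs2015_top_wg_sources.csv"),
                  stringsAsFactors = FALSE)
}

#' Published adjusted group means for selected outcomes
#' @return Data.frame: `outcome`, `stratum`, `wg_group`, `lsmean`, `se`,
#'   `unit`.
#' @export
cchs_adjusted_means <- function() {
  utils::read.csv(ref_path("cchs2015_adjusted_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Top-10 subtotal of a source table
#'
#' Sums the listed per-source mean grams for one (stratum, WG group) table —
#' the "total intake from top 10 sources" row of a top-sources table.
#'
#' @param sources A top-sources data.frame (published
#'   [cchs_top_wg_sources()] or the output of [rank_wg_sources()], using
#'   its `mean_grams` column).
#' @param stratum `"child"` or `"adult"`.
#' @param wg_group One of `"low_wg"`, `"mid_wg"`, `"high_wg"`.
#' @return The subtotal in grams/day.
#' @export
top_source_total <- function(sources, stratum, wg_group) {
  rows <- sources[sources$stratum == stratum & sources$wg_group == wg_group, ]
  if (nrow(rows) == 0) validation_error("no rows for that stratum/group")
  col <- if ("mean_g" %in% names(rows)) "mean_g" else "mean_grams"
  sum(rows[[col]])
}

#' Percent difference in top-10 WG intake between two groups
#'
#' 100 x (total(group_hi) - total(group_lo)) / total(group_lo).
#'
#' @inheritParams top_source_total
#' @param group_hi,group_lo WG groups to compare.
#' @return Percent higher intake in `group_hi` relative to `group_lo`.
#' @export
top_source_pct_higher <- function(sources, stratum, group_hi = "high_wg",
                                  group_lo = "low_wg") {
  hi <- top_source_total(sources, stratum, group_hi)
  lo <- top_source_total(sources, stratum, group_lo)
  100 * (hi - lo) / lo
}

#' Percent reduction in an adjusted mean from no-WG to high-WG
#'
#' @param means An adjusted-means data.frame ([cchs_adjusted_means()] shape).
#' @param outcome Outcome id (e.g. `"folic_acid"`).
#' @param stratum `"child"` or `"adult"`.
#' @return 100 x (mean(no_wg) - mean(high_wg)) / mean(no_wg).
#' @export
pct_reduction_no_to_high <- function(means, outcome, stratum) {
  rows <- means[means$outcome == outcome & means$stratum == stratum, ]
  no <- rows$lsmean[rows$wg_group == "no_wg"]
  hi <- rows$lsmean[rows$wg_group == "high_wg"]
  if (length(no) != 1 || length(hi) != 1) {
    validation_error("need exactly one no_wg and one high_wg row")
  }
  100 * (no - hi) / no
}
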