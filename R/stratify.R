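#' @title Whole-grain intake group assignment
#'
#' @description
#' Participants reporting no whole-grain food are the no-WG group; consumers
#' are split into low/mid/high at the unweighted empirical 1/3 and 2/3
#' quantiles of WG grams within age stratum (children 1-18, adults >= 19).
#' Type-1 (inverse-CDF) quantiles are used and boundary-valued participants
#' go to the lower group, so assignment is deterministic and independent of
#' input order.
#'
#' @name wg_stratification
NULL

#' WG group levels in exposure order
#' @return `c("no_wg", "low_wg", "mid_wg", "high_wg")`.
#' @export
wg_group_levels <- function() c("no_wg", "low_wg", "mid_wg", "high_wg")

# type-1 empirical quantile: smallest order statistic with cdf >= p
quantile_type1 <- function(x, p) {
  sx <- sort(x)
  sx[pmax(ceiling(p * length(sx)), 1)]
}

#' Assign participants to the four WG intake groups
#'
#' @param exposures Output of [compute_wg_exposure()].
#' @param participants Participant table supplying `age_years` (matched by
#'   `participant_id`; every exposure row needs one).
#' @return A data.frame `participant_id`, `stratum` (`child`/`adult`),
#'   `wg_group` (ordered factor over [wg_group_levels()]).
#' @export
assign_wg_groups <- function(exposures, participants) {
  m <- match(exposures$participant_id, participants$participant_id)
  if (any(is.na(m))) {
    integrity_error("every exposure row needs a participant with an age")
  }
  age <- participants$age_years[m]
  if (any(!is.finite(age) | age < 1)) validation_error("ages must be >= 1")
  stratum <- ifelse(age >= 19, "adult", "child")

  group <- rep("no_wg", nrow(exposures))
  for (s in unique(stratum)) {
    in_s <- stratum == s
    cons <- in_s & exposures$wg_grams > 0
    if (!any(in_s)) next
    if (sum(cons) < 3) {
      gs_stop("grainscore_stratification_error", sprintf(
        "stratum '%s' has %d WG consumer(s); at least 3 are needed for tertiles",
        s, sum(cons)
      ))
    }
    g <- exposures$wg_grams[cons]
    q1 <- quantile_type1(g, 1 / 3)
    q2 <- quantile_type1(g, 2 / 3)
    if (q1 == q2 && length(unique(g)) == 1) {
      warning(sprintf(
        "all WG consumers in stratum '%s' report identical grams; all assigned low_wg",
        s
      ), call. = FALSE)
    }
    group[cons] <- ifelse(g <= q1, "low_wg", ifelse(g <= q2, "mid_wg", "high_wg"))
  }
  data.frame(
    participant_id = exposures$participant_id,
    stratum = stratum,
    wg_group = factor(group, levels = wg_group_levels(), ordered = TRUE),
    stringsAsFactors = FALSE
  )
}
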