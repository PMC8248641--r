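#' @title Top food sources of whole grain by BNS group
#'
#' @description
#' For each age stratum and WG intake group, ranks BNS food groups by the
#' covariate-adjusted mean grams of whole-grain food consumed from that
#' source (participants who did not eat a source count 0 grams), and
#' reports the top-10 subtotal and its share of total WG-food intake.
#'
#' @name top_sources
NULL

#' Rank BNS food groups as sources of whole grain
#'
#' @param recalls Recall records.
#' @param catalog Validated catalog (BNS labels and WG flags come from it).
#' @param assignments Output of [assign_wg_groups()].
#' @param participants Participant table (weights and replicate weights).
#' @param covariates Output of [build_covariates()]; when supplied, means
#'   are least-squares means adjusted for [covariate_columns()] (as in the
#'   published tables); when `NULL` with `adjusted = FALSE`, raw weighted
#'   means are reported.
#' @param adjusted Use adjusted LS-means (default) or raw weighted means.
#' @param top_n Rows per table (default 10; fewer if fewer sources).
#' @return A data.frame with one row per (stratum, wg_group, bns_group):
#'   `rank`, `mean_grams`, `se`, plus columns `top10_total_grams` and
#'   `pct_of_total_wg` repeated per table. Only consumer groups
#'   (low/mid/high) are tabulated. Ties in adjusted means break by
#'   lexicographic BNS label, so output is independent of catalog row order.
#' @export
rank_wg_sources <- function(recalls, catalog, assignments, participants,
                            covariates = NULL, adjusted = TRUE, top_n = 10) {
  validate_recalls(recalls, catalog)
  if (adjusted && is.null(covariates)) {
    gs_stop("grainscore_configuration_error",
            "adjusted ranking needs a covariate set (or set adjusted = FALSE)")
  }
  ri <- match(recalls$food_code, catalog$food_code)
  wg_rows <- catalog$is_whole_grain[ri] & recalls$grams > 0
  wgr <- recalls[wg_rows, , drop = FALSE]
  wgr$bns_group <- catalog$bns_group[match(wgr$food_code, catalog$food_code)]

  out <- list()
  for (s in c("child", "adult")) {
    ids <- assignments$participant_id[assignments$stratum == s]
    if (length(ids) == 0) next
    if (!is.null(covariates)) {
      ids <- intersect(ids, covariates$participant_id)
    }
    grp <- assignments$wg_group[match(ids, assignments$participant_id)]
    pm <- match(ids, participants$participant_id)
    w <- participants$weight[pm]
    rw <- replicate_weight_matrix(participants)[pm, , drop = FALSE]
    cov_s <- if (!is.null(covariates)) {
      covariates[match(ids, covariates$participant_id), covariate_columns(),
                 drop = FALSE]
    } else NULL

    in_s <- wgr[wgr$participant_id %in% ids, , drop = FALSE]
    bns <- sort(unique(in_s$bns_group))
    pid <- factor(in_s$participant_id, levels = ids)
    # per-participant WG grams by source (and in total)
    gmat <- vapply(bns, function(b) {
      as.numeric(tapply(in_s$grams * (in_s$bns_group == b), pid, sum, default = 0))
    }, numeric(length(ids)))
    total <- as.numeric(tapply(in_s$grams, pid, sum, default = 0))

    est_by_group <- function(y) {
      if (adjusted) {
        fit <- weighted_lsmeans(y, grp, covariates = cov_s, weights = w,
                                repweights = rw)
        list(est = fit$estimate, se = fit$se)
      } else {
        est <- vapply(levels(grp), function(g)
          stats::weighted.mean(y[grp == g], w[grp == g]), numeric(1))
        reps <- t(vapply(seq_len(ncol(rw)), function(b)
          vapply(levels(grp), function(g)
            stats::weighted.mean(y[grp == g], rw[grp == g, b]), numeric(1)),
          numeric(nlevels(grp))))
        list(est = est, se = stats::setNames(replicate_se(est, reps), levels(grp)))
      }
    }
    fits <- lapply(seq_along(bns), function(j) est_by_group(gmat[, j]))
    fit_total <- est_by_group(total)

    for (g in c("low_wg", "mid_wg", "high_wg")) {
      means <- vapply(fits, function(f) f$est[[g]], numeric(1))
      ses <- vapply(fits, function(f) f$se[[g]], numeric(1))
      ord <- order(-means, bns)
      k <- min(top_n, length(bns))
      top <- ord[seq_len(k)]
      subtotal <- sum(means[top])
      tot <- fit_total$est[[g]]
      out[[paste(s, g)]] <- data.frame(
        stratum = s, wg_group = g, rank = seq_len(k),
        bns_group = bns[top], mean_grams = means[top], se = ses[top],
        top10_total_grams = subtotal,
        pct_of_total_wg = if (tot > 0) 100 * subtotal / tot else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
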