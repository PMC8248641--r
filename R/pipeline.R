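#' @title End-to-end analysis pipeline
#'
#' @description
#' Orchestrates a full run: load (or simulate) inputs, aggregate intakes,
#' stratify by WG intake, score diet quality, estimate adjusted group means
#' and trends for nutrients and food groups, test the NRF score, and rank
#' top WG sources. Every stage logs a row count; stage failures are
#' recorded with their stage name.
#'
#' @name cli_runner
NULL

#' Build a run configuration
#'
#' Exactly one input source: either the four CSV paths, or a simulation
#' config.
#'
#' @param catalog_path,recalls_path,participants_path Paths to input CSVs.
#' @param dv_path Optional DV CSV (default [default_dv_table()]).
#' @param sim A [sim_config()] to generate inputs instead of reading them.
#' @param alpha Family-wise alpha (default 0.05).
#' @param m_nut Nutrient-family test count for Bonferroni (default 22).
#' @param m_fg Food-group-family test count (default 24).
#' @param nrf_cap,energy_basis NRF 9.3 cap (percent) and energy basis (kcal).
#' @param n_energy_levels Energy-category count per stratum.
#' @return A validated `run_config` list.
#' @export
run_config <- function(catalog_path = NULL, recalls_path = NULL,
                       participants_path = NULL, dv_path = NULL, sim = NULL,
                       alpha = 0.05, m_nut = 22, m_fg = 24,
                       nrf_cap = 100, energy_basis = 2000,
                       n_energy_levels = 5) {
  paths <- c(catalog_path, recalls_path, participants_path)
  from_files <- length(paths) == 3
  if (identical(from_files, !is.null(sim)) ) {
    validation_error("supply either the three input CSV paths or a sim config, not both")
  }
  if (m_nut < 1 || m_fg < 1) validation_error("m_nut and m_fg must be >= 1")
  bonferroni_threshold(alpha, 1) # validates alpha
  structure(list(
    catalog_path = catalog_path, recalls_path = recalls_path,
    participants_path = participants_path, dv_path = dv_path, sim = sim,
    alpha = alpha, m_nut = m_nut, m_fg = m_fg,
    nrf_cap = nrf_cap, energy_basis = energy_basis,
    n_energy_levels = n_energy_levels
  ), class = "run_config")
}

weighted_group_means <- function(y, grp, w, rw) {
  lev <- levels(grp)
  est <- vapply(lev, function(g) stats::weighted.mean(y[grp == g], w[grp == g]),
                numeric(1))
  reps <- t(vapply(seq_len(ncol(rw)), function(b)
    vapply(lev, function(g) {
      wb <- rw[grp == g, b]
      if (sum(wb) == 0) est[[g]] else stats::weighted.mean(y[grp == g], wb)
    }, numeric(1)), numeric(length(lev))))
  data.frame(wg_group = lev, mean = est, se = replicate_se(est, reps),
             n = as.integer(table(grp)[lev]), row.names = NULL)
}

outcome_table <- function(outcomes, grp, cov, w, rw, alpha, m) {
  thresh <- bonferroni_threshold(alpha, m)
  res <- lapply(names(outcomes), function(nm) {
    y <- outcomes[[nm]]
    fit <- weighted_lsmeans(y, grp, covariates = cov, weights = w, repweights = rw)
    tr <- linear_trend_test(y, grp, covariates = cov, weights = w, repweights = rw)
    row <- data.frame(outcome = nm, stringsAsFactors = FALSE)
    for (g in fit$groups) {
      row[[paste0("lsmean_", g)]] <- fit$estimate[[g]]
      row[[paste0("se_", g)]] <- fit$se[[g]]
    }
    row$trend_p <- tr$p.value
    row$significant <- tr$p.value <= thresh
    row
  })
  do.call(rbind, res)
}

#' Run the whole pipeline
#'
#' @param config A [run_config()].
#' @return A report bundle (list): WG group counts, descriptive exposure
#'   table, adjusted nutrient and food-group tables with trend p-values and
#'   Bonferroni flags, NRF 9.3 summaries (weighted mean/median/quartiles and
#'   5th/95th percentiles per group, boxplot-ready), NRF LS-means, trend and
#'   Tukey-Kramer contrasts, top WG sources, a stage log, and any stage
#'   errors (each named by stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  errors <- list()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$sim)) {
    catalog <- generate_catalog(config$sim)
    sv <- generate_survey(config$sim, catalog)
    participants <- sv$participants
    recalls <- sv$recalls
    seed <- config$sim$seed
  } else {
    catalog <- read_catalog(config$catalog_path)
    participants <- read_participants(config$participants_path)
    recalls <- read_recalls(config$recalls_path, catalog)
    seed <- NA_integer_
  }
  dv <- if (is.null(config$dv_path)) default_dv_table() else read_dv(config$dv_path)
  note("inputs: %d foods, %d participants, %d recall records",
       nrow(catalog), nrow(participants), nrow(recalls))

  ids <- participants$participant_id
  profiles <- build_intake_profiles(recalls, catalog, participant_ids = ids)
  exposures <- compute_wg_exposure(recalls, catalog, participant_ids = ids)
  note("intake profiles and WG exposure built for %d participants", nrow(profiles))

  assignments <- tryCatch(
    assign_wg_groups(exposures, participants),
    grainscore_stratification_error = function(e) {
      errors$stratification <<- conditionMessage(e)
      NULL
    }
  )

  bundle <- list(
    seed = seed, config = config, log = log, errors = errors,
    profiles = profiles, exposures = exposures
  )
  if (is.null(assignments)) {
    bundle$log <- c(log, "stratification failed; group analyses skipped")
    return(bundle)
  }
  counts <- table(assignments$stratum, assignments$wg_group)
  note("WG groups assigned (%s)",
       paste(capture_counts(counts), collapse = "; "))

  covariates <- build_covariates(participants, profiles,
                                 n_energy_levels = config$n_energy_levels)
  nrf <- nrf93(profiles, dv, cap = config$nrf_cap, basis = config$energy_basis)

  nut_ids <- analysis_nutrients()$nutrient_id
  fg_cols <- c(food_group_cells(), "fg_total_t13", "fg_total_t4", "fg_total_non_cfg")
  rw_all <- replicate_weight_matrix(participants)

  per_stratum <- list()
  for (s in intersect(c("child", "adult"), unique(assignments$stratum))) {
    sid <- intersect(assignments$participant_id[assignments$stratum == s],
                     covariates$participant_id)
    grp <- droplevels(assignments$wg_group[match(sid, assignments$participant_id)])
    pm <- match(sid, participants$participant_id)
    w <- participants$weight[pm]
    rw <- rw_all[pm, , drop = FALSE]
    cov_s <- covariates[match(sid, covariates$participant_id),
                        covariate_columns(), drop = FALSE]
    prof_s <- profiles[match(sid, profiles$participant_id), ]
    expo_s <- exposures[match(sid, exposures$participant_id), ]
    nrf_s <- nrf$score[match(sid, nrf$participant_id)]

    res <- list()
    # descriptive exposure table (unadjusted, weighted)
    res$exposure <- rbind(
      cbind(measure = "wg_grams",
            weighted_group_means(expo_s$wg_grams, grp, w, rw)),
      cbind(measure = "wg_servings",
            weighted_group_means(ifelse(is.na(expo_s$wg_servings), 0,
                                        expo_s$wg_servings), grp, w, rw)),
      cbind(measure = "pct_grain_from_wg",
            weighted_group_means(expo_s$pct_grain_from_wg, grp, w, rw)),
      cbind(measure = "energy_kcal",
            weighted_group_means(prof_s$energy_kcal, grp, w, rw))
    )
    res$gender_chi2 <- weighted_chi2(cov_s$gender, grp, w, rw)$p.value

    nut_out <- stats::setNames(
      lapply(nut_ids, function(nm) prof_s[[nut_col(nm)]]), nut_ids)
    res$nutrients <- outcome_table(nut_out, grp, cov_s, w, rw,
                                   config$alpha, config$m_nut)
    fg_out <- stats::setNames(lapply(fg_cols, function(cc) prof_s[[cc]]), fg_cols)
    res$food_groups <- outcome_table(fg_out, grp, cov_s, w, rw,
                                     config$alpha, config$m_fg)

    # NRF 9.3: single outcome, tested at alpha (not Bonferroni-corrected)
    ok <- !is.na(nrf_s)
    nrf_fit <- weighted_lsmeans(nrf_s[ok], grp[ok], covariates = cov_s[ok, ],
                                weights = w[ok], repweights = rw[ok, , drop = FALSE])
    nrf_tr <- linear_trend_test(nrf_s[ok], grp[ok], covariates = cov_s[ok, ],
                                weights = w[ok], repweights = rw[ok, , drop = FALSE])
    res$nrf <- list(
      lsmeans = data.frame(wg_group = nrf_fit$groups, lsmean = nrf_fit$estimate,
                           se = nrf_fit$se, n = nrf_fit$n_per_group,
                           row.names = NULL),
      trend_p = nrf_tr$p.value,
      significant = nrf_tr$p.value <= config$alpha,
      posthoc = tukey_kramer(nrf_fit),
      summary = do.call(rbind, lapply(levels(grp), function(g) {
        y <- nrf_s[ok & grp == g]; wy <- w[ok & grp == g]
        qs <- weighted_quantile(y, wy, c(.05, .25, .5, .75, .95))
        data.frame(wg_group = g, mean = stats::weighted.mean(y, wy),
                   p5 = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4],
                   p95 = qs[5], row.names = NULL)
      }))
    )
    per_stratum[[s]] <- res
  }

  top <- rank_wg_sources(recalls, catalog, assignments, participants,
                         covariates = covariates, adjusted = TRUE)
  note("top WG sources ranked (%d table rows)", nrow(top))

  bundle$assignments <- assignments
  bundle$group_counts <- counts
  bundle$covariates <- covariates
  bundle$nrf <- nrf
  bundle$per_stratum <- per_stratum
  bundle$top_sources <- top
  bundle$log <- log
  bundle$errors <- errors
  bundle
}

capture_counts <- function(counts) {
  vapply(rownames(counts), function(s)
    paste0(s, ": ", paste(counts[s, ], collapse = "/")), character(1))
}

#' Write a report bundle to CSV files
#'
#' Emits per-stratum nutrient, food-group, exposure and NRF tables, the top
#' WG sources table, group counts and a plain-text run log into `dir`.
#'
#' @param bundle Output of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  for (s in names(bundle$per_stratum)) {
    res <- bundle$per_stratum[[s]]
    emit(res$exposure, paste0("exposure_", s))
    emit(res$nutrients, paste0("nutrients_", s))
    emit(res$food_groups, paste0("food_groups_", s))
    emit(res$nrf$lsmeans, paste0("nrf_lsmeans_", s))
    emit(res$nrf$summary, paste0("nrf_summary_", s))
    emit(res$nrf$posthoc, paste0("nrf_posthoc_", s))
  }
  if (!is.null(bundle$top_sources)) emit(bundle$top_sources, "top_sources")
  if (!is.null(bundle$group_counts)) {
    emit(as.data.frame(bundle$group_counts), "group_counts")
  }
  writeLines(c(
    sprintf("seed: %s", bundle$seed),
    sprintf("R version: %s", getRversion()),
    sprintf("grainscore version: %s",
            as.character(utils::packageVersion("grainscore"))),
    if (length(bundle$errors) > 0)
      paste0("error[", names(bundle$errors), "]: ", unlist(bundle$errors)),
    bundle$log
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}
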