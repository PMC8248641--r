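#' @title Synthetic survey generator with known ground truth
#'
#' @description
#' Generates a food catalog, a participant table with calibrated bootstrap
#' replicate weights, and long-format 24-hr recall records whose statistical
#' structure is known exactly, so every downstream stage of the pipeline can
#' be tested without restricted survey microdata.
#'
#' Ground-truth nutrient gradients are injected through composite "mixed
#' dish" catalog entries: a pool of baseline dishes with randomized density
#' patterns supplies the baseline nutrient intake (and its between-person
#' noise), and two gradient dishes whose densities encode the configured
#' per-WG-gram slopes supply the association between whole-grain grams and
#' per-2000-kcal nutrient intake. Grain-category foods carry mass (for
#' exposure and food-group tables) but zero energy and nutrient density, so a
#' configured slope of zero is exactly zero in the generating process and a
#' nonzero slope is exact, not approximate. All dish and category-food grams
#' scale with the participant's energy so that recall-derived energy equals
#' the drawn energy exactly.
#'
#' @name synthetic_data
NULL

# descriptions identifying the generator's special dishes
WG_GRADIENT_POS <- "composite dish (whole-grain fortification gradient)"
WG_GRADIENT_NEG <- "composite dish (refined-grain fortification gradient)"

wg_bns_labels <- function() {
  c(
    "whole grain, oat, and high fibre breakfast cereal",
    "whole grain and whole wheat bread",
    "rice",
    "rolls, bagels, pita bread, croutons, dumplings, matzo, tortilla",
    "other breakfast cereal",
    "salty and high-fat snacks (including tortilla chips)",
    "cereal grains and flours",
    "pasta"
  )
}

default_wg_source_shares <- function() {
  stats::setNames(
    c(0.40, 0.30, 0.10, 0.08, 0.04, 0.03, 0.03, 0.02),
    wg_bns_labels()
  )
}

#' Typical per-2000-kcal baseline intakes used by the generator
#'
#' Baseline daily intakes (per 2000 kcal) for the 22 analysis nutrients,
#' chosen to resemble national dietary-surveillance magnitudes.
#'
#' @return Named numeric vector over the analysis nutrient ids.
#' @export
default_baseline_per2000 <- function() {
  c(
    carbohydrate = 230, fiber = 15, total_sugar = 100, total_fat = 67,
    saturated_fat = 22, protein = 72, vitamin_b12 = 4, vitamin_b6 = 1.6,
    vitamin_c = 110, folate = 430, folic_acid = 120, vitamin_d = 5.2,
    niacin = 35, vitamin_a = 620, riboflavin = 1.85, thiamin = 1.6,
    sodium = 2650, potassium = 2500, zinc = 9.5, calcium = 880,
    iron = 12, magnesium = 280
  )
}

#' Default ground-truth nutrient gradients (per WG gram, per 2000 kcal)
#'
#' Additive shifts in per-2000-kcal daily intake per gram of whole-grain food,
#' sized to reproduce the gradients national surveillance reports across WG
#' intake groups (positive for fiber and key minerals, negative for folic
#' acid, which tracks fortified refined grains, and for fats).
#'
#' @return Named numeric vector (nutrient id -> slope).
#' @export
default_nutrient_effect <- function() {
  c(
    fiber = 0.041, magnesium = 0.41, iron = 0.0068, potassium = 0.94,
    calcium = 0.24, thiamin = 0.001,
    folic_acid = -0.20, total_fat = -0.028, saturated_fat = -0.013
  )
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: roughly half of
#' each age stratum consumes no whole grain, whole-grain grams among
#' consumers are heavy-tailed log-normal, energy is positively associated
#' with WG grams for children and not for adults, and sampling weights carry
#' calibrated bootstrap replicates.
#'
#' @param seed Integer seed (|seed| <= 2^30); all generator randomness
#'   derives from it.
#' @param n_children,n_adults Participants per age stratum.
#' @param n_foods_per_category Foods generated in each of the 12 categories.
#'   Must be >= 3 when `nutrient_effect` is non-empty (the unclassified
#'   category then needs two gradient dishes plus at least one baseline dish).
#' @param prob_wg_consumer Probability a participant consumes any whole
#'   grain, named vector `c(child=, adult=)`.
#' @param wg_meanlog,wg_sdlog Log-normal parameters of WG grams among
#'   consumers, per stratum.
#' @param wg_cap Upper truncation (g/d) of WG grams; also the pivot of the
#'   negative-gradient dish.
#' @param nutrient_effect Named vector of ground-truth slopes
#'   (per-2000-kcal intake shift per WG gram); empty vector for no gradients.
#' @param baseline_per2000 Named vector of baseline per-2000-kcal intakes.
#' @param energy_mean,energy_sd Normal energy (kcal) parameters per stratum.
#' @param energy_min Lower energy truncation (kcal).
#' @param energy_per_wg_gram Added kcal per WG gram, per stratum (positive
#'   for children, 0 for adults by default).
#' @param wg_source_shares Expected share of WG grams by BNS source label;
#'   normalized to sum to 1.
#' @param dish_noise_sdlog Log-normal sd of baseline-dish gram noise.
#' @param prob_refined_consumer Probability of any refined-grain intake.
#' @param refined_meanlog,refined_sdlog Log-normal refined-grain grams.
#' @param n_replicates Number of bootstrap replicate weights B (>= 8).
#' @param n_psu First-stage units per stratum for the rescaled bootstrap.
#' @param weight_cv Coefficient of variation of sampling weights.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_children = 2000,
                       n_adults = 2000,
                       n_foods_per_category = 8,
                       prob_wg_consumer = c(child = 0.50, adult = 0.46),
                       wg_meanlog = c(child = log(45), adult = log(65)),
                       wg_sdlog = c(child = 1.0, adult = 1.0),
                       wg_cap = 1500,
                       nutrient_effect = default_nutrient_effect(),
                       baseline_per2000 = default_baseline_per2000(),
                       energy_mean = c(child = 1800, adult = 1900),
                       energy_sd = c(child = 550, adult = 650),
                       energy_min = 200,
                       energy_per_wg_gram = c(child = 1.2, adult = 0),
                       wg_source_shares = default_wg_source_shares(),
                       dish_noise_sdlog = 0.4,
                       prob_refined_consumer = 0.9,
                       refined_meanlog = log(120),
                       refined_sdlog = 0.7,
                       n_replicates = 100,
                       n_psu = 50,
                       weight_cv = 0.5) {
  if (is.null(nutrient_effect)) nutrient_effect <- stats::setNames(numeric(0), character(0))
  cfg <- list(
    seed = seed, n_children = n_children, n_adults = n_adults,
    n_foods_per_category = n_foods_per_category,
    prob_wg_consumer = prob_wg_consumer,
    wg_meanlog = wg_meanlog, wg_sdlog = wg_sdlog, wg_cap = wg_cap,
    nutrient_effect = nutrient_effect,
    baseline_per2000 = baseline_per2000,
    energy_mean = energy_mean, energy_sd = energy_sd,
    energy_min = energy_min, energy_per_wg_gram = energy_per_wg_gram,
    wg_source_shares = wg_source_shares / sum(wg_source_shares),
    dish_noise_sdlog = dish_noise_sdlog,
    prob_refined_consumer = prob_refined_consumer,
    refined_meanlog = refined_meanlog, refined_sdlog = refined_sdlog,
    n_replicates = n_replicates, n_psu = n_psu, weight_cv = weight_cv
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(cfg$seed) || abs(cfg$seed) > 2^30) {
    validation_error("seed must be an integer with |seed| <= 2^30")
  }
  counts <- c(cfg$n_children, cfg$n_adults, cfg$n_foods_per_category, cfg$n_psu)
  if (any(counts < 1)) validation_error("all counts must be >= 1")
  if (cfg$n_replicates < 8) validation_error("n_replicates must be >= 8")
  if (any(cfg$prob_wg_consumer < 0 | cfg$prob_wg_consumer > 1) ||
      cfg$prob_refined_consumer < 0 || cfg$prob_refined_consumer > 1) {
    validation_error("probabilities must lie in [0, 1]")
  }
  for (nm in c("prob_wg_consumer", "wg_meanlog", "wg_sdlog", "energy_mean",
               "energy_sd", "energy_per_wg_gram")) {
    if (!all(c("child", "adult") %in% names(cfg[[nm]]))) {
      validation_error(sprintf("%s must be named c(child=, adult=)", nm))
    }
  }
  nut_ids <- analysis_nutrients()$nutrient_id
  if (length(cfg$nutrient_effect) > 0) {
    if (!all(names(cfg$nutrient_effect) %in% nut_ids)) {
      validation_error("nutrient_effect names must be analysis nutrient ids")
    }
    if (cfg$n_foods_per_category < 3) {
      validation_error(
        "n_foods_per_category must be >= 3 when nutrient_effect is non-empty"
      )
    }
  }
  if (!all(names(cfg$baseline_per2000) %in% nut_ids) ||
      !all(nut_ids %in% names(cfg$baseline_per2000))) {
    validation_error("baseline_per2000 must cover exactly the analysis nutrients")
  }
  if (any(cfg$baseline_per2000 < 0)) validation_error("baseline intakes must be >= 0")
  if (cfg$weight_cv <= 0) validation_error("weight_cv must be > 0")
  cfg
}

#' Generate a synthetic food catalog
#'
#' Produces `n_foods_per_category` foods in each of the 12 analysis
#' categories. Whole-grain foods span tiers 1-4 and the WG BNS source labels
#' (breakfast cereal and bread analogues first); unclassified foods are the
#' composite mixed dishes carrying baseline nutrient density (and, when
#' gradients are configured, the two gradient dishes).
#'
#' @param config A [sim_config()].
#' @return A validated catalog data.frame.
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  k <- config$n_foods_per_category
  nut_ids <- analysis_nutrients()$nutrient_id
  ncol_nut <- length(nut_ids)

  rows <- list()
  add_category <- function(cat, tiers, bns, serving, energy, descr) {
    df <- data.frame(
      food_code = NA_character_, description = descr, cfg_group = cat,
      cfg_tier = tiers, bns_group = bns,
      is_whole_grain = cat == "whole_grains",
      grams_per_serving = serving, energy_kcal_per_g = energy,
      stringsAsFactors = FALSE
    )
    df[nut_col(nut_ids)] <- 0
    rows[[length(rows) + 1]] <<- df
  }

  # whole and refined grains: mass only (zero energy/nutrient density, see
  # the generator design notes in the methods vignette)
  add_category(
    "whole_grains", rep_len(1:4, k), rep_len(wg_bns_labels(), k),
    round(stats::runif(k, 25, 65)), 0,
    paste0("whole grain food ", seq_len(k))
  )
  add_category(
    "refined_grains", rep_len(1:4, k),
    rep_len(c("white and enriched bread", "refined breakfast cereal",
              "white rice", "refined pasta"), k),
    round(stats::runif(k, 30, 80)), 0,
    paste0("refined grain food ", seq_len(k))
  )

  other <- list(
    fruit = c(0.3, 0.9), vegetables = c(0.2, 0.8),
    dairy_alternatives = c(0.4, 1.5), meat_poultry = c(1.5, 3.0),
    processed_meats = c(2.0, 3.5), fish_shellfish = c(1.0, 2.5),
    legumes_nuts_seeds = c(2.0, 6.0), eggs = c(1.4, 1.6)
  )
  for (cat in names(other)) {
    rng <- other[[cat]]
    add_category(
      cat, rep_len(1:4, k), gsub("_", " ", cat),
      round(stats::runif(k, 30, 150)), round(stats::runif(k, rng[1], rng[2]), 2),
      paste0(gsub("_", " ", cat), " food ", seq_len(k))
    )
  }
  add_category(
    "discretionary", rep(NA_integer_, k), "confectionery and snacks",
    rep(NA_real_, k), round(stats::runif(k, 2, 5), 2),
    paste0("discretionary food ", seq_len(k))
  )

  # unclassified: gradient dishes (if configured) + baseline dish pool
  eff <- config$nutrient_effect
  n_grad <- if (length(eff) > 0) 2L else 0L
  n_base <- k - n_grad
  if (n_grad > 0) {
    grad <- data.frame(
      food_code = NA_character_,
      description = c(WG_GRADIENT_POS, WG_GRADIENT_NEG),
      cfg_group = "unclassified", cfg_tier = NA_integer_,
      bns_group = "mixed dishes", is_whole_grain = FALSE,
      grams_per_serving = NA_real_, energy_kcal_per_g = 0,
      stringsAsFactors = FALSE
    )
    grad[nut_col(nut_ids)] <- 0
    for (nm in names(eff)) {
      grad[1, nut_col(nm)] <- max(eff[[nm]], 0)
      grad[2, nut_col(nm)] <- max(-eff[[nm]], 0)
    }
    rows[[length(rows) + 1]] <- grad
  }
  base <- data.frame(
    food_code = NA_character_,
    description = paste0("composite mixed dish ", seq_len(n_base)),
    cfg_group = "unclassified", cfg_tier = NA_integer_,
    bns_group = "mixed dishes", is_whole_grain = FALSE,
    grams_per_serving = NA_real_,
    energy_kcal_per_g = round(stats::runif(n_base, 0.8, 2.0), 2),
    stringsAsFactors = FALSE
  )
  g_dish <- dish_design_grams(config)           # per-2000 design grams per dish
  jitter <- matrix(stats::rlnorm(n_base * ncol_nut, 0, 0.5), n_base, ncol_nut)
  dens <- sweep(jitter, 2, colSums(jitter), "/")           # columns sum to 1
  dens <- sweep(dens, 2, config$baseline_per2000[nut_ids] / g_dish, "*")
  base[nut_col(nut_ids)] <- dens
  rows[[length(rows) + 1]] <- base

  catalog <- do.call(rbind, rows)
  catalog$food_code <- sprintf("F%03d", seq_len(nrow(catalog)))
  validate_catalog(catalog)
  catalog
}

# per-2000 design grams of each baseline dish (total 600 g split evenly)
dish_design_grams <- function(config) {
  n_grad <- if (length(config$nutrient_effect) > 0) 2L else 0L
  n_base <- config$n_foods_per_category - n_grad
  600 / n_base
}

# truncated log-normal via inverse CDF (no atom at the cap)
rlnorm_trunc <- function(n, meanlog, sdlog, cap) {
  pmax <- stats::plnorm(cap, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, 0, pmax), meanlog, sdlog)
}

#' Generate a synthetic survey: participants and recall records
#'
#' @param config A [sim_config()].
#' @param catalog The catalog from [generate_catalog()] under the same config.
#' @return A list with elements:
#'   * `participants` — validated participant table (with `psu` and
#'     `bsw_1..bsw_B` columns; each replicate column is calibrated to the
#'     full-sample weight total within stratum),
#'   * `recalls` — long-format recall records,
#'   * `truth` — per-participant ground truth: drawn WG grams, energy, and
#'     the expected per-2000-kcal intake of every nutrient with a configured
#'     gradient.
#' @export
generate_survey <- function(config, catalog) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  nc <- config$n_children; na <- config$n_adults
  n <- nc + na
  stratum <- c(rep("child", nc), rep("adult", na))
  id <- sprintf("P%05d", seq_len(n))

  age <- ifelse(stratum == "child",
                sample(1:18, n, replace = TRUE),
                sample(19:90, n, replace = TRUE))
  gender <- sample(c("female", "male"), n, replace = TRUE)
  hh_size <- sample(1:6, n, replace = TRUE, prob = c(.15, .30, .20, .20, .10, .05))
  income <- round(stats::rlnorm(n, log(60000), 0.6))
  bmi <- ifelse(stratum == "adult", pmin(pmax(stats::rnorm(n, 26.5, 4.5), 15), 55), NA_real_)
  bmi_z <- ifelse(stratum == "child", stats::runif(n, 0, 100), NA_real_)
  suppl <- stats::runif(n) < 0.45

  # exposure and energy
  p_wg <- config$prob_wg_consumer[stratum]
  consumer <- stats::runif(n) < p_wg
  wg <- numeric(n)
  for (s in c("child", "adult")) {
    idx <- which(consumer & stratum == s)
    wg[idx] <- rlnorm_trunc(length(idx), config$wg_meanlog[[s]],
                            config$wg_sdlog[[s]], config$wg_cap)
  }
  energy <- stats::rnorm(n, config$energy_mean[stratum], config$energy_sd[stratum]) +
    config$energy_per_wg_gram[stratum] * wg
  energy <- pmax(energy, config$energy_min)

  # sampling weights and Rao-Wu-style calibrated bootstrap replicates
  sdlog_w <- sqrt(log(1 + config$weight_cv^2))
  w <- stats::rlnorm(n, log(1000) - sdlog_w^2 / 2, sdlog_w)
  psu <- integer(n)
  B <- config$n_replicates
  bsw <- matrix(0, n, B)
  for (s in c("child", "adult")) {
    idx <- which(stratum == s)
    m <- config$n_psu
    psu[idx] <- sample.int(m, length(idx), replace = TRUE)
    for (b in seq_len(B)) {
      repeat {
        draws <- sample.int(m, m - 1L, replace = TRUE)
        mult <- tabulate(draws, nbins = m) * m / (m - 1L)
        wb <- w[idx] * mult[psu[idx]]
        if (sum(wb) > 0) break
      }
      bsw[idx, b] <- wb * sum(w[idx]) / sum(wb)
    }
  }

  participants <- data.frame(
    participant_id = id, age_years = age, gender = gender,
    household_size = hh_size, household_income = income,
    bmi = bmi, bmi_z_pctile = bmi_z, supplement_use = suppl,
    weight = w, psu = psu, stringsAsFactors = FALSE
  )
  participants[paste0("bsw_", seq_len(B))] <- as.data.frame(bsw)
  validate_participants(participants)

  recalls <- build_recalls(config, catalog, id, stratum, wg, energy)

  eff <- config$nutrient_effect
  truth <- data.frame(participant_id = id, stratum = stratum,
                      wg_grams = wg, energy_kcal = energy,
                      stringsAsFactors = FALSE)
  for (nm in names(eff)) {
    s <- eff[[nm]]
    grad <- if (s >= 0) s * wg else abs(s) * (config$wg_cap - wg)
    truth[[paste0("gradient_", nm)]] <- grad
  }
  list(participants = participants, recalls = recalls, truth = truth)
}

# assemble the long recall table; grams of dish/category foods scale with
# energy so that recall-derived energy equals the drawn energy exactly
build_recalls <- function(config, catalog, id, stratum, wg, energy) {
  n <- length(id)
  out <- list()

  # whole-grain foods: split wg grams by Dirichlet around the source shares
  wg_foods <- catalog[catalog$cfg_group == "whole_grains", ]
  shares <- config$wg_source_shares
  food_share <- shares[wg_foods$bns_group]
  food_share[is.na(food_share)] <- min(shares) / 2
  food_share <- food_share / ave(rep(1, nrow(wg_foods)), wg_foods$bns_group, FUN = sum)
  cons <- which(wg > 0)
  if (length(cons) > 0) {
    conc <- 4
    kw <- nrow(wg_foods)
    g <- matrix(stats::rgamma(length(cons) * kw,
                              shape = rep(conc * kw * food_share, each = length(cons))),
                nrow = length(cons))
    g <- g / rowSums(g) * wg[cons]
    out$wg <- data.frame(
      participant_id = rep(id[cons], kw),
      food_code = rep(wg_foods$food_code, each = length(cons)),
      grams = as.vector(g), stringsAsFactors = FALSE
    )
  }

  # refined grains: one food per refined-grain consumer
  rg_foods <- catalog$food_code[catalog$cfg_group == "refined_grains"]
  refined <- which(stats::runif(n) < config$prob_refined_consumer)
  if (length(refined) > 0) {
    out$refined <- data.frame(
      participant_id = id[refined],
      food_code = sample(rg_foods, length(refined), replace = TRUE),
      grams = stats::rlnorm(length(refined), config$refined_meanlog,
                            config$refined_sdlog),
      stringsAsFactors = FALSE
    )
  }

  # regular category foods (per-2000 design grams, scaled later)
  pool <- catalog$food_code[catalog$cfg_group %in%
                              setdiff(cfg_categories(),
                                      c("whole_grains", "refined_grains", "unclassified"))]
  m_i <- sample(4:10, n, replace = TRUE)
  reg_pid <- rep(id, m_i)
  reg_food <- unlist(lapply(m_i, function(m) sample(pool, m)), use.names = FALSE)
  reg_g2000 <- stats::rlnorm(length(reg_pid), log(80), 0.6)

  # baseline dishes: everyone eats the full pool with log-normal noise
  is_grad <- catalog$description %in% c(WG_GRADIENT_POS, WG_GRADIENT_NEG)
  dish <- catalog[catalog$cfg_group == "unclassified" & !is_grad, ]
  J <- nrow(dish)
  dish_pid <- rep(id, each = J)
  dish_food <- rep(dish$food_code, n)
  dish_g2000 <- dish_design_grams(config) *
    stats::rlnorm(n * J, 0, config$dish_noise_sdlog)

  # energy scaling: per-participant per-2000 energy of the scaled pool -> 2000
  edens <- stats::setNames(catalog$energy_kcal_per_g, catalog$food_code)
  e_contrib <- c(reg_g2000 * edens[reg_food], dish_g2000 * edens[dish_food])
  pid_all <- c(reg_pid, dish_pid)
  s_i <- tapply(e_contrib, factor(pid_all, levels = id), sum)
  scale_i <- stats::setNames(energy / as.numeric(s_i), id)
  out$regular <- data.frame(
    participant_id = reg_pid, food_code = reg_food,
    grams = reg_g2000 * scale_i[reg_pid], stringsAsFactors = FALSE
  )
  out$dishes <- data.frame(
    participant_id = dish_pid, food_code = dish_food,
    grams = dish_g2000 * scale_i[dish_pid], stringsAsFactors = FALSE
  )

  # gradient dishes (exact slope carriers)
  if (any(is_grad)) {
    pos_code <- catalog$food_code[catalog$description == WG_GRADIENT_POS]
    neg_code <- catalog$food_code[catalog$description == WG_GRADIENT_NEG]
    out$grad_pos <- data.frame(
      participant_id = id, food_code = pos_code,
      grams = wg * energy / 2000, stringsAsFactors = FALSE
    )
    out$grad_neg <- data.frame(
      participant_id = id, food_code = neg_code,
      grams = (config$wg_cap - wg) * energy / 2000, stringsAsFactors = FALSE
    )
  }

  recalls <- do.call(rbind, out)
  rownames(recalls) <- NULL
  recalls <- recalls[recalls$grams > 0, , drop = FALSE]
  validate_recalls(recalls, catalog)
  recalls
}
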