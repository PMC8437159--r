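# Synthetic six-site household survey generator.
#
# The generator states a world with the statistical structure the analysis
# assumes: six sites in three countries, configured exposure prevalences and
# covariate mixes (defaults calibrated once to the published descriptive
# magnitudes), per-food-group consumption propensities on the logit scale,
# additive exposure/covariate logit shifts for the during-emergency period,
# a shared per-site normal random effect inducing exchangeable within-site
# correlation, beta-binomial overdispersion, and per-field missingness.

# internal: run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic survey generator
#'
#' Every argument has a default stating the generator's world; defaults for
#' exposure prevalences and covariate mixes are calibrated to the magnitudes
#' of the published site-stratified descriptive tables, and food-group
#' propensities are set so that before-period dietary diversity scores land
#' in the low range (site means roughly 1.3-2.3) typical of these sites.
#' Probabilities are unconditional per household; matrices are site x
#' category with sites in codebook order (nouna, ouagadougou, kersa,
#' addis_ababa, ibadan, lagos).
#'
#' @param n_per_site named integer vector of households per site.
#' @param price_increase,price_decrease 6 x 5 matrices of price-change
#'   probabilities per food category (`staples`, `pulses`, `fruits`,
#'   `vegetables`, `asf`); `unchanged` takes the remainder.
#' @param female,head,worried,skipped,whole_day,social_assistance named
#'   6-vectors of per-site probabilities.
#' @param age_probs,education_probs,occupation_probs,crop_probs 6 x k
#'   category-probability matrices (rows sum to 1).
#' @param assistance_type_probs probabilities of cash/food/school_meals/other
#'   given assistance received.
#' @param household_size_mean named 6-vector; sizes are 1 + Poisson(mean - 1).
#' @param baseline_logit named 20-vector of baseline consumption propensities
#'   (logit scale, survey-group ids).
#' @param during_drift logit shift applied to every group in the during
#'   period (the emergency-wide consumption decline).
#' @param effects named list: exposure/covariate indicator id (one of the five
#'   `price_*` fields, `worried_food`, `skipped_meal`, `whole_day_no_food`,
#'   `locality_rural`, `female`) -> named vector of additive logit shifts per
#'   survey food group, applied in the during period for households with the
#'   indicator set.
#' @param site_sd SD of the shared per-site normal random effect (logit
#'   scale); the paper reports no variance components, so the default 0.25 is
#'   an arbitrary, documented choice.
#' @param overdispersion beta-binomial intra-household correlation rho in
#'   `[0, 1)`; 0 gives pure Binomial(7, p) days.
#' @param missingness named per-field missingness rates (confounders and
#'   exposures only; food-frequency outcomes are never set missing).
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @return list of class `dietshock_synthetic_config`.
#' @export
synthetic_config <- function(
    n_per_site = c(nouna = 300L, ouagadougou = 300L, kersa = 300L,
                   addis_ababa = 300L, ibadan = 300L, lagos = 300L),
    price_increase = default_price_increase(),
    price_decrease = default_price_decrease(),
    female = c(nouna = 0.118, ouagadougou = 0.320, kersa = 0.222,
               addis_ababa = 0.646, ibadan = 0.513, lagos = 0.383),
    head = c(nouna = 0.869, ouagadougou = 0.867, kersa = 0.852,
             addis_ababa = 0.788, ibadan = 0.507, lagos = 0.605),
    worried = c(nouna = 0.444, ouagadougou = 0.643, kersa = 0.795,
                addis_ababa = 0.542, ibadan = 0.738, lagos = 0.653),
    skipped = c(nouna = 0.137, ouagadougou = 0.240, kersa = 0.139,
                addis_ababa = 0.199, ibadan = 0.703, lagos = 0.591),
    whole_day = c(nouna = 0.096, ouagadougou = 0.117, kersa = 0.030,
                  addis_ababa = 0.153, ibadan = 0.263, lagos = 0.237),
    social_assistance = c(nouna = 0.041, ouagadougou = 0.233, kersa = 0.145,
                          addis_ababa = 0.153, ibadan = 0.092, lagos = 0.074),
    age_probs = rbind(nouna = c(0.047, 0.209, 0.744),
                      ouagadougou = c(0.023, 0.167, 0.810),
                      kersa = c(0.111, 0.502, 0.387),
                      addis_ababa = c(0.247, 0.364, 0.389),
                      ibadan = c(0.187, 0.243, 0.570),
                      lagos = c(0.211, 0.250, 0.539)),
    education_probs = rbind(nouna = c(0.771, 0.199, 0.030),
                            ouagadougou = c(0.710, 0.270, 0.020),
                            kersa = c(0.744, 0.212, 0.044),
                            addis_ababa = c(0.355, 0.251, 0.394),
                            ibadan = c(0.037, 0.282, 0.681),
                            lagos = c(0.007, 0.066, 0.927)),
    occupation_probs = rbind(nouna = c(0.024, 0.792, 0.045, 0.139),
                             ouagadougou = c(0.193, 0.173, 0.167, 0.467),
                             kersa = c(0.088, 0.865, 0.010, 0.037),
                             addis_ababa = c(0.444, 0.001, 0.133, 0.422),
                             ibadan = c(0.013, 0.063, 0.269, 0.655),
                             lagos = c(0.028, 0.028, 0.423, 0.521)),
    crop_probs = rbind(nouna = c(0.418, 0.259, 0.279, 0.044),
                       ouagadougou = c(0.266, 0.033, 0.003, 0.698),
                       kersa = c(0.478, 0.434, 0.057, 0.031),
                       addis_ababa = c(0.010, 0.004, 0.003, 0.983),
                       ibadan = c(0.138, 0.076, 0.030, 0.756),
                       lagos = c(0.010, 0.019, 0.032, 0.939)),
    assistance_type_probs = c(cash = 0.21, food = 0.61, school_meals = 0.02,
                              other = 0.16),
    household_size_mean = c(nouna = 9.9, ouagadougou = 7.3, kersa = 7.0,
                            addis_ababa = 4.2, ibadan = 5.3, lagos = 4.9),
    baseline_logit = default_baseline_logit(),
    during_drift = -0.25,
    effects = default_effects(),
    site_sd = 0.25,
    overdispersion = 0.08,
    missingness = default_missingness(),
    seed = 20200801L) {
  cfg <- structure(as.list(environment()),
                   class = "dietshock_synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @export
default_price_increase <- function() {
  m <- rbind(nouna = c(0.710, 0.696, 0.598, 0.612, 0.612),
             ouagadougou = c(0.879, 0.796, 0.758, 0.825, 0.798),
             kersa = c(0.976, 0.980, 0.958, 0.959, 0.963),
             addis_ababa = c(0.933, 0.908, 0.597, 0.757, 0.782),
             ibadan = c(0.909, 0.920, 0.912, 0.906, 0.916),
             lagos = c(0.987, 0.977, 0.970, 0.980, 0.983))
  colnames(m) <- c("staples", "pulses", "fruits", "vegetables", "asf")
  m
}

#' @rdname synthetic_config
#' @export
default_price_decrease <- function() {
  m <- rbind(nouna = c(0.026, 0.029, 0.035, 0.043, 0.101),
             ouagadougou = c(0.000, 0.011, 0.004, 0.018, 0.000),
             kersa = c(0.004, 0.000, 0.004, 0.007, 0.000),
             addis_ababa = c(0.032, 0.013, 0.157, 0.146, 0.056),
             ibadan = c(0.024, 0.020, 0.017, 0.020, 0.024),
             lagos = c(0.003, 0.007, 0.003, 0.003, 0.007))
  colnames(m) <- c("staples", "pulses", "fruits", "vegetables", "asf")
  m
}

#' @rdname synthetic_config
#' @export
default_baseline_logit <- function() {
  p <- c(dark_green_leafy_veg = 0.75, other_vit_a_fruit_veg = 0.40,
         cruciferous_veg = 0.35, other_veg = 0.78, citrus_fruits = 0.25,
         other_fruits = 0.35, fish = 0.30, eggs = 0.20, poultry = 0.12,
         legumes = 0.80, nuts_seeds = 0.20, dairy = 0.20,
         whole_grains = 0.85, liquid_veg_oils = 0.70, red_meat = 0.20,
         processed_meat = 0.05, refined_grains = 0.88, ssb = 0.35,
         desserts_sweets = 0.25, roots_tubers = 0.78)
  stats::qlogis(p)
}

#' @rdname synthetic_config
#' @export
default_effects <- function() {
  list(
    price_staples = c(whole_grains = -0.2, refined_grains = -0.2,
                      roots_tubers = -0.2),
    price_pulses = c(legumes = -0.5),
    price_fruits = c(citrus_fruits = -0.3, other_fruits = -0.3),
    price_vegetables = c(dark_green_leafy_veg = -0.2, cruciferous_veg = -0.2,
                         other_veg = -0.2, other_vit_a_fruit_veg = -0.2),
    price_asf = c(fish = -0.25, poultry = -0.25, red_meat = -0.25,
                  processed_meat = -0.25, eggs = -0.25, dairy = -0.25)
  )
}

#' @rdname synthetic_config
#' @export
default_missingness <- function() {
  c(price_staples = 0.05, price_pulses = 0.05, price_fruits = 0.05,
    price_vegetables = 0.05, price_asf = 0.05,
    respondent_sex = 0.002, age_band = 0.005, education = 0.01,
    head_of_household = 0.005, household_size = 0.01, occupation = 0.01,
    worried_food = 0.003, skipped_meal = 0.003, whole_day_no_food = 0.003,
    crop_production = 0.01, social_assistance = 0.003)
}

# valid effect-map indicator ids
effect_keys <- function() c("price_staples", "price_pulses", "price_fruits",
                            "price_vegetables", "price_asf", "worried_food",
                            "skipped_meal", "whole_day_no_food",
                            "locality_rural", "female")

#' Validate a synthetic-survey configuration
#' @param cfg a `dietshock_synthetic_config`.
#' @return `cfg`, invisibly; errors with class `dietshock_config_error`.
#' @export
validate_synthetic_config <- function(cfg) {
  fail <- function(msg) abort(msg, "dietshock_config_error")
  cb <- default_codebook()
  sites <- cb$sites$site
  if (!all(sites %in% names(cfg$n_per_site)) || any(cfg$n_per_site <= 0))
    fail("n_per_site must name all six sites with positive counts")
  prob_ok <- function(x) all(!is.na(x)) && all(x >= 0) && all(x <= 1)
  for (f in c("female", "head", "worried", "skipped", "whole_day",
              "social_assistance"))
    if (!prob_ok(cfg[[f]])) fail(paste0(f, " probabilities must be in [0,1]"))
  for (f in c("price_increase", "price_decrease"))
    if (!prob_ok(cfg[[f]])) fail(paste0(f, " probabilities must be in [0,1]"))
  if (any(cfg$price_increase + cfg$price_decrease > 1))
    fail("price increase + decrease probabilities exceed 1")
  for (f in c("age_probs", "education_probs", "occupation_probs",
              "crop_probs")) {
    m <- cfg[[f]]
    if (!prob_ok(m) || any(abs(rowSums(m) - 1) > 1e-6))
      fail(paste0(f, " rows must be probabilities summing to 1"))
  }
  if (!prob_ok(cfg$missingness)) fail("missingness rates must be in [0,1]")
  if (any(grepl("^fg_", names(cfg$missingness))))
    fail("missingness must not target food-frequency outcome fields")
  if (cfg$overdispersion < 0 || cfg$overdispersion >= 1)
    fail("overdispersion must be in [0,1)")
  if (cfg$site_sd < 0) fail("site_sd must be non-negative")
  bad <- setdiff(names(cfg$effects), effect_keys())
  if (length(bad))
    fail(paste0("unknown effect key(s): ", paste(bad, collapse = ", ")))
  for (k in names(cfg$effects)) {
    bad <- setdiff(names(cfg$effects[[k]]), cb$survey_groups$id)
    if (length(bad))
      fail(paste0("effect '", k, "' targets unknown food group(s): ",
                  paste(bad, collapse = ", ")))
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    fail("seed must be a single integer")
  invisible(cfg)
}

# internal: beta-binomial days draw, vectorized over p
rdays <- function(n, p, rho) {
  if (rho <= 0) return(stats::rbinom(n, 7L, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  q <- stats::rbeta(n, a, b)
  stats::rbinom(n, 7L, q)
}

# internal: household-level 0/1 indicator for an effect key
effect_indicator <- function(df, key) {
  switch(key,
         price_staples = ,
         price_pulses = ,
         price_fruits = ,
         price_vegetables = ,
         price_asf = as.integer(!is.na(df[[key]]) & df[[key]] == "increased"),
         worried_food = ,
         skipped_meal = ,
         whole_day_no_food = as.integer(!is.na(df[[key]]) & df[[key]] == "yes"),
         locality_rural = as.integer(df$locality == "rural"),
         female = as.integer(!is.na(df$respondent_sex) &
                               df$respondent_sex == "female"),
         abort(paste0("unknown exposure id: ", key), "dietshock_key_error"))
}

# internal: generate one site's households (no missingness yet)
generate_site <- function(site, cfg, cb, site_effect) {
  n <- cfg$n_per_site[[site]]
  info <- cb$sites[cb$sites$site == site, ]
  draw <- function(levels, probs) sample(levels, n, replace = TRUE,
                                         prob = probs)
  yn <- function(p) draw(c("yes", "no"), c(p, 1 - p))
  df <- data.frame(
    household_id = sprintf("%s_%04d", site, seq_len(n)),
    country = info$country, site = site, locality = info$locality,
    respondent_sex = draw(c("female", "male"),
                          c(cfg$female[[site]], 1 - cfg$female[[site]])),
    age_band = draw(c("20_29", "30_39", "40_plus"), cfg$age_probs[site, ]),
    education = draw(c("none_incomplete_primary",
                       "primary_incomplete_secondary", "secondary_or_higher"),
                     cfg$education_probs[site, ]),
    head_of_household = yn(cfg$head[[site]]),
    household_size = 1L + stats::rpois(n, cfg$household_size_mean[[site]] - 1),
    occupation = draw(c("unemployed", "farmer_casual_labor", "employed",
                        "student_self_employed_other"),
                      cfg$occupation_probs[site, ]),
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(cfg$price_increase))) {
    cat_name <- colnames(cfg$price_increase)[j]
    pi <- cfg$price_increase[site, j]
    pd <- cfg$price_decrease[site, j]
    df[[paste0("price_", cat_name)]] <-
      draw(c("increased", "decreased", "unchanged"), c(pi, pd, 1 - pi - pd))
  }
  df$worried_food <- yn(cfg$worried[[site]])
  df$skipped_meal <- yn(cfg$skipped[[site]])
  df$whole_day_no_food <- yn(cfg$whole_day[[site]])
  df$social_assistance <- yn(cfg$social_assistance[[site]])
  df$assistance_type <- ifelse(
    df$social_assistance == "yes",
    draw(names(cfg$assistance_type_probs), cfg$assistance_type_probs),
    "none")
  df$crop_production <- draw(c("unchanged", "decreased", "increased",
                               "does_not_farm"), cfg$crop_probs[site, ])

  # consumption: logit(p) = baseline + site effect (+ drift + effects, during)
  ids <- cb$survey_groups$id
  base <- cfg$baseline_logit[ids] + site_effect
  shift <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  for (k in names(cfg$effects)) {
    ind <- effect_indicator(df, k)
    eff <- cfg$effects[[k]]
    shift[, names(eff)] <- shift[, names(eff), drop = FALSE] +
      outer(ind, unname(eff))
  }
  for (g in seq_along(ids)) {
    p_before <- stats::plogis(base[g])
    p_during <- stats::plogis(base[g] + cfg$during_drift + shift[, g])
    df[[paste0("fg_", ids[g], "_before")]] <-
      rdays(n, rep(p_before, n), cfg$overdispersion)
    df[[paste0("fg_", ids[g], "_during")]] <-
      rdays(n, p_during, cfg$overdispersion)
  }
  df
}

#' Generate a synthetic six-site household survey
#'
#' Draws covariates and exposures per configured prevalences, consumption
#' days as (beta-)binomial counts of 7 with logit-scale propensities
#' (baseline + during-period drift + exposure/covariate shifts + shared site
#' effect), then injects per-field missingness. Deterministic given the
#' config seed; per-site sub-streams are derived so sites are independent.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `records` (survey data.frame, schema column order) and
#'   `truth` (realized site effects, effect map, drift, and config snapshot —
#'   enough to rerun the oracle).
#' @export
generate_survey <- function(cfg = synthetic_config()) {
  validate_synthetic_config(cfg)
  cb <- default_codebook()
  site_effects <- with_seed(derive_seed(cfg$seed, "site_effects"),
                            stats::setNames(stats::rnorm(nrow(cb$sites), 0,
                                                         cfg$site_sd),
                                            cb$sites$site))
  parts <- lapply(cb$sites$site, function(s)
    with_seed(derive_seed(cfg$seed, paste0("site_", s)),
              generate_site(s, cfg, cb, site_effects[[s]])))
  records <- do.call(rbind, parts)
  records <- records[, survey_schema(cb)$column]
  records <- inject_missingness(records, cfg$missingness,
                                derive_seed(cfg$seed, "missingness"))
  truth <- list(site_effects = site_effects, effects = cfg$effects,
                during_drift = cfg$during_drift, config = cfg)
  list(records = records, truth = truth)
}

#' Inject per-field missingness
#'
#' Each targeted field is independently set missing at its rate. Outcome
#' food-frequency fields (`fg_*`) are refused: the analysis treats only
#' confounder/exposure missingness.
#'
#' @param records survey data.frame.
#' @param rates named vector of per-field rates in `[0, 1]`.
#' @param seed integer seed.
#' @return records with `NA`s injected.
#' @export
inject_missingness <- function(records, rates, seed = 1L) {
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    abort("missingness rates must be in [0,1]", "dietshock_config_error")
  if (any(grepl("^fg_", names(rates))))
    abort("missingness must not target food-frequency outcome fields",
          "dietshock_config_error")
  for (f in names(rates)) {
    if (rates[[f]] == 0 || !f %in% names(records)) next
    hit <- with_seed(derive_seed(seed, paste0("miss_", f)),
                     stats::runif(nrow(records)) < rates[[f]])
    records[[f]][hit] <- NA
  }
  records
}

#' Monte-Carlo oracle for the implied score-level effect of an exposure
#'
#' Computes the marginal mean difference in DDS or PDQS between exposed and
#' unexposed households implied by the generator's food-group-level effect
#' map, with all other inputs (covariates, other exposures, site membership,
#' site effects, sampling noise) marginalized. Households are simulated in
#' matched pairs (exposure forced on/off, all else shared), and scored with
#' the production scoring module — the oracle owns no second scoring rule.
#'
#' @param cfg a [synthetic_config()].
#' @param exposure indicator id (see `effects` in [synthetic_config()]).
#' @param score `"dds"` or `"pdqs"`.
#' @param n_mc number of Monte-Carlo households (>= 1000).
#' @param seed integer seed (defaults to a sub-stream of the config seed).
#' @return list with `effect` (mean paired difference), `se` (Monte-Carlo
#'   standard error), `n_mc`.
#' @export
implied_effect_oracle <- function(cfg, exposure, score = c("dds", "pdqs"),
                                  n_mc = 10000L,
                                  seed = derive_seed(cfg$seed, "oracle")) {
  score <- match.arg(score)
  validate_synthetic_config(cfg)
  if (!exposure %in% effect_keys())
    abort(paste0("unknown exposure id: ", exposure), "dietshock_key_error")
  if (n_mc < 1000L)
    abort("n_mc must be at least 1000", "dietshock_config_error")
  cb <- default_codebook()
  ids <- cb$survey_groups$id
  eff <- cfg$effects[[exposure]]
  with_seed(seed, {
    sites <- sample(cb$sites$site, n_mc, replace = TRUE,
                    prob = cfg$n_per_site[cb$sites$site])
    site_eff <- stats::rnorm(n_mc, 0, cfg$site_sd)  # marginalized per draw
    # covariate/other-exposure indicators only matter through the effect map
    other_shift <- matrix(0, n_mc, length(ids), dimnames = list(NULL, ids))
    for (k in setdiff(names(cfg$effects), exposure)) {
      prob <- switch(k,
        price_staples = cfg$price_increase[sites, "staples"],
        price_pulses = cfg$price_increase[sites, "pulses"],
        price_fruits = cfg$price_increase[sites, "fruits"],
        price_vegetables = cfg$price_increase[sites, "vegetables"],
        price_asf = cfg$price_increase[sites, "asf"],
        worried_food = cfg$worried[sites],
        skipped_meal = cfg$skipped[sites],
        whole_day_no_food = cfg$whole_day[sites],
        locality_rural = as.numeric(cb$sites$locality[
          match(sites, cb$sites$site)] == "rural"),
        female = cfg$female[sites])
      ind <- stats::rbinom(n_mc, 1L, prob)
      ek <- cfg$effects[[k]]
      other_shift[, names(ek)] <- other_shift[, names(ek), drop = FALSE] +
        outer(ind, unname(ek))
    }
    mk_records <- function(exposed) {
      df <- data.frame(site = sites, stringsAsFactors = FALSE)
      for (g in seq_along(ids)) {
        shift_g <- other_shift[, g] +
          if (exposed && ids[g] %in% names(eff)) eff[[ids[g]]] else 0
        p <- stats::plogis(cfg$baseline_logit[[ids[g]]] + site_eff +
                             cfg$during_drift + shift_g)
        d <- rdays(n_mc, p, cfg$overdispersion)
        df[[paste0("fg_", ids[g], "_before")]] <- d  # unused, schema filler
        df[[paste0("fg_", ids[g], "_during")]] <- d
      }
      df
    }
    s1 <- score_survey(mk_records(TRUE), cb)
    s0 <- score_survey(mk_records(FALSE), cb)
    diff <- s1[[paste0(score, "_during")]] - s0[[paste0(score, "_during")]]
    list(effect = mean(diff), se = stats::sd(diff) / sqrt(n_mc), n_mc = n_mc)
  })
}
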