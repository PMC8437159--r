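# Shared fixtures: everything is built in code, nothing is read from disk.

CB <- default_codebook()
SITES <- CB$sites$site

# a valid survey data.frame of n households, all food-group days 0 by default
make_blank_survey <- function(n, site = "nouna") {
  if (n == 0L) return(make_blank_survey(1L, site)[0L, ])
  info <- CB$sites[CB$sites$site == site, ]
  df <- data.frame(
    household_id = sprintf("%s_%04d", site, seq_len(n)),
    country = info$country, site = site, locality = info$locality,
    respondent_sex = "male", age_band = "30_39",
    education = "primary_incomplete_secondary", head_of_household = "yes",
    household_size = 4L, occupation = "employed",
    price_staples = "increased", price_pulses = "increased",
    price_fruits = "increased", price_vegetables = "increased",
    price_asf = "increased", worried_food = "no", skipped_meal = "no",
    whole_day_no_food = "no", social_assistance = "no",
    assistance_type = "none", crop_production = "unchanged",
    stringsAsFactors = FALSE)
  for (col in c(paste0("fg_", CB$survey_groups$id, "_before"),
                paste0("fg_", CB$survey_groups$id, "_during")))
    df[[col]] <- 0L
  df[, survey_schema(CB)$column]
}

# named 20-vector of days with overrides, e.g. days_vec(legumes = 7)
days_vec <- function(...) {
  d <- stats::setNames(rep(0, 20), CB$survey_groups$id)
  over <- list(...)
  d[names(over)] <- unlist(over)
  d
}

# set food-group day columns for one period from a named list
set_days <- function(df, period, ...) {
  over <- list(...)
  for (g in names(over))
    df[[paste0("fg_", g, "_", period)]] <- over[[g]]
  df
}

# a small fast synthetic config (no missingness unless asked)
small_config <- function(n = 30L, ...) {
  synthetic_config(
    n_per_site = stats::setNames(rep(as.integer(n), 6), SITES),
    missingness = c(price_staples = 0), ...)
}

# brute-force scorers: explicit loops over the printed point rules,
# independent of the production (vectorized) scoring path.
brute_dds <- function(days, masked = character(0), threshold = 7) {
  sg <- CB$survey_groups
  score <- 0L
  for (g in CB$mddw_groups$id) {
    members <- sg$id[sg$mddw_group == g & !(sg$id %in% masked)]
    if (!length(members)) next
    best <- 0
    for (m in members) if (days[[m]] > best) best <- days[[m]]
    if (best >= threshold) score <- score + 1L
  }
  score
}

brute_pdqs <- function(days, masked = character(0)) {
  sg <- CB$survey_groups
  score <- 0L
  for (i in seq_len(nrow(sg))) {
    if (sg$id[i] %in% masked) next
    s <- days[[sg$id[i]]]
    pts <- if (sg$pdqs_healthy[i]) {
      if (s <= 1) 0L else if (s <= 3) 1L else 2L
    } else {
      if (s <= 1) 2L else if (s <= 3) 1L else 0L
    }
    score <- score + pts
  }
  score
}
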