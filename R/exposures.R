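#' Code a price-change response as the binary exposure
#'
#' `increased` codes 1; `unchanged` and `decreased` code 0 (the published
#' reference category is "No change or decreased"); missing stays missing.
#'
#' @param resp character vector with values `unchanged`, `decreased`,
#'   `increased` or `NA`.
#' @return integer vector of 0/1/NA.
#' @export
code_price_change <- function(resp) {
  bad <- !is.na(resp) & !resp %in% c("unchanged", "decreased", "increased")
  if (any(bad))
    abort(paste0("unknown price-change level(s): ",
                 paste(unique(resp[bad]), collapse = ", ")),
          "dietshock_coding_error")
  ifelse(is.na(resp), NA_integer_, as.integer(resp == "increased"))
}

#' Code the three food-insecurity items
#'
#' Worried about running out of food, skipped a meal, and went a whole day
#' without eating (all past month): yes codes 1, no codes 0, else missing.
#'
#' @param records survey data.frame.
#' @return data.frame with integer columns `worried_food`, `skipped_meal`,
#'   `whole_day_no_food`.
#' @export
code_food_security <- function(records) {
  code1 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x == "yes"))
  data.frame(worried_food = code1(records$worried_food),
             skipped_meal = code1(records$skipped_meal),
             whole_day_no_food = code1(records$whole_day_no_food))
}

#' Code crop production as a 4-level factor
#'
#' Levels: unchanged (reference), decreased, increased, does_not_farm;
#' missing preserved.
#'
#' @param x character vector of raw responses.
#' @return factor with the 4 levels in reference-first order.
#' @export
code_crop_production <- function(x) {
  levels <- c("unchanged", "decreased", "increased", "does_not_farm")
  bad <- !is.na(x) & !x %in% levels
  if (any(bad))
    abort(paste0("unknown crop-production level(s): ",
                 paste(unique(x[bad]), collapse = ", ")),
          "dietshock_coding_error")
  factor(x, levels = levels)
}

#' Declare a model term
#'
#' @param field survey column the term reads.
#' @param type `"price"` (binary increase indicator), `"yesno"` (binary),
#'   `"categorical"` (reference-coded dummies) or `"continuous"`.
#' @param role `"exposure"` (always retained), `"candidate"` (subject to the
#'   univariate screen) or `"forced"` (retained regardless of the screen).
#' @param ref reference level for categorical terms.
#' @param levels level order for categorical terms (defaults to the schema).
#' @return list of class `dietshock_term`.
#' @export
term_spec <- function(field, type = c("categorical", "price", "yesno",
                                      "continuous"),
                      role = c("candidate", "exposure", "forced"),
                      ref = NULL, levels = NULL) {
  structure(list(field = field, type = match.arg(type),
                 role = match.arg(role), ref = ref, levels = levels),
            class = "dietshock_term")
}

#' Default model terms mirroring the published model-building setup
#'
#' Five price-change exposures (always retained); candidate confounders
#' screened univariately; crop production and household size forced into the
#' multivariate model. Reference levels follow the published tables:
#' price reference = no change or decreased; occupation reference = employed;
#' education reference = primary/incomplete secondary; age reference = 20-29;
#' locality reference = urban; sex reference = female.
#'
#' @return named list of [term_spec()] objects.
#' @export
default_model_terms <- function() {
  list(
    price_staples = term_spec("price_staples", "price", "exposure"),
    price_pulses = term_spec("price_pulses", "price", "exposure"),
    price_fruits = term_spec("price_fruits", "price", "exposure"),
    price_vegetables = term_spec("price_vegetables", "price", "exposure"),
    price_asf = term_spec("price_asf", "price", "exposure"),
    worried_food = term_spec("worried_food", "yesno", "candidate"),
    skipped_meal = term_spec("skipped_meal", "yesno", "candidate"),
    whole_day_no_food = term_spec("whole_day_no_food", "yesno", "candidate"),
    age_band = term_spec("age_band", "categorical", "candidate",
                         ref = "20_29",
                         levels = c("20_29", "30_39", "40_plus")),
    respondent_sex = term_spec("respondent_sex", "categorical", "candidate",
                               ref = "female", levels = c("female", "male")),
    education = term_spec("education", "categorical", "candidate",
                          ref = "primary_incomplete_secondary",
                          levels = c("primary_incomplete_secondary",
                                     "none_incomplete_primary",
                                     "secondary_or_higher")),
    head_of_household = term_spec("head_of_household", "yesno", "candidate"),
    occupation = term_spec("occupation", "categorical", "candidate",
                           ref = "employed",
                           levels = c("employed", "unemployed",
                                      "farmer_casual_labor",
                                      "student_self_employed_other")),
    locality = term_spec("locality", "categorical", "candidate",
                         ref = "urban", levels = c("urban", "rural")),
    crop_production = term_spec("crop_production", "categorical", "forced",
                                ref = "unchanged",
                                levels = c("unchanged", "decreased",
                                           "increased", "does_not_farm")),
    household_size = term_spec("household_size", "continuous", "forced")
  )
}

#' Build a regression design matrix with missing-indicator adjustment
#'
#' Encodes the requested terms against the outcome score, applying the
#' missing-indicator method for confounder missingness: categorical terms get
#' an explicit missing column where any missingness exists (dummies 0,
#' indicator 1); continuous terms are mean-imputed with a companion 0/1
#' indicator. Rows with a missing outcome (or missing cluster id) are dropped
#' with a logged count — outcome missingness is never imputed.
#'
#' @param records scored survey data.frame (see [score_survey()]).
#' @param terms named list of [term_spec()]s.
#' @param outcome `"dds"` or `"pdqs"` (the during-pandemic score).
#' @param cluster column used as the cluster id (default `"site"`).
#' @return list of class `dietshock_design`: `y`, `X` (with intercept),
#'   `cluster`, `term_map` (data.frame `column`, `term`, `level`, `is_missing_col`),
#'   `n_dropped_outcome`, `outcome`.
#' @export
encode_with_missing_indicators <- function(records, terms = default_model_terms(),
                                           outcome = c("dds", "pdqs"),
                                           cluster = "site") {
  outcome <- match.arg(outcome)
  ycol <- paste0(outcome, "_during")
  if (!ycol %in% names(records))
    abort(paste0("outcome column ", ycol,
                 " absent; run score_survey() first"), "dietshock_spec_error")
  bad <- setdiff(vapply(terms, `[[`, "", "field"), names(records))
  if (length(bad))
    abort(paste0("term(s) reference unknown field(s): ",
                 paste(bad, collapse = ", ")), "dietshock_spec_error")

  keep <- !is.na(records[[ycol]]) & !is.na(records[[cluster]])
  n_dropped <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  y <- as.numeric(rec[[ycol]])

  cols <- list(`(intercept)` = rep(1, nrow(rec)))
  map <- data.frame(column = "(intercept)", term = "(intercept)",
                    level = "", is_missing_col = FALSE,
                    stringsAsFactors = FALSE)
  add_col <- function(name, values, term, level, is_missing = FALSE) {
    cols[[name]] <<- values
    map <<- rbind(map, data.frame(column = name, term = term, level = level,
                                  is_missing_col = is_missing,
                                  stringsAsFactors = FALSE))
  }

  for (tn in names(terms)) {
    tm <- terms[[tn]]
    x <- rec[[tm$field]]
    if (tm$type == "price") {
      v <- code_price_change(x)
      miss <- is.na(v)
      v[miss] <- 0L
      add_col(paste0(tn, "_increased"), as.numeric(v), tn, "increased")
      if (any(miss)) add_col(paste0(tn, "_missing"), as.numeric(miss), tn,
                             "missing", TRUE)
    } else if (tm$type == "yesno") {
      v <- ifelse(is.na(x), NA_integer_, as.integer(x == "yes"))
      miss <- is.na(v)
      v[miss] <- 0L
      add_col(paste0(tn, "_yes"), as.numeric(v), tn, "yes")
      if (any(miss)) add_col(paste0(tn, "_missing"), as.numeric(miss), tn,
                             "missing", TRUE)
    } else if (tm$type == "categorical") {
      levels <- tm$levels %||% sort(unique(x[!is.na(x)]))
      ref <- tm$ref %||% levels[1]
      miss <- is.na(x)
      for (lv in setdiff(levels, ref))
        add_col(paste0(tn, "_", lv), as.numeric(!miss & x == lv), tn, lv)
      if (any(miss)) add_col(paste0(tn, "_missing"), as.numeric(miss), tn,
                             "missing", TRUE)
    } else {  # continuous: mean imputation + indicator
      v <- as.numeric(x)
      miss <- is.na(v)
      v[miss] <- mean(v, na.rm = TRUE)
      if (all(miss)) v[] <- 0
      add_col(tn, v, tn, "")
      if (any(miss)) add_col(paste0(tn, "_missing"), as.numeric(miss), tn,
                             "missing", TRUE)
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(y = y, X = X, cluster = as.character(rec[[cluster]]),
                 term_map = map, n_dropped_outcome = n_dropped,
                 outcome = outcome),
            class = "dietshock_design")
}
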