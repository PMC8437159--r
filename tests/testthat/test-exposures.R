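test_that("exposure coding follows the binary and factor rules", {
  expect_equal(code_price_change(c("increased", "decreased", "unchanged", NA)),
               c(1L, 0L, 0L, NA))
  expect_error(code_price_change("skyrocketed"),
               class = "dietshock_coding_error")
  # idempotent / total on valid enums
  expect_equal(code_price_change(c("increased", "increased")), c(1L, 1L))

  df <- make_blank_survey(3)
  df$worried_food <- c("yes", NA, "no")
  df$skipped_meal <- c("no", NA, "yes")
  df$whole_day_no_food <- c("no", NA, "yes")
  fs <- code_food_security(df)
  expect_equal(fs$worried_food, c(1L, NA, 0L))
  expect_equal(fs$skipped_meal, c(0L, NA, 1L))
  expect_equal(fs$whole_day_no_food, c(0L, NA, 1L))

  cp <- code_crop_production(c("decreased", "does_not_farm", NA, "unchanged"))
  expect_equal(levels(cp), c("unchanged", "decreased", "increased",
                             "does_not_farm"))
  expect_equal(as.character(cp), c("decreased", "does_not_farm", NA,
                                   "unchanged"))
  expect_error(code_crop_production("abandoned"),
               class = "dietshock_coding_error")
})

test_that("missing-indicator encoding matches the method's definition", {
  df <- make_blank_survey(20)
  df <- score_survey(df, CB)
  df$education[1:5] <- NA
  terms <- default_model_terms()[c("education", "household_size")]
  d <- encode_with_missing_indicators(df, terms, "dds")
  expect_true("education_missing" %in% colnames(d$X))
  expect_equal(sum(d$X[, "education_missing"]), 5)
  # missing rows contribute no level dummy
  expect_true(all(d$X[1:5, grep("^education_(none|secondary)",
                                colnames(d$X))] == 0))
})

test_that("no missingness gives plain reference coding", {
  df <- score_survey(make_blank_survey(10), CB)
  df$education <- rep(c("none_incomplete_primary", "secondary_or_higher",
                        "primary_incomplete_secondary"), length.out = 10)
  d <- encode_with_missing_indicators(
    df, default_model_terms()["education"], "dds")
  expect_setequal(colnames(d$X),
                  c("(intercept)", "education_none_incomplete_primary",
                    "education_secondary_or_higher"))
})

test_that("continuous terms are mean-imputed with an indicator", {
  df <- score_survey(make_blank_survey(6), CB)
  df$household_size <- c(2L, 4L, 6L, 8L, 10L, NA)
  d <- encode_with_missing_indicators(
    df, default_model_terms()["household_size"], "dds")
  expect_equal(unname(d$X[6, "household_size"]), 6)  # mean of observed
  expect_equal(unname(d$X[, "household_size_missing"]), c(0, 0, 0, 0, 0, 1))
})

test_that("outcome-missing rows are dropped and counted, never imputed", {
  df <- score_survey(make_blank_survey(8), CB)
  df$fg_legumes_during[c(2, 5)] <- NA   # incomplete -> NA outcome
  df <- score_survey(df[, survey_schema(CB)$column], CB)
  d <- encode_with_missing_indicators(df, default_model_terms()["age_band"],
                                      "dds")
  expect_equal(length(d$y), 6)
  expect_equal(d$n_dropped_outcome, 2L)
  expect_equal(length(d$y) + d$n_dropped_outcome, 8L)
  expect_false(anyNA(d$X))
})

test_that("unknown term fields raise a spec error", {
  df <- score_survey(make_blank_survey(3), CB)
  bad <- list(shoe_size = term_spec("shoe_size", "continuous"))
  expect_error(encode_with_missing_indicators(df, bad, "dds"),
               class = "dietshock_spec_error")
  expect_error(encode_with_missing_indicators(make_blank_survey(3),
                                              outcome = "dds"),
               class = "dietshock_spec_error")  # unscored records
})
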