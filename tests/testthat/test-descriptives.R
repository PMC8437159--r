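test_that("single-record input puts 100% in its categories", {
  df <- make_blank_survey(1)
  tab <- characteristics_table(df)$frequencies
  male <- tab[tab$variable == "respondent_sex" & tab$stratum == "overall", ]
  expect_equal(male$pct[male$category == "male"], 100)
  expect_equal(male$count[male$category == "female"], 0)
  expect_error(characteristics_table(df[0, ]), class = "dietshock_spec_error")
})

test_that("all-missing variables report denominator 0 and undefined pct", {
  df <- make_blank_survey(4)
  df$respondent_sex <- NA_character_
  tab <- characteristics_table(df)$frequencies
  sex <- tab[tab$variable == "respondent_sex" & tab$stratum == "overall", ]
  expect_true(all(sex$denominator == 0))
  expect_true(all(is.na(sex$pct)))
})

test_that("percentages recompute from their own counts and denominators", {
  rec <- generate_survey(small_config(80))$records
  rec <- inject_missingness(rec, default_missingness(), 9L)
  for (tab in list(price_change_table(rec),
                   characteristics_table(rec)$frequencies)) {
    ok <- tab$denominator > 0
    expect_equal(tab$pct[ok],
                 round_half_up(100 * tab$count[ok] / tab$denominator[ok], 1))
    # denominator bookkeeping: counts across categories sum to non-missing N
    agg <- stats::aggregate(count ~ variable + stratum, tab, sum)
    den <- unique(tab[, c("variable", "stratum", "denominator")])
    m <- merge(agg, den)
    expect_equal(m$count, m$denominator)
  }
})

test_that("consumption change summary matches a hand tabulation", {
  df <- make_blank_survey(20)
  # legumes: 8 decrease (5 -> 2), 7 unchanged (3 -> 3), 5 increase (1 -> 4)
  df <- set_days(df, "before", legumes = c(rep(5L, 8), rep(3L, 7), rep(1L, 5)))
  df <- set_days(df, "during", legumes = c(rep(2L, 8), rep(3L, 7), rep(4L, 5)))
  cs <- consumption_change_summary(df, "mddw", CB)
  leg <- cs[cs$group == "legumes" & cs$stratum == "overall", ]
  expect_equal(leg$n, 20L)
  expect_equal(leg$pct_decreased, 40)
  expect_equal(leg$pct_unchanged, 35)
  expect_equal(leg$pct_increased, 25)
  # the three shares always sum to 100 within rounding
  done <- cs[cs$n > 0, ]
  expect_true(all(abs(done$pct_decreased + done$pct_unchanged +
                        done$pct_increased - 100) <= 0.15))
})

test_that("change summary degenerates correctly and masks apply", {
  df <- make_blank_survey(5, "kersa")
  df <- set_days(df, "before", legumes = 4L, fish = 2L)
  df <- set_days(df, "during", legumes = 2L, fish = 1L)
  cs <- consumption_change_summary(df, "mddw", CB)
  moved <- cs[cs$group %in% c("legumes", "meat_poultry_fish"), ]
  expect_true(all(moved$pct_decreased == 100))
  still <- cs[cs$group == "eggs", ]
  expect_true(all(still$pct_unchanged == 100))
  # Kersa's masked group has no denominator
  expect_true(all(cs$n[cs$group == "other_vit_a_fruit_veg"] == 0))
})

test_that("score summaries match hand-computed mean/SD and median/IQR", {
  df <- make_blank_survey(5)
  df <- score_survey(df, CB)
  df$dds_before <- df$dds_during <- c(0L, 1L, 2L, 3L, 4L)
  df$pdqs_before <- df$pdqs_during <- c(10L, 12L, 14L, 18L, 20L)
  s <- mean_scores_before_during(df)
  ov <- s[s$stratum == "overall" & s$period == "before", ]
  expect_equal(ov$dds_mean, 2)
  expect_equal(ov$dds_sd, sd(0:4))
  expect_equal(ov$pdqs_median, 14)
  expect_equal(ov$pdqs_q1, 12)
  expect_equal(ov$pdqs_q3, 18)
  # identical before/during frequencies give identical summaries
  before <- s[s$period == "before", -2]
  during <- s[s$period == "during", -2]
  rownames(before) <- rownames(during) <- NULL
  expect_equal(before, during)
  expect_error(mean_scores_before_during(make_blank_survey(2)),
               class = "dietshock_spec_error")
})
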