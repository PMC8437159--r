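test_that("MDD-W mapping aggregates constituent days per the configured rule", {
  # other_veg group = {cruciferous_veg, other_veg}: max(3, 5) = 5
  d <- days_vec(cruciferous_veg = 3, other_veg = 5)
  prof <- map_to_mddw_groups(d, CB)
  expect_equal(unname(prof["other_veg"]), 5)
  # sum capped at 7: 4 + 5 -> 7
  prof2 <- map_to_mddw_groups(days_vec(cruciferous_veg = 4, other_veg = 5),
                              CB, options = scoring_options(aggregator = "sum_capped"))
  expect_equal(unname(prof2["other_veg"]), 7)
  # all-zero frequencies give an all-zero profile
  expect_true(all(map_to_mddw_groups(days_vec(), CB) == 0))
  # unknown group id is a codebook error
  expect_error(map_to_mddw_groups(c(days_vec(), pizza = 3), CB),
               class = "dietshock_codebook_error")
})

test_that("DDS follows the daily-consumption rule with its printed range", {
  all7 <- stats::setNames(rep(7, 20), CB$survey_groups$id)
  expect_equal(compute_dds(map_to_mddw_groups(all7, CB))$dds, 10L)
  expect_equal(compute_dds(map_to_mddw_groups(days_vec(), CB))$dds, 0L)
  # 6/7 days is below "at least once each day": only the 7-day group counts
  d <- days_vec(legumes = 7, dark_green_leafy_veg = 6)
  expect_equal(compute_dds(map_to_mddw_groups(d, CB))$dds, 1L)
  # threshold is configurable: a 1-day rule counts both
  opt <- scoring_options(dds_days_threshold = 1)
  expect_equal(compute_dds(map_to_mddw_groups(d, CB), options = opt)$dds, 2L)
})

test_that("PDQS point rules match the published scoring bands", {
  zero <- map_to_pdqs_groups(days_vec(), CB)
  expect_equal(compute_pdqs(zero, CB)$pdqs, 12L)  # 14x0 + 6x2
  best <- days_vec()
  best[CB$survey_groups$id[CB$survey_groups$pdqs_healthy]] <- 7
  expect_equal(compute_pdqs(map_to_pdqs_groups(best, CB), CB)$pdqs, 40L)
  two <- stats::setNames(rep(2, 20), CB$survey_groups$id)
  expect_equal(compute_pdqs(map_to_pdqs_groups(two, CB), CB)$pdqs, 20L)
  # maize-flour products are scored as refined grains (unhealthy): 4 days -> 0 pts
  mf <- map_to_pdqs_groups(days_vec(refined_grains = 4), CB)
  expect_equal(unname(mf["refined_grains"]), 4)
  expect_equal(unname(compute_pdqs(mf, CB)$points["refined_grains"]), 0L)
})

test_that("site masks exclude groups without rescaling", {
  d <- days_vec(other_vit_a_fruit_veg = 7, legumes = 7)
  kersa_mask <- dietshock:::site_mask(CB, "kersa")
  prof <- map_to_mddw_groups(d, CB, masked = kersa_mask)
  expect_equal(attr(prof, "excluded"), "other_vit_a_fruit_veg")
  dds <- compute_dds(prof, masked = attr(prof, "excluded"))
  expect_equal(dds$dds, 1L)  # only legumes counts at Kersa
  expect_equal(unname(dds$contributions["other_vit_a_fruit_veg"]), 0L)

  serv <- map_to_pdqs_groups(d, CB, masked = kersa_mask)
  pd <- compute_pdqs(serv, CB, masked = attr(serv, "excluded"))
  expect_equal(pd$max_attainable, 38L)  # 2 x 19, no rescaling
})

test_that("consumption change classifies per group with indeterminate NAs", {
  before <- days_vec(legumes = 5, fish = 2)
  during <- days_vec(legumes = 3, fish = 2, eggs = 4)
  ch <- classify_consumption_change(before, during, "mddw", CB)
  expect_equal(unname(ch["legumes"]), "decreased")
  expect_equal(unname(ch["meat_poultry_fish"]), "unchanged")
  expect_equal(unname(ch["eggs"]), "increased")
  before[["legumes"]] <- NA
  ch2 <- classify_consumption_change(before, during, "mddw", CB)
  expect_equal(unname(ch2["legumes"]), "indeterminate")
})

test_that("score_survey appends scores, applies masks per site, flags gaps", {
  df <- rbind(make_blank_survey(2, "nouna"), make_blank_survey(2, "kersa"))
  df <- set_days(df, "during", other_vit_a_fruit_veg = 7L)
  df$fg_legumes_during[2] <- NA  # incomplete during period, nouna row 2
  out <- score_survey(df, CB)
  expect_equal(out$dds_during[1], 1L)   # nouna: group counts
  expect_equal(out$dds_during[3], 0L)   # kersa: group masked
  expect_true(is.na(out$dds_during[2]) && !out$complete_during[2])
  expect_true(all(out$complete_before))
  expect_true(all(out$dds_before == 0L))
  # masked NA does not disqualify completeness at the masking site
  df2 <- make_blank_survey(1, "kersa")
  df2$fg_other_vit_a_fruit_veg_during <- NA
  expect_true(score_survey(df2, CB)$complete_during)
})

test_that("scores are monotone in the published directions", {
  set.seed(4821)
  sg <- CB$survey_groups
  for (i in 1:40) {
    days <- stats::setNames(sample(0:7, 20, replace = TRUE), sg$id)
    g <- sample(sg$id, 1)
    bumped <- days
    bumped[[g]] <- min(7, bumped[[g]] + sample(1:3, 1))
    dds0 <- compute_dds(map_to_mddw_groups(days, CB))$dds
    dds1 <- compute_dds(map_to_mddw_groups(bumped, CB))$dds
    expect_gte(dds1, dds0)
    p0 <- compute_pdqs(map_to_pdqs_groups(days, CB), CB)$pdqs
    p1 <- compute_pdqs(map_to_pdqs_groups(bumped, CB), CB)$pdqs
    if (sg$pdqs_healthy[sg$id == g]) expect_gte(p1, p0) else expect_lte(p1, p0)
    # masking a group never increases the DDS
    m <- sample(sg$id, 1)
    mm <- dietshock:::masked_mddw_groups(CB, m)
    dds_m <- compute_dds(map_to_mddw_groups(days, CB, masked = m),
                         masked = mm)$dds
    expect_lte(dds_m, dds0)
  }
})
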