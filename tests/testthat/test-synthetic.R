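test_that("generator produces the configured number of valid households", {
  cfg <- small_config(25)
  gen <- generate_survey(cfg)
  expect_equal(nrow(gen$records), 150L)
  expect_equal(nrow(validate_survey(gen$records, CB)), 0L)
  expect_equal(as.vector(table(gen$records$site)[SITES]), rep(25L, 6))
  # truth record carries what the oracle needs
  expect_named(gen$truth$site_effects, SITES)
  expect_identical(gen$truth$config$seed, cfg$seed)
})

test_that("same seed gives identical datasets; different seeds differ", {
  cfg <- small_config(40)
  g1 <- generate_survey(cfg)
  g2 <- generate_survey(cfg)
  expect_identical(g1$records, g2$records)
  expect_identical(g1$truth$site_effects, g2$truth$site_effects)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  expect_false(identical(generate_survey(cfg2)$records, g1$records))
})

test_that("observed exposure prevalence tracks the configured value", {
  pi <- default_price_increase()
  pi[, "staples"] <- 0.90
  cfg <- synthetic_config(price_increase = pi,
                          missingness = c(price_staples = 0), seed = 2024L)
  rec <- generate_survey(cfg)$records  # n = 1800
  obs <- mean(rec$price_staples == "increased")
  expect_lt(abs(obs - 0.90), 3 * sqrt(0.9 * 0.1 / 1800))  # within 3 binomial SEs
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(site_sd = -1),
               class = "dietshock_config_error")
  expect_error(synthetic_config(overdispersion = 1),
               class = "dietshock_config_error")
  expect_error(synthetic_config(effects = list(lottery_win = c(fish = 1))),
               class = "dietshock_config_error")
  expect_error(synthetic_config(effects = list(price_asf = c(pizza = -1))),
               class = "dietshock_config_error")
  pi <- default_price_increase()
  pi[1, 1] <- 1.2
  expect_error(synthetic_config(price_increase = pi),
               class = "dietshock_config_error")
})

test_that("inject_missingness hits per-field rates and spares outcomes", {
  cfg <- small_config(300)
  rec <- generate_survey(cfg)$records  # n = 1800, no missingness
  expect_identical(inject_missingness(rec, c(education = 0), 5L), rec)
  all_gone <- inject_missingness(rec, c(education = 1), 5L)
  expect_true(all(is.na(all_gone$education)))
  some <- inject_missingness(rec, c(age_band = 0.1), 5L)
  n_miss <- sum(is.na(some$age_band))
  expect_lt(abs(n_miss - 180), 3 * sqrt(1800 * 0.1 * 0.9))
  expect_error(inject_missingness(rec, c(age_band = 1.5), 5L),
               class = "dietshock_config_error")
  expect_error(inject_missingness(rec, c(fg_legumes_during = 0.5), 5L),
               class = "dietshock_config_error")
})

test_that("the implied-effect oracle is null-consistent and monotone", {
  null_cfg <- synthetic_config(effects = list(), during_drift = 0)
  orc <- implied_effect_oracle(null_cfg, "price_pulses", "dds",
                               n_mc = 4000L, seed = 11L)
  expect_lt(abs(orc$effect), 4 * orc$se)

  up_cfg <- synthetic_config(effects = list(price_pulses = c(legumes = 0.8)),
                             during_drift = 0)
  orc_up <- implied_effect_oracle(up_cfg, "price_pulses", "dds",
                                  n_mc = 4000L, seed = 11L)
  expect_gt(orc_up$effect, 3 * orc_up$se)  # positive shift, positive effect

  expect_error(implied_effect_oracle(null_cfg, "meteor_strike", "dds"),
               class = "dietshock_key_error")
  expect_error(implied_effect_oracle(null_cfg, "price_pulses", "dds",
                                     n_mc = 10L),
               class = "dietshock_config_error")
})

test_that("Monte-Carlo SE shrinks like one over root n", {
  cfg <- synthetic_config(effects = list(price_pulses = c(legumes = -0.8)),
                          during_drift = 0)
  s1 <- implied_effect_oracle(cfg, "price_pulses", "dds", n_mc = 2000L,
                              seed = 21L)
  s4 <- implied_effect_oracle(cfg, "price_pulses", "dds", n_mc = 8000L,
                              seed = 22L)
  ratio <- s1$se / s4$se  # quadrupling n should halve the SE
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})
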