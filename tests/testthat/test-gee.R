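# The frozen expected values below were computed once with an independent
# reference implementation of Gaussian exchangeable GEE (robust sandwich
# covariance) on exactly this deterministically generated fixture.

gee_fixture <- function() {
  set.seed(99)
  n <- 120
  cl <- rep(paste0("c", 1:6), each = 20)
  u <- rnorm(6, 0, 0.5)[rep(1:6, each = 20)]
  x1 <- rbinom(n, 1, 0.5)
  x2 <- round(rnorm(n), 3)
  y <- round(1 + 0.5 * x1 - 0.3 * x2 + u + rnorm(n), 3)
  list(y = y, X = cbind(`(intercept)` = 1, x1 = x1, x2 = x2), cluster = cl)
}

test_that("exchangeable GEE reproduces the frozen reference fit", {
  fit <- fit_gee_linear(gee_fixture())
  co <- fit$coefficients
  expect_equal(co$estimate, c(0.7200129957, 1.1370734764, -0.4815791210),
               tolerance = 1e-6)
  expect_equal(co$se, c(0.1557722092, 0.1329483860, 0.0981846926),
               tolerance = 1e-5)
  expect_equal(fit$alpha, 0.0120983357, tolerance = 1e-5)
  expect_true(fit$converged)
  expect_equal(fit$n_clusters, 6L)
})

test_that("one observation per cluster degenerates to OLS", {
  set.seed(7)
  n <- 40
  X <- cbind(`(intercept)` = 1, x = rnorm(n))
  y <- 2 + 0.7 * X[, 2] + rnorm(n)
  fit <- fit_gee_linear(list(y = y, X = X, cluster = paste0("h", 1:n)))
  ols <- unname(coef(lm(y ~ X[, 2])))
  expect_equal(fit$coefficients$estimate, ols, tolerance = 1e-10)
  expect_equal(fit$alpha, 0)
})

test_that("fixed alpha = 0 equals the independence fit exactly", {
  fx <- gee_fixture()
  f0 <- fit_gee_linear(fx, correlation = "independence")
  ff <- fit_gee_linear(fx, fixed_alpha = 0)
  expect_equal(ff$coefficients$estimate, f0$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(ff$coefficients$se, f0$coefficients$se, tolerance = 1e-12)
  expect_equal(f0$coefficients$estimate,
               unname(coef(lm(fx$y ~ fx$X[, -1]))), tolerance = 1e-10)
})

test_that("on zero-correlation data the estimated alpha is near zero", {
  cfg <- small_config(150, site_sd = 0, overdispersion = 0,
                      effects = list(), during_drift = 0)
  rec <- score_survey(generate_survey(cfg)$records, CB)
  d <- encode_with_missing_indicators(rec, default_model_terms()["price_pulses"],
                                      "dds")
  fit <- fit_gee_linear(d)
  # alpha is moment noise of order 1/sqrt(N) around its true value 0
  expect_lt(abs(fit$alpha), 4 / sqrt(fit$n))
})

test_that("degenerate designs raise instructive errors", {
  fx <- gee_fixture()
  one <- list(y = fx$y, X = fx$X, cluster = rep("only", length(fx$y)))
  expect_error(fit_gee_linear(one), "independence",
               class = "dietshock_model_error")
  zv <- fx
  zv$X <- cbind(zv$X, flat = 0)
  expect_error(fit_gee_linear(zv), "flat", class = "dietshock_model_error")
  coll <- fx
  coll$X <- cbind(coll$X, dup = coll$X[, "x1"])
  expect_error(fit_gee_linear(coll), "rank",
               class = "dietshock_model_error")
})

test_that("p-values and CI ordering honor the result contract", {
  set.seed(31)
  for (i in 1:5) {
    n <- 90
    X <- cbind(`(intercept)` = 1, a = rnorm(n), b = rbinom(n, 1, 0.4))
    y <- rnorm(n)
    fit <- fit_gee_linear(list(y = y, X = X,
                               cluster = sample(paste0("c", 1:6), n, TRUE)))
    co <- fit$coefficients
    expect_true(all(co$p >= 0 & co$p <= 1))
    expect_true(all(co$ci_low <= co$estimate & co$estimate <= co$ci_high))
    expect_equal(co$ci_high - co$estimate, 1.96 * co$se, tolerance = 1e-10)
  }
})

test_that("univariate screen keeps candidates below alpha plus forced terms", {
  cfg <- small_config(120, effects = list(), during_drift = 0)
  rec <- score_survey(generate_survey(cfg)$records, CB)
  scr <- univariate_screen(rec, "dds", alpha = 0.20)
  expect_true(all(c(paste0("price_", c("staples", "pulses", "fruits",
                                       "vegetables", "asf")),
                    "crop_production", "household_size") %in% scr$selected))
  cands <- scr$screen[scr$screen$role == "candidate", ]
  expect_equal(cands$kept, cands$p < 0.20)
  # screen is deterministic: same data in, same set out
  scr2 <- univariate_screen(rec, "dds", alpha = 0.20)
  expect_identical(scr$selected, scr2$selected)
  # all-missing candidate is excluded with a warning
  rec2 <- rec
  rec2$worried_food <- NA_character_
  expect_warning(scr3 <- univariate_screen(rec2, "dds"),
                 "worried_food")
  expect_false("worried_food" %in% scr3$selected)
})

test_that("build_and_fit assembles per the published model-building rules", {
  cfg <- small_config(100, effects = list(), during_drift = 0)
  rec <- score_survey(generate_survey(cfg)$records, CB)
  res <- build_and_fit(rec, model_spec("dds", "combined"))
  mv <- res$results[res$results$model == "multivariate", ]
  expect_true(all(paste0("price_", c("staples", "pulses", "fruits",
                                     "vegetables", "asf")) %in% mv$term))
  expect_true(all(c("crop_production", "household_size") %in% mv$term))
  kept <- res$screens$combined$term[res$screens$combined$kept]
  expect_setequal(setdiff(unique(mv$term), "(intercept)"), kept)

  # per-country scope: one result set per country, both sites required
  pc <- build_and_fit(rec, model_spec("dds", "per_country"))
  expect_setequal(unique(pc$results$scope),
                  c("burkina_faso", "ethiopia", "nigeria"))
  expect_error(build_and_fit(rec[rec$site == "nouna", ],
                             model_spec("dds", "per_country")),
               class = "dietshock_model_error")
})

test_that("results_report renders the published estimate/CI/star format", {
  df <- data.frame(scope = "combined", outcome = "dds",
                   model = "multivariate", term = "price_vegetables",
                   level = "increased", estimate = 0.224, se = 0.074,
                   ci_low = 0.079, ci_high = 0.369, p = 0.004,
                   n = 1797, n_clusters = 6, stringsAsFactors = FALSE)
  rep <- results_report(df)
  cell <- rep$multivariate[rep$level == "increased"]
  expect_equal(cell, "0.22 (0.08 to 0.37)**")
  expect_equal(rep$multivariate[rep$level == "no_change_or_decreased"], "ref")
  df$p <- 0.06
  rep2 <- results_report(df)
  expect_equal(rep2$multivariate[rep2$level == "increased"],
               "0.22 (0.08 to 0.37)")  # no star at p = 0.06
})
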