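test_that("the odds-ratio tilt matches its closed form", {
  got <- shift_category_probs(rep(0.25, 4), c(1.2, 1.5, 2.0))
  expect_equal(got, c(1, 1.2, 1.5, 2.0) / 5.7, tolerance = 1e-12)

  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(shift_category_probs(p, c(1, 1, 1)), p)
  expect_equal(shift_category_probs(c(1, 0, 0, 0), c(9, 5, 7)), c(1, 0, 0, 0))
  expect_equal(shift_category_probs(p, NULL), p)

  set.seed(71)
  for (i in 1:50) {
    p <- as.numeric(stats::rgamma(4, 1)); p <- p / sum(p)
    th <- stats::rexp(3) + 0.1
    direct <- p * c(1, th) / sum(p * c(1, th))
    expect_equal(shift_category_probs(p, th), direct, tolerance = 1e-12)
  }
  expect_error(shift_category_probs(p, c(1, 2, Inf)), "finite positive")
  expect_error(shift_category_probs(p, c(1, 2)), "finite positive")
})

test_that("mean shifting is a translation", {
  expect_equal(shift_mean(5, 0), 5)
  x <- rnorm(10)
  expect_equal(shift_mean(x + 2, 0.7), shift_mean(x, 0.7) + 2)
})

test_that("a large pmm shift concentrates imputations at the top of the support", {
  # toy grid: the predictor tracks the true value, so predictions separate
  # the support and a big upward shift matches only the top donors
  set.seed(72)
  y_obs <- as.numeric(sample(0:3, 500, replace = TRUE))
  y <- c(y_obs, rep(NA, 500))
  X <- cbind(1, c(y_obs, sample(0:3, 500, replace = TRUE)) + rnorm(1000, sd = 0.1))
  out <- pmm_impute_variable(y, X, delta = 50)
  expect_gt(mean(out[is.na(y)] == 3), 0.95)
})

test_that("the four printed scenarios carry the published odds ratios", {
  sc <- built_in_scenarios()
  expect_length(sc, 4)
  expect_equal(sc[[1]]$theta_negative, c(1.2, 1.5, 2.0))
  expect_equal(sc[[1]]$theta_positive, c(1.2, 1.5, 2.0))
  expect_equal(sc[[2]]$theta_positive, c(1.5, 2.0, 2.5))
  expect_equal(sc[[3]]$theta_negative, c(2.0, 3.0, 5.0))
  expect_equal(sc[[3]]$theta_positive, c(3.0, 5.0, 8.0))
  expect_equal(sc[[4]]$theta_negative, c(4.0, 6.0, 10.0))
  expect_equal(sc[[4]]$theta_positive, c(6.0, 10.0, 15.0))
  for (s in sc) {
    expect_true(all(diff(s$theta_negative) >= 0))
    expect_true(all(diff(s$theta_positive) >= 0))
  }
})

test_that("scenario validation rejects malformed parameters", {
  expect_error(mnar_scenario("x", theta_negative = c(1, 2)), "3 finite positive")
  expect_error(mnar_scenario("x", theta_negative = c(1, 2, -1)), "finite positive")
  expect_error(mnar_scenario("x", delta = rep(0, 5)), "length-20")
})

test_that("the identity scenario reproduces the ignorable run bit-for-bit", {
  co <- small_complete_cohort(n = 300)
  gm <- generate_missingness(co, missingness_spec("MAR"), seed = 73)
  spec <- build_model("items_parsimonious", method = "polyreg", m = 2,
                      n_iter = 2)
  ign <- mice_run(gm$cohort, spec, seed = 74)
  id <- mice_run(gm$cohort, spec, scenario = mnar_scenario("identity"),
                 seed = 74)
  expect_identical(ign$datasets, id$datasets)
})

test_that("tilting touches only rows with missing cells", {
  co <- small_complete_cohort(n = 250)
  gm <- generate_missingness(co, missingness_spec("MCAR"), seed = 75)
  obs_mask <- !gm$mask
  spec <- build_model("items_parsimonious", method = "polyreg", m = 2,
                      n_iter = 2)
  sets <- mice_run(gm$cohort, spec,
                   scenario = built_in_scenarios()[[4]], seed = 76)
  for (d in sets$datasets) {
    expect_identical(item_matrix(d)[obs_mask], gm$truth[obs_mask])
  }
})

test_that("sensitivity_run reports every scenario-stratum cell and nests the ignorable run", {
  co <- small_complete_cohort(n = 300)
  gm <- generate_missingness(co, missingness_spec("MAR"), seed = 77)
  spec <- build_model("items_parsimonious", method = "polyreg", m = 2,
                      n_iter = 2)
  scns <- c(list(mnar_scenario("ignorable")), built_in_scenarios()[1])
  rep_tab <- sensitivity_run(gm$cohort, spec, scenarios = scns, seed = 78,
                             strata = c(10, 20))
  expect_equal(nrow(rep_tab), 2 * 2)
  ign <- pooled_summary(mice_run(gm$cohort, spec, seed = 78),
                        subset = rowSums(gm$mask) <= 20)
  expect_equal(rep_tab$pct_hds[rep_tab$scenario == "ignorable" &
                                 rep_tab$max_mv == 20], ign$pct_hds)
  expect_error(sensitivity_run(gm$cohort,
                               build_model("score_pmm",
                                           covariates = covariate_cols()),
                               scenarios = scns, seed = 1), "item-level")
})
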