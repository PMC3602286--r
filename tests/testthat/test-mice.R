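test_that("model structures enumerate the documented predictor sets", {
  p1 <- build_model("items_parsimonious")
  expect_equal(unname(rowSums(p1$predictors)), rep(19, 20))
  expect_true(all(p1$methods == "pmm"))

  p2 <- build_model("items_full", method = "polyreg",
                    covariates = covariate_cols())
  expect_equal(unname(rowSums(p2$predictors)), rep(19 + 17, 20))

  p3 <- build_model("score_pmm", covariates = covariate_cols())
  expect_equal(rownames(p3$predictors), "cesd_score")
  expect_equal(sum(p3$predictors), 17)

  p4 <- build_model("status_logreg", covariates = covariate_cols())
  expect_equal(p4$methods, c(hds = "logreg"))

  expect_error(build_model("bogus"), "arg")
  expect_error(build_model("score_pmm"), "covariate block")
})

test_that("the spec constructor enforces its invariants", {
  pm <- matrix(TRUE, 1, 1, dimnames = list("a", "b"))
  expect_error(imputation_spec(c(a = "pmm"), pm, m = 1), "at least 2")
  expect_error(imputation_spec(c(a = "magic"), pm), "unknown imputation")
  self <- matrix(TRUE, 1, 1, dimnames = list("a", "a"))
  expect_error(imputation_spec(c(a = "pmm"), self), "predict itself")
})

test_that("a cohort with no missing cells passes through unchanged", {
  co <- small_complete_cohort(n = 120)
  spec <- build_model("items_parsimonious", m = 2, n_iter = 2)
  sets <- mice_run(co, spec, seed = 51)
  expect_length(sets$datasets, 2)
  expect_identical(sets$datasets[[1]], co)
  expect_identical(sets$datasets[[2]], co)
})

test_that("observed cells survive imputation bit-for-bit and support is preserved", {
  co <- small_complete_cohort(n = 250)
  amp <- ampute_mcar(co, k = 4, seed = 52)
  obs_mask <- !is.na(item_matrix(amp))
  spec <- build_model("items_parsimonious", m = 3, n_iter = 3)
  sets <- mice_run(amp, spec, seed = 53)
  for (d in sets$datasets) {
    m <- item_matrix(d)
    expect_false(anyNA(m))
    expect_identical(m[obs_mask], item_matrix(amp)[obs_mask])
    expect_true(all(m %in% 0:3))
  }
})

test_that("identical seeds reproduce the completed sets exactly", {
  co <- small_complete_cohort(n = 200)
  amp <- ampute_mcar(co, k = 3, seed = 54)
  spec <- build_model("items_parsimonious", method = "polyreg", m = 2,
                      n_iter = 2)
  a <- mice_run(amp, spec, seed = 55)
  b <- mice_run(amp, spec, seed = 55)
  c2 <- mice_run(amp, spec, seed = 56)
  expect_identical(a$datasets, b$datasets)
  expect_false(identical(a$datasets, c2$datasets))
})

test_that("degenerate inputs are rejected with clear errors", {
  co <- small_complete_cohort(n = 80)
  co$item_01 <- NA_real_
  spec <- build_model("items_parsimonious", m = 2, n_iter = 1)
  expect_error(mice_run(co, spec, seed = 57), "no observed values")
  expect_error(mice_run(co, spec, seed = NULL), "seed")

  co2 <- small_complete_cohort(n = 80)
  co2$item_02[1:5] <- NA
  spec2 <- spec
  spec2$methods["item_02"] <- "none"
  expect_error(mice_run(co2, spec2, seed = 58), "method 'none'")
})

test_that("the trace records one mean/sd per target, iteration and chain", {
  co <- small_complete_cohort(n = 150)
  amp <- ampute_mcar(co, k = 2, fraction = 0.5, seed = 59)
  spec <- build_model("items_parsimonious", m = 2, n_iter = 4)
  sets <- mice_run(amp, spec, seed = 60)
  tr <- sets$trace[[1]]
  n_targets <- sum(colSums(is.na(item_matrix(amp))) > 0)
  expect_equal(dim(tr), c(4, n_targets, 2))
  expect_false(anyNA(tr))
})
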