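test_that("cohort generation is seed-deterministic and validates parameters", {
  a <- generate_cohort(150, seed = 91)
  b <- generate_cohort(150, seed = 91)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(150, seed = 92)))
  expect_equal(dim(item_matrix(a)), c(150, 20))
  expect_true(all(covariate_cols() %in% names(a)))
  expect_length(covariate_cols(), 17)

  bad_th <- default_thresholds(); bad_th[3, ] <- c(1, 1, 1)
  expect_error(generate_cohort(10, thresholds = bad_th), "strictly increasing")
  expect_error(generate_cohort(10, loadings = rep(-1, 20)), "positive")
})

test_that("near-zero loadings destroy internal consistency", {
  co <- generate_cohort(800, loadings = rep(1e-4, 20), seed = 93)
  expect_lt(abs(cronbach_alpha(co)), 0.15)
})

test_that("missingness mechanisms behave as declared", {
  co <- small_complete_cohort(n = 1500)
  s <- score_total(co)

  none <- generate_missingness(co, missingness_spec("MCAR",
                                                    overall_fraction = 0),
                               seed = 94)
  expect_false(any(none$mask))
  expect_identical(none$cohort, co)

  mcar <- generate_missingness(co, missingness_spec("MCAR"), seed = 95)
  hit <- rowSums(mcar$mask) > 0
  expect_equal(mean(hit), 0.448, tolerance = 0.01)
  expect_gt(stats::wilcox.test(s[hit], s[!hit])$p.value, 0.01)

  mar <- generate_missingness(co, missingness_spec("MAR", mar_drivers = "age",
                                                   mar_strength = 1.5),
                              seed = 96)
  hit_mar <- rowSums(mar$mask) > 0
  # selection odds rise with the driver, which is fully observed
  expect_gt(mean(co$age[hit_mar]), mean(co$age[!hit_mar]))

  mnar <- generate_missingness(co, missingness_spec("MNAR",
                                                    mnar_theta = c(2, 3, 5)),
                               seed = 97)
  # deleted cells carry systematically higher true categories
  expect_gt(mean(mnar$truth[mnar$mask]), mean(mnar$truth[!mnar$mask]) + 0.15)
  expect_error(generate_missingness(mnar$cohort, missingness_spec("MCAR"),
                                    seed = 1), "fully observed")
})

test_that("masks and truth reconstruct the generated cohort exactly", {
  co <- small_complete_cohort(n = 400)
  gm <- generate_missingness(co, missingness_spec("MNAR"), seed = 98)
  m <- item_matrix(gm$cohort)
  expect_true(all(is.na(m[gm$mask])))
  expect_identical(m[!gm$mask], gm$truth[!gm$mask])
  expect_identical(gm$truth, item_matrix(co))
})

test_that("the interview-study fixture carries the published counts", {
  fx <- fixture_table1()
  st <- fx$status
  expect_equal(sum(st[st$response == "complete", c("NhDS", "hDS")]), 149)
  expect_equal(sum(st[st$response == "incomplete",
                      c("NhDS", "hDS", "undetermined")]), 34)
  expect_equal(sum(st[c("NhDS", "hDS", "undetermined")]), 183)
  expect_equal(st$undetermined[st$response == "incomplete"], 8)
  expect_equal(sum(fx$q8_by_mv), 182)   # one MV-status pairing unrecorded
  expect_equal(sum(fx$q8_by_status), 146)
  expect_equal(fx$n_invited, 204)
})
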