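test_that("reverse coding flips positive items and is an involution", {
  # exhaustive enumeration over the response range in every positive slot
  m <- matrix(as.numeric(rep(0:3, each = 20)), ncol = 20, byrow = TRUE)
  flipped <- reverse_code(m)
  pos <- positive_items_default()
  neg <- setdiff(1:20, pos)
  expect_equal(flipped[, pos], 3 - m[, pos], ignore_attr = TRUE)
  expect_equal(flipped[, neg], m[, neg], ignore_attr = TRUE)
  expect_equal(reverse_code(flipped), m, ignore_attr = TRUE)

  withNA <- m
  withNA[2, 4] <- NA
  expect_true(is.na(reverse_code(withNA)[2, 4]))
  expect_error(reverse_code(m, positive_items = c(4, 8, 12, 21)), "1..20")
  expect_error(reverse_code(m + 3), "\\[0, 3\\]")
})

test_that("score_total sums complete rows and rejects missing cells", {
  expect_equal(score_total(matrix(0, 1, 20)), 0)
  expect_equal(score_total(matrix(3, 1, 20)), 60)
  expect_equal(score_total(matrix(c(rep(1, 10), rep(2, 10)), 1, 20)), 30)
  expect_error(score_total(matrix(c(NA, rep(1, 19)), 1, 20)), "complete")
})

test_that("score_total is permutation-invariant and monotone per item", {
  set.seed(5)
  for (i in 1:25) {
    row <- sample(0:3, 20, replace = TRUE)
    expect_equal(score_total(matrix(row, 1)), score_total(matrix(sample(row), 1)))
    j <- sample.int(20, 1)
    bumped <- row
    bumped[j] <- min(bumped[j] + 1, 3)
    expect_gte(score_total(matrix(bumped, 1)), score_total(matrix(row, 1)))
  }
})

test_that("the hDS cut-off is >= 16 with a strict lower side", {
  expect_equal(classify_hds(16), "hDS")
  expect_equal(classify_hds(15.99), "NhDS")
  expect_equal(classify_hds(0), "NhDS")
  expect_error(classify_hds(61), "\\[0, 60\\]")
})

test_that("classify_partial matches the stated bound arithmetic", {
  row <- function(obs, k) matrix(c(obs, rep(NA, k)), 1, 20)
  # observed sum already over the cut-off: minimum completion is hDS
  expect_equal(classify_partial(row(c(rep(2, 8), rep(0, 8)), 4)), "hDS")
  # observed 3 with 4 missing: maximum completion is 3 + 12 = 15 < 16
  expect_equal(classify_partial(row(c(3, rep(0, 15)), 4)), "NhDS")
  # observed 10 with 4 missing: completions span 10-22
  expect_equal(classify_partial(row(c(rep(1, 10), rep(0, 6)), 4)), "undetermined")
})

test_that("classify_partial equals brute force over all completions", {
  set.seed(11)
  for (i in 1:300) {
    k <- sample(0:6, 1)
    r <- random_partial_row(k)
    expect_equal(classify_partial(matrix(r, 1)), brute_force_status(r),
                 info = paste("k =", k))
  }
})

test_that("complete rows classify identically through both paths", {
  set.seed(12)
  m <- matrix(sample(0:3, 20 * 50, replace = TRUE), ncol = 20)
  expect_equal(classify_partial(m), unname(classify_hds(score_total(m))))
})

test_that("prevalence bounds reproduce the interview-study arithmetic", {
  b <- prevalence_bounds(14, 12, 8)
  expect_equal(round(b$low_pct, 1), 41.2)
  expect_equal(round(b$high_pct, 1), 64.7)
  expect_equal(b$denominator, 34)

  whole <- prevalence_bounds(59, 116, 8)
  expect_equal(round(whole$low_pct, 1), 32.2)
  expect_equal(round(whole$high_pct, 1), 36.6)

  no_und <- prevalence_bounds(7, 13, 0)
  expect_equal(no_und$low_pct, no_und$high_pct)
  expect_error(prevalence_bounds(0, 0, 0), "denominator")
  expect_error(prevalence_bounds(-1, 2, 0), "non-negative")
})

test_that("prevalence bounds agree with min/max imputation prevalences", {
  set.seed(13)
  m <- matrix(sample(c(0:3, NA), 20 * 200, replace = TRUE,
                     prob = c(rep(0.2, 4), 0.2)), ncol = 20)
  b <- prevalence_bounds_from_items(m)
  prev_min <- 100 * mean(score_total(impute_min(m)) >= 16)
  prev_max <- 100 * mean(score_total(impute_max(m)) >= 16)
  expect_equal(b$low_pct, prev_min)
  expect_equal(b$high_pct, prev_max)
})

test_that("add_derived exposes score and determined status consistently", {
  m <- rbind(
    c(rep(2, 20)),                       # complete, total 40
    c(rep(0, 19), NA),                   # max completion 3 < 16
    c(rep(1, 10), rep(NA, 10))           # undetermined
  )
  d <- as.data.frame(m)
  names(d) <- item_cols()
  out <- add_derived(d)
  expect_equal(out$cesd_score, c(40, NA, NA))
  expect_equal(out$hds, c(1L, 0L, NA))
})
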