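# Independent oracles used across test files.

# Brute-force status of a partially observed row: enumerate every possible
# completion of the missing items (4^k tuples) and classify each total.
brute_force_status <- function(row, cutoff = 16) {
  miss <- which(is.na(row))
  obs_sum <- sum(row[setdiff(seq_along(row), miss)])
  if (length(miss) == 0) {
    return(if (obs_sum >= cutoff) "hDS" else "NhDS")
  }
  grids <- rev(expand.grid(rep(list(0:3), length(miss))))
  totals <- obs_sum + rowSums(grids)
  if (all(totals >= cutoff)) "hDS"
  else if (all(totals < cutoff)) "NhDS"
  else "undetermined"
}

# A random 20-item row with n_missing missing cells.
random_partial_row <- function(n_missing) {
  row <- sample(0:3, 20, replace = TRUE)
  row[sample.int(20, n_missing)] <- NA
  row
}

# Small fully observed cohort shared by the imputation tests.
small_complete_cohort <- function(n = 400, seed = 99) {
  generate_cohort(n, seed = seed)
}
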