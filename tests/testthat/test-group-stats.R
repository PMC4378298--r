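make_null_pool <- function(n = 8, t_len = 237, seed0 = 500) {
  spec <- decoupled_band_spec()
  lapply(seq_len(n), function(i) {
    detrend_bandpass(simulate_var(spec, t_len, seed = seed0 + i,
                                  band_limited = TRUE))
  })
}

test_that("permutation thresholds are deterministic and monotone in alpha", {
  pool <- make_null_pool(6)
  t1 <- suppressWarnings(permutation_threshold(pool, c("x", "y"),
                                               n_perm = 200, seed = 7,
                                               order = 3))
  t2 <- suppressWarnings(permutation_threshold(pool, c("x", "y"),
                                               n_perm = 200, seed = 7,
                                               order = 3))
  expect_identical(as.numeric(t1), as.numeric(t2))
  t3 <- suppressWarnings(permutation_threshold(pool, c("x", "y"),
                                               n_perm = 200, seed = 8,
                                               order = 3))
  expect_false(identical(as.numeric(t1), as.numeric(t3)))

  lax <- permutation_threshold(pool, c("x", "y"), n_perm = 400,
                               alpha = 0.05, seed = 7, order = 3)
  expect_lte(as.numeric(lax), as.numeric(
    suppressWarnings(permutation_threshold(pool, c("x", "y"), n_perm = 400,
                                           alpha = 0.01, seed = 7, order = 3))
  ))
  expect_warning(
    permutation_threshold(pool, c("x", "y"), n_perm = 200, alpha = 0.01,
                          seed = 1, order = 3),
    "unstable"
  )
  expect_error(
    permutation_threshold(pool, c("x", "y"), n_perm = 200, alpha = 0,
                          seed = 1, order = 3),
    "alpha"
  )
})

test_that("a strongly coupled pair exceeds the whitening-permutation threshold", {
  spec <- two_region_spec(coef = 0.4, ar_self = 0.35)
  subs <- lapply(1:13, function(i) {
    detrend_bandpass(simulate_var(spec, 237, seed = 600 + i,
                                  band_limited = TRUE))
  })
  pool <- c(subs, make_null_pool(13, seed0 = 700))
  thr <- permutation_threshold(pool, c("x", "y"), n_perm = 1000,
                               alpha = 0.01, seed = 3, order = 3,
                               scheme = "full")
  group_mean <- mean(vapply(subs, function(s) {
    unname(pair_igc(s, c("x", "y"), order = 3)["forward"])
  }, numeric(1)))
  expect_gt(group_mean, as.numeric(thr))
})

test_that("percent difference and modulation follow their defining formulas", {
  expect_equal(percent_difference(1, 1), 0)
  expect_equal(percent_difference(0.5, 1.0), -50)
  expect_equal(percent_difference(0.03, 1.0), -97)
  expect_error(percent_difference(0.5, 0), "must be > 0")

  expect_equal(percent_modulation(0.1, 0.1), 0)
  expect_equal(percent_modulation(0.10, 0.05), 50)
  expect_equal(percent_modulation(0.05, 0.10), -100)
  expect_error(percent_modulation(0, 0.1), "nonzero")
  # identities for arbitrary positive flow
  for (x in c(0.01, 0.37, 2)) {
    expect_equal(percent_difference(x, x), 0)
    expect_equal(percent_modulation(x, x), 0)
  }
})

test_that("network and paired t tests match their classical forms", {
  r1 <- network_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r1$t, 0); expect_equal(r1$p, 1)

  r2 <- suppressWarnings(network_ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE))
  expect_equal(r2$t, 0); expect_equal(r2$p, 1)
  expect_error(network_ttest(c(1), c(1, 2)), "n >= 2")

  d <- paired_delta_ttest(c(1, -1))
  expect_equal(d$t, 0); expect_equal(d$p, 1)

  # one-sample equivalence: paired network test on (deltas, zeros)
  deltas <- c(4, 9, 9, 2, 2, 1, 0)
  a <- paired_delta_ttest(deltas)
  b <- network_ttest(deltas, rep(0, length(deltas)), paired = TRUE)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  expect_warning(paired_delta_ttest(rep(0, 5)), "degenerate")
})

test_that("the printed change scores reproduce the reported paired tests", {
  mppt <- c(4, 9, 9, 2, 2, 1, 0)
  mp <- c(6, 7, 10, 7, -2, 0)
  expect_lt(paired_delta_ttest(mppt)$p, 0.05)
  expect_gt(paired_delta_ttest(mp)$p, 0.05)
})

test_that("brain-behavior correlation matches the printed table and is affine invariant", {
  fma <- c(4, 9, 9, 2, 2, 1, 0)
  gc <- c(0.02, 0.02, 0.19, 0.02, -0.03, 0.00, -0.03)
  ct <- correlate_brain_behavior(fma, gc)
  expect_equal(round(ct$p, 2), 0.06)
  expect_equal(ct$r, 0.7258, tolerance = 1e-4)

  # affine rescaling leaves |r| and p unchanged
  ct2 <- correlate_brain_behavior(10 * fma - 3, -2 * gc + 1)
  expect_equal(abs(ct2$r), abs(ct$r), tolerance = 1e-12)
  expect_equal(ct2$p, ct$p, tolerance = 1e-12)

  col <- correlate_brain_behavior(1:5, 2 * (1:5) + 3)
  expect_equal(col$r, 1)
  expect_lt(col$p, 1e-10)

  expect_error(correlate_brain_behavior(1:3, rep(1, 3)), "zero variance")
  expect_error(correlate_brain_behavior(1:3, 1:4), "length")
})

test_that("clinical tables load, validate, and summarise as printed", {
  recs <- load_clinical_tables()
  expect_equal(nrow(recs), 13)
  expect_equal(round(mean(recs$age_years), 2), 59.23)
  expect_equal(max(recs$post_stroke_months), 54)
  expect_equal(min(recs$post_stroke_months), 1)
  expect_true(all(recs$mmse <= 30))
  expect_equal(sum(recs$intervention == "MP"), 6)
  expect_equal(sum(recs$intervention == "MPPT"), 7)
  expect_equal(sum(recs$sex == "M"), 9)

  bad <- tempfile(fileext = ".tsv")
  tab <- readr::read_tsv(system.file("extdata", "table1_demographics.tsv",
                                     package = "lfogcnet"),
                         show_col_types = FALSE)
  tab$mmse[4] <- NA
  readr::write_tsv(tab, bad)
  expect_error(load_clinical_tables(table1_path = bad), "row 4")
  tab$mmse[4] <- 31
  readr::write_tsv(tab, bad)
  expect_error(load_clinical_tables(table1_path = bad), "MMSE")
})
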