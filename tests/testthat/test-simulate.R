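test_that("a fully decoupled spec yields independent white noise", {
  spec <- network_spec(c("a", "b", "c"), ar_self = 0)
  s <- simulate_var(spec, 2000, seed = 1)
  m <- lfogcnet:::ts_matrix(s)
  for (j in 1:3) {
    ac1 <- cor(m[-1, j], m[-nrow(m), j])
    expect_lt(abs(ac1), 3 / sqrt(nrow(m)))
  }
  expect_lt(abs(cor(m[, 1], m[, 2])), 3 / sqrt(nrow(m)))
  expect_lt(max(abs(colMeans(m))), 3 / sqrt(nrow(m)))
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- two_region_spec(coef = 0.4, ar_self = 0.5)
  s1 <- simulate_var(spec, 300, seed = 42, band_limited = TRUE)
  s2 <- simulate_var(spec, 300, seed = 42, band_limited = TRUE)
  expect_identical(lfogcnet:::ts_matrix(s1), lfogcnet:::ts_matrix(s2))
  s3 <- simulate_var(spec, 300, seed = 43, band_limited = TRUE)
  expect_false(identical(lfogcnet:::ts_matrix(s1), lfogcnet:::ts_matrix(s3)))
})

test_that("sample cross-covariance matches the Lyapunov-equation oracle", {
  spec <- two_region_spec(coef = 0.4, ar_self = 0.5)
  a_mat <- lfogcnet:::coef_array(spec)[, , 1]
  p_cov <- lyapunov_cov(a_mat, diag(2))
  cc_true <- (a_mat %*% p_cov)[2, 1]  # cov(y_t, x_{t-1}); order (x, y)

  m <- lfogcnet:::ts_matrix(simulate_var(spec, 10000, seed = 4))
  cc_emp <- cov(m[-1, "y"], m[-nrow(m), "x"])
  expect_lt(abs(cc_emp - cc_true) / abs(cc_true), 0.05)
  # variances recovered too
  expect_lt(abs(var(m[, "x"]) - p_cov[1, 1]) / p_cov[1, 1], 0.05)
})

test_that("simulate_var rejects invalid inputs", {
  spec <- two_region_spec()
  expect_error(simulate_var(spec, 20, seed = 1), "n_samples")
  expect_error(simulate_var(spec, 100, burn_in = 2, seed = 1), "burn_in")
})

test_that("group scenarios scale couplings and derive per-subject seeds", {
  spec <- motor_network_spec()
  sc <- group_scenario("SS", seed = 9)
  subs <- simulate_group(sc, spec)
  expect_length(subs, 13)
  expect_equal(attr(subs, "spec")$edges$coef, rep(0.35 * 0.2, 7))
  expect_equal(attr(subs[[1]], "group_label"), "SS")
  expect_equal(nrow(subs[[1]]), 130)
  # reproducible
  subs2 <- simulate_group(group_scenario("SS", seed = 9), spec)
  expect_identical(lfogcnet:::ts_matrix(subs[[3]]),
                   lfogcnet:::ts_matrix(subs2[[3]]))
  # zero coupling scale: generating process has no cross terms at all
  s0 <- simulate_group(group_scenario("SS", coupling_scale = 0, seed = 1), spec)
  expect_true(all(attr(s0, "spec")$edges$coef == 0))
  expect_error(simulate_group(group_scenario("SS", coupling_scale = 5, seed = 1), spec),
               "destabilizes")
})

test_that("group-mean SMA power peaks inside the 0.06-0.08 Hz band", {
  freqs <- gc_freq_grid(2)
  subs <- simulate_group(group_scenario("AB", seed = 701), motor_network_spec())
  filt <- lapply(subs, detrend_bandpass)
  pw <- quiet_var_warnings(
    Reduce(`+`, lapply(filt, function(s) var_spectrum(fit_var(s, 3), freqs)$power))
  ) / length(filt)
  peak <- peak_frequency(freqs, pw[, "SMA"], band = c(0.04, 0.1))
  expect_gte(peak, 0.06)
  expect_lte(peak, 0.08)
})

test_that("stronger coupling yields larger mean flow over the true edges", {
  spec <- motor_network_spec()
  edges <- spec$edges
  band <- c(0.04, 0.1); freqs <- gc_freq_grid(2)
  mean_edge_igc <- function(scale, seed) {
    subs <- simulate_group(
      group_scenario("SS", coupling_scale = scale, n_samples = 237,
                     n_subjects = 13, seed = seed), spec)
    vals <- vapply(subs, function(s) {
      m <- lfogcnet:::ts_matrix(detrend_bandpass(s))
      mean(vapply(seq_len(nrow(edges)), function(i) {
        lfogcnet:::igc_pair_cpp(
          m[, c(edges$source[i], edges$target[i])], 3L, freqs, 2,
          band[1], band[2])[1]
      }, numeric(1)))
    }, numeric(1))
    mean(vals)
  }
  wins <- vapply(seq_len(100), function(r) {
    mean_edge_igc(0.8, seed = 5000 + r) > mean_edge_igc(0.2, seed = 9000 + r)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
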