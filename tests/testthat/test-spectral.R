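test_that("the parametric spectrum matches closed forms", {
  # white noise: S(f) = tr * Sigma at every frequency
  wn <- lfogcnet:::new_var_fit(
    coeffs = array(0, c(2, 2, 1)), sigma = diag(2), order_p = 1L,
    n_samples_fit = NA_integer_, region_names = c("a", "b"), tr_s = 2
  )
  sp <- var_spectrum(wn, gc_freq_grid(2, 64))
  expect_true(all(abs(sp$power - 2) < 1e-12))

  # univariate AR(1), a = 0.5: closed form sigma^2 tr / |1 - a e^-iw|^2
  ar1 <- lfogcnet:::new_var_fit(
    coeffs = array(0.5, c(1, 1, 1)), sigma = matrix(1), order_p = 1L,
    n_samples_fit = NA_integer_, region_names = "a", tr_s = 2
  )
  f <- 0.05
  got <- var_spectrum(ar1, f)$power[1, 1]
  want <- 2 / Mod(1 - 0.5 * exp(-1i * 2 * pi * f * 2))^2
  expect_lt(abs(got - want), 1e-10)

  # a = 0.9: power decreases monotonically over (0, Nyquist]
  ar9 <- lfogcnet:::new_var_fit(
    coeffs = array(0.9, c(1, 1, 1)), sigma = matrix(1), order_p = 1L,
    n_samples_fit = NA_integer_, region_names = "a", tr_s = 2
  )
  pw <- var_spectrum(ar9, gc_freq_grid(2, 128))$power[, 1]
  expect_true(all(diff(pw) < 0))
})

test_that("the interdependence decomposition holds and measures are nonnegative", {
  for (seed in 1:5) {
    set.seed(seed)
    spec <- two_region_spec(coef = runif(1, 0.1, 0.45),
                            ar_self = runif(1, 0.2, 0.5),
                            sigma = matrix(c(1, 0.3, 0.3, 1), 2))
    s <- simulate_var(spec, 400, seed = 20 + seed)
    g <- quiet_var_warnings(pairwise_gc(s, c("x", "y"), order = "auto"))
    resid <- abs(g$m_total - g$m_forward - g$m_backward - g$m_inst)
    expect_lt(max(resid), 1e-6)
    expect_gte(min(g$m_forward), 0)
    expect_gte(min(g$m_backward), 0)
    # the instantaneous term may dip below zero pointwise for estimated
    # models; it must stay finite and satisfy the identity above
    expect_true(all(is.finite(g$m_inst)))
    expect_true(all(is.finite(g$m_total)))
  }
})

test_that("swapping the pair swaps the directed measures", {
  s <- simulate_var(two_region_spec(coef = 0.4), 500, seed = 26)
  g1 <- pairwise_gc(s, c("x", "y"), order = 3)
  g2 <- pairwise_gc(s, c("y", "x"), order = 3)
  expect_equal(g1$m_forward, g2$m_backward, tolerance = 1e-12)
  expect_equal(g1$m_backward, g2$m_forward, tolerance = 1e-12)
  expect_equal(g1$m_total, g2$m_total, tolerance = 1e-12)
  expect_equal(g1$m_inst, g2$m_inst, tolerance = 1e-12)
})

test_that("fully decoupled processes show vanishing directed spectra", {
  spec <- network_spec(c("x", "y"), ar_self = c(0.5, 0.5))
  s <- simulate_var(spec, 5000, seed = 27)
  g <- pairwise_gc(s, c("x", "y"), order = "auto")
  expect_lt(max(g$m_forward), 0.01)
  expect_lt(max(g$m_backward), 0.01)
  expect_lt(max(abs(g$m_inst)), 0.01)
})

test_that("estimates match the hand-coded plug-in oracle for a unidirectional model", {
  s <- simulate_var(two_region_spec(coef = 0.4, ar_self = 0.5), 10000,
                    seed = 8)
  g <- pairwise_gc(s, c("x", "y"), order = "auto")
  truth <- unidirectional_truth(g$freq_hz, tr = 2)
  expect_lt(max(abs(g$m_forward - truth) / truth), 0.10)
  expect_lt(max(g$m_backward), 0.01)

  # spectral-temporal equivalence: grid mean equals the log variance ratio
  p <- attr(g, "order_p")
  full <- fit_var(s, p)
  y_only <- roi_ts(as.data.frame(s)[, "y", drop = FALSE], tr_s = 2)
  restricted <- fit_var(y_only, as.integer(select_order(y_only, 20)))
  td <- log(restricted$sigma[1, 1] / full$sigma["y", "y"])
  expect_lt(abs(mean(g$m_forward) - td) / td, 0.05)
})

test_that("band integration is a normalized trapezoid with edge interpolation", {
  freqs <- gc_freq_grid(2, 256)
  expect_equal(integrate_gc(rep(3, 256), band = c(0.04, 0.1), freqs = freqs), 3)
  expect_equal(integrate_gc(rep(0, 256), band = c(0.04, 0.1), freqs = freqs), 0)
  ramp <- (freqs - 0.04) / 0.06  # linear 0 at f1 to 1 at f2
  expect_equal(integrate_gc(ramp, band = c(0.04, 0.1), freqs = freqs), 0.5,
               tolerance = 1e-10)
  expect_error(integrate_gc(ramp, band = c(0.2, 0.3), freqs = freqs),
               "not covered")
})

test_that("peak frequency restricts to the band and breaks ties downward", {
  freqs <- gc_freq_grid(2, 512)
  bump <- exp(-((freqs - 0.07) / 0.005)^2)
  expect_equal(peak_frequency(freqs, bump, c(0.04, 0.1)),
               freqs[which.min(abs(freqs - 0.07))])
  flat <- rep(1, 512)
  inband <- freqs[freqs >= 0.04 & freqs <= 0.1]
  expect_equal(peak_frequency(freqs, flat, c(0.04, 0.1)), min(inband))
  expect_error(peak_frequency(freqs, flat, c(0.3, 0.4)), "band")
})

test_that("the compiled kernel agrees with the reference spectral path", {
  for (seed in 1:4) {
    spec <- two_region_spec(coef = 0.3, ar_self = 0.4)
    s <- detrend_bandpass(simulate_var(spec, 237, seed = 40 + seed,
                                       band_limited = TRUE))
    for (p in c(2, 5)) {
      ref <- integrate_gc(quiet_var_warnings(pairwise_gc(s, c("x", "y"), order = p)))
      fast <- pair_igc(s, c("x", "y"), order = p)
      expect_equal(unname(fast["forward"]), ref$igc_forward, tolerance = 1e-8)
      expect_equal(unname(fast["backward"]), ref$igc_backward, tolerance = 1e-8)
    }
  }
})

test_that("subject flow tables cover every directed pair once", {
  subs <- simulate_group(group_scenario("MP", seed = 3), motor_network_spec())
  s <- detrend_bandpass(subs[[1]])
  tab <- subject_igc(s, order = 3)
  expect_equal(nrow(tab), 20)  # 10 unordered pairs, both directions
  expect_equal(anyDuplicated(paste(tab$source, tab$target)), 0)
  expect_true(all(tab$igc >= 0))
  ref <- subject_igc(s, order = 3, engine = "reference")
  expect_equal(tab$igc, ref$igc, tolerance = 1e-8)
})
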