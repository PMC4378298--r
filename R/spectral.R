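#' Frequency grid for spectral analysis
#'
#' `n` evenly spaced frequencies on `(0, Nyquist]`.
#'
#' @param tr_s sampling interval in seconds.
#' @param n grid size (default 512).
#' @return Numeric vector of frequencies in Hz.
#' @export
gc_freq_grid <- function(tr_s, n = 512) {
  nyq <- 1 / (2 * tr_s)
  seq_len(n) * nyq / n
}

#' Parametric spectral matrix of a fitted VAR model
#'
#' Evaluates `A(f) = I - sum_k A_k exp(-i 2 pi f k tr)`, the transfer
#' function `H(f) = A(f)^-1`, and the one-sided spectral density
#' `S(f) = H(f) Sigma H(f)* tr`.  Diagonal entries of `S` are the region
#' power spectra; the fixed density convention cancels inside every
#' causality log-ratio.
#'
#' @param model a `var_fit` (or the truth embedded in one).
#' @param freqs_hz frequency grid; default [gc_freq_grid()] at the model's
#'   TR.
#' @return A list of class `var_spectrum`: `freqs_hz`, complex arrays `S`
#'   and `H` (R x R x F), `power` (F x R real matrix), `region_names`,
#'   `tr_s`.
#' @export
var_spectrum <- function(model, freqs_hz = NULL) {
  stopifnot(inherits(model, "var_fit") || is.list(model))
  tr <- model$tr_s
  if (is.null(freqs_hz)) freqs_hz <- gc_freq_grid(tr)
  r <- length(model$region_names)
  p <- model$order_p
  nf <- length(freqs_hz)
  s_arr <- array(complex(real = 0), dim = c(r, r, nf))
  h_arr <- array(complex(real = 0), dim = c(r, r, nf))
  power <- matrix(NA_real_, nf, r, dimnames = list(NULL, model$region_names))
  eye <- diag(r)
  for (fi in seq_len(nf)) {
    a_f <- eye
    for (k in seq_len(p)) {
      a_f <- a_f - model$coeffs[, , k] * exp(-1i * 2 * pi * freqs_hz[fi] * k * tr)
    }
    h <- tryCatch(solve(a_f), error = function(e) {
      abort(sprintf("A(f) numerically singular at f = %g Hz", freqs_hz[fi]))
    })
    s <- h %*% model$sigma %*% Conj(t(h)) * tr
    h_arr[, , fi] <- h
    s_arr[, , fi] <- s
    power[fi, ] <- Re(diag(s))
  }
  structure(
    list(freqs_hz = freqs_hz, S = s_arr, H = h_arr, power = power,
         region_names = model$region_names, tr_s = tr),
    class = "var_spectrum"
  )
}

#' Tidy a spectral matrix into a long power table
#'
#' @param x a `var_spectrum`.
#' @param ... unused.
#' @return Tibble `freq_hz`, `region`, `power`.
#' @export
tidy.var_spectrum <- function(x, ...) {
  out <- as_tibble(x$power)
  out$freq_hz <- x$freqs_hz  # assigned outside data masking: regions may
  out |>                     # be named like locals
    tidyr::pivot_longer(-"freq_hz", names_to = "region", values_to = "power")
}

# Geweke decomposition from a bivariate var_spectrum and innovation
# covariance.  Returns the four per-frequency measures; `m_forward` is
# region1 -> region2.
geweke_measures <- function(sp, sigma, clamp_tol = 1e-8) {
  stopifnot(length(sp$region_names) == 2)
  tr <- sp$tr_s
  s11 <- Re(sp$S[1, 1, ]); s22 <- Re(sp$S[2, 2, ])
  s12 <- sp$S[1, 2, ]
  det_s <- s11 * s22 - Re(s12 * Conj(s12))
  if (any(det_s <= 0) || any(s11 <= 0) || any(s22 <= 0)) {
    bad <- sp$freqs_hz[which(det_s <= 0 | s11 <= 0 | s22 <= 0)[1]]
    abort(sprintf("spectral matrix near-singular (coherence ~ 1) at f = %g Hz", bad))
  }
  h11 <- sp$H[1, 1, ]; h12 <- sp$H[1, 2, ]
  h21 <- sp$H[2, 1, ]; h22 <- sp$H[2, 2, ]
  # Orthogonalized transfer terms: e2 regressed on e1 and vice versa.
  ht11 <- h11 + (sigma[1, 2] / sigma[1, 1]) * h12
  ht22 <- h22 + (sigma[1, 2] / sigma[2, 2]) * h21
  intr1 <- Re(ht11 * Conj(ht11)) * sigma[1, 1] * tr
  intr2 <- Re(ht22 * Conj(ht22)) * sigma[2, 2] * tr
  m_backward <- log(s11 / intr1)   # region2 -> region1
  m_forward <- log(s22 / intr2)    # region1 -> region2
  m_total <- log(s11 * s22 / det_s)
  m_inst <- log(intr1 * intr2 / det_s)
  clamp <- function(v) {
    n_clamped <- sum(v < 0 & v >= -clamp_tol)
    v[v < 0 & v >= -clamp_tol] <- 0
    attr(v, "n_clamped") <- n_clamped
    v
  }
  out <- list(
    m_total = m_total,
    m_forward = clamp(m_forward), m_backward = clamp(m_backward),
    m_inst = clamp(m_inst)
  )
  attr(out, "n_clamped") <- sum(vapply(out[-1],
                                       function(v) attr(v, "n_clamped") %||% 0L,
                                       numeric(1)))
  out
}

#' Pairwise spectral Granger causality
#'
#' Fits a fresh bivariate VAR on the two requested region columns and
#' returns the Geweke interdependence spectra: the total interdependence
#' `m_total`, the two directed causal flows, and the instantaneous term,
#' satisfying `m_total = m_forward + m_backward + m_inst` at every
#' frequency.  The directed measures are nonnegative by construction
#' (tiny rounding negatives are clamped at zero and counted in attribute
#' `"n_clamped"`); the instantaneous term may dip below zero pointwise
#' for estimated models.
#'
#' @param series a [roi_ts()] containing both regions.
#' @param pair character 2-vector `c(region1, region2)`; `m_forward` is
#'   region1 -> region2.
#' @param freqs_hz frequency grid; default [gc_freq_grid()].
#' @param order `"auto"` (criterion-selected) or an integer order.
#' @param p_max,criterion passed to [select_order()] when `order =
#'   "auto"`.
#' @return Tibble of class `gc_spectrum` with columns `freq_hz`,
#'   `m_total`, `m_forward`, `m_backward`, `m_inst`; attributes `pair`,
#'   `order_p`, `sigma`, `tr_s`, `n_clamped`.
#' @export
pairwise_gc <- function(series, pair, freqs_hz = NULL, order = "auto",
                        p_max = 10, criterion = "AIC") {
  if (!all(pair %in% names(series))) {
    abort(paste0("regions not found in series: ",
                 paste(setdiff(pair, names(series)), collapse = ", ")))
  }
  sub <- roi_ts(as.data.frame(series)[, pair, drop = FALSE],
                tr_s = tr_of(series),
                subject_id = attr(series, "subject_id"),
                group_label = attr(series, "group_label"),
                filtered = attr(series, "filtered"))
  p <- if (identical(order, "auto")) {
    as.integer(select_order(sub, p_max = p_max, criterion = criterion))
  } else {
    as.integer(order)
  }
  fit <- fit_var(sub, p)
  if (is.null(freqs_hz)) freqs_hz <- gc_freq_grid(fit$tr_s)
  sp <- var_spectrum(fit, freqs_hz)
  meas <- geweke_measures(sp, fit$sigma)
  out <- tibble(
    freq_hz = freqs_hz,
    m_total = meas$m_total,
    m_forward = as.numeric(meas$m_forward),
    m_backward = as.numeric(meas$m_backward),
    m_inst = as.numeric(meas$m_inst)
  )
  attr(out, "pair") <- pair
  attr(out, "order_p") <- p
  attr(out, "sigma") <- fit$sigma
  attr(out, "tr_s") <- fit$tr_s
  attr(out, "n_clamped") <- attr(meas, "n_clamped")
  class(out) <- c("gc_spectrum", class(out))
  out
}

# Normalized trapezoidal band average of `values` sampled at `freqs`,
# with linear interpolation at the band edges.
band_average <- function(freqs, values, band) {
  f1 <- band[1]; f2 <- band[2]
  if (!(f1 < f2)) abort("band must satisfy f1 < f2")
  if (f1 < min(freqs) || f2 > max(freqs)) {
    abort(sprintf("band [%g, %g] Hz not covered by the frequency grid [%g, %g]",
                  f1, f2, min(freqs), max(freqs)))
  }
  inner <- freqs > f1 & freqs < f2
  fe <- c(f1, freqs[inner], f2)
  ve <- c(approx(freqs, values, f1)$y, values[inner],
          approx(freqs, values, f2)$y)
  sum(diff(fe) * (head(ve, -1) + tail(ve, -1)) / 2) / (f2 - f1)
}

#' Band-integrated causal flow
#'
#' The normalized integral `1/(f2 - f1) * integral of M(f) df` over the
#' analysis band, by the trapezoidal rule on the spectrum's grid (band
#' edges linearly interpolated).  Equals the band average for a constant
#' spectrum.
#'
#' @param x a `gc_spectrum` from [pairwise_gc()], or a numeric vector of
#'   per-frequency values (then `freqs` is required).
#' @param band `c(f1, f2)` in Hz; the grid must cover it.
#' @param freqs frequency grid for the numeric-vector form.
#' @return For a `gc_spectrum`: a one-row tibble with the band-integrated
#'   `igc_forward`, `igc_backward`, `igc_total`, `igc_inst` plus the pair
#'   labels.  For a numeric vector: a scalar.
#' @export
integrate_gc <- function(x, band = c(0.04, 0.1), freqs = NULL) {
  if (inherits(x, "gc_spectrum")) {
    pair <- attr(x, "pair")
    tibble(
      source = pair[1], target = pair[2],
      igc_forward = band_average(x$freq_hz, x$m_forward, band),
      igc_backward = band_average(x$freq_hz, x$m_backward, band),
      igc_total = band_average(x$freq_hz, x$m_total, band),
      igc_inst = band_average(x$freq_hz, x$m_inst, band),
      f1 = band[1], f2 = band[2]
    )
  } else {
    if (is.null(freqs)) abort("freqs is required when x is a numeric vector")
    band_average(freqs, as.numeric(x), band)
  }
}

#' Peak frequency of a spectrum within a band
#'
#' Argmax of the spectrum restricted to the band, ties broken toward the
#' lower frequency.
#'
#' @param freqs frequency grid (Hz).
#' @param values per-frequency values (same length).
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return The peak frequency in Hz.
#' @export
peak_frequency <- function(freqs, values, band = c(0.04, 0.1)) {
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) abort("no grid frequencies inside the requested band")
  f <- freqs[keep]; v <- values[keep]
  f[which.max(v)]
}

all_region_pairs <- function(region_names) {
  cmb <- utils::combn(region_names, 2)
  tibble(region1 = cmb[1, ], region2 = cmb[2, ])
}

#' Band-integrated causal flow for every directed region pair
#'
#' One bivariate model per unordered pair (each yielding both directed
#' flows).  The `"compiled"` engine runs the C++ kernel used by the
#' permutation machinery; `"reference"` runs the R spectral path.  The two
#' agree to numerical tolerance (asserted by the test suite).
#'
#' @param series a [roi_ts()].
#' @param band integration band `c(f1, f2)` Hz.
#' @param order `"auto"` or integer VAR order.
#' @param p_max,criterion order-selection settings.
#' @param n_freq frequency-grid size.
#' @param engine `"compiled"` (default) or `"reference"`.
#' @return Tibble with one row per ordered pair: `subject_id`,
#'   `group_label`, `source`, `target`, `igc`, `order_p`.
#' @export
subject_igc <- function(series, band = c(0.04, 0.1), order = "auto",
                        p_max = 10, criterion = "AIC", n_freq = 512,
                        engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  pairs <- all_region_pairs(names(series))
  tr <- tr_of(series)
  freqs <- gc_freq_grid(tr, n_freq)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    pr <- c(pairs$region1[i], pairs$region2[i])
    if (engine == "reference") {
      spec <- pairwise_gc(series, pr, freqs_hz = freqs, order = order,
                          p_max = p_max, criterion = criterion)
      ig <- integrate_gc(spec, band)
      fwd <- ig$igc_forward; bwd <- ig$igc_backward
      p <- attr(spec, "order_p")
    } else {
      p <- resolve_order(series, pr, order, p_max, criterion)
      v <- igc_pair_cpp(ts_matrix(series)[, pr, drop = FALSE], p, freqs, tr,
                        band[1], band[2])
      fwd <- v[1]; bwd <- v[2]
    }
    tibble(
      subject_id = attr(series, "subject_id") %||% NA_character_,
      group_label = attr(series, "group_label") %||% NA_character_,
      source = c(pr[1], pr[2]), target = c(pr[2], pr[1]),
      igc = c(fwd, bwd), order_p = as.integer(p)
    )
  })
}

resolve_order <- function(series, pair, order, p_max, criterion) {
  if (identical(order, "auto")) {
    sub <- roi_ts(as.data.frame(series)[, pair, drop = FALSE],
                  tr_s = tr_of(series))
    as.integer(select_order(sub, p_max = p_max, criterion = criterion))
  } else {
    as.integer(order)
  }
}

#' Surrogate bias of the band-integrated flow estimator
#'
#' Mean band-integrated causal flow over surrogate pairs in which one
#' member's time axis has been randomly rotated (cyclic permutation),
#' estimating the finite-sample bias of the flow estimator for this
#' subject at this session length.  Subtracting it yields a
#' session-length-comparable flow for group contrasts.
#'
#' @inheritParams pair_igc
#' @param n_draws surrogate draws averaged.
#' @param seed integer seed.
#' @return Named numeric vector `c(forward, backward)` of mean surrogate
#'   flow.
#' @export
igc_surrogate_bias <- function(series, pair, band = c(0.04, 0.1),
                               order = "auto", n_draws = 20, seed = 1L,
                               p_max = 10, criterion = "AIC", n_freq = 512) {
  p <- resolve_order(series, pair, order, p_max, criterion)
  tr <- tr_of(series)
  freqs <- gc_freq_grid(tr, n_freq)
  m <- ts_matrix(series)[, pair, drop = FALSE]
  null_mat <- with_seed(seed, {
    perm_null_cpp(list(m), p, as.integer(n_draws), freqs, tr,
                  band[1], band[2], TRUE)
  })
  c(forward = mean(null_mat[, 1]), backward = mean(null_mat[, 2]))
}

#' Fast band-integrated causal flow for one pair
#'
#' Thin wrapper over the compiled kernel (least-squares bivariate VAR fit,
#' Geweke directed spectra on the grid, trapezoidal band integral) used by
#' the permutation-null and Monte-Carlo machinery.
#'
#' @inheritParams pairwise_gc
#' @param band integration band `c(f1, f2)` Hz.
#' @param n_freq frequency-grid size.
#' @return Named numeric vector: `forward` (region1 -> region2),
#'   `backward`.
#' @export
pair_igc <- function(series, pair, band = c(0.04, 0.1), order = "auto",
                     p_max = 10, criterion = "AIC", n_freq = 512) {
  p <- resolve_order(series, pair, order, p_max, criterion)
  tr <- tr_of(series)
  freqs <- gc_freq_grid(tr, n_freq)
  v <- igc_pair_cpp(ts_matrix(series)[, pair, drop = FALSE], p, freqs, tr,
                    band[1], band[2])
  c(forward = v[1], backward = v[2])
}
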