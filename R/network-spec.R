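#' Specify a directed oscillatory network
#'
#' A `network_spec` defines the ground-truth generating process used by the
#' simulator: a stable vector-autoregressive (VAR) model whose lag-1 diagonal
#' holds per-region self-regression terms, whose directed couplings live on
#' an explicit edge list, and whose innovations can be band-shaped so that
#' power concentrates around a target low frequency.
#'
#' @param region_names character vector of region labels.
#' @param edges data frame with columns `source`, `target`, `coef`, `lag`
#'   (lag in samples, >= 1).  Self-edges are not allowed here; self terms
#'   live in `ar_self`.
#' @param ar_self per-region lag-1 self-regression coefficients (recycled to
#'   length R).
#' @param innovation_cov R x R symmetric positive-definite innovation
#'   covariance (default identity).
#' @param band_center_hz target dominant frequency of the innovations (Hz).
#' @param band_half_width_hz half-width of the innovation shaping band; the
#'   shaping band-pass corners sit at `band_center_hz` +/-
#'   `band_half_width_hz`.
#' @param tr_s sampling interval in seconds.
#'
#' @return A list of class `network_spec`.
#' @seealso [motor_network_spec()] for the five-node motor network default.
#' @export
network_spec <- function(region_names, edges = NULL, ar_self = 0.35,
                         innovation_cov = NULL, band_center_hz = 0.07,
                         band_half_width_hz = 0.025, tr_s = 2.0) {
  region_names <- as.character(region_names)
  r <- length(region_names)
  if (r < 1L || anyDuplicated(region_names)) {
    abort("region_names must be non-empty and unique")
  }
  if (is.null(edges)) {
    edges <- tibble(
      source = character(), target = character(),
      coef = numeric(), lag = integer()
    )
  }
  edges <- as_tibble(edges)
  if (!all(c("source", "target", "coef", "lag") %in% names(edges))) {
    abort("edges needs columns source, target, coef, lag")
  }
  bad <- setdiff(c(edges$source, edges$target), region_names)
  if (length(bad) > 0) {
    abort(paste0("edges reference unknown regions: ", paste(bad, collapse = ", ")))
  }
  if (any(edges$source == edges$target)) {
    abort("self-edges are not allowed in `edges`; use ar_self")
  }
  if (any(edges$lag < 1 | edges$lag != round(edges$lag))) {
    abort("edge lags must be positive integers")
  }
  ar_self <- rep_len(ar_self, r)
  if (is.null(innovation_cov)) innovation_cov <- diag(r)
  innovation_cov <- as.matrix(innovation_cov)
  if (!isTRUE(all.equal(innovation_cov, t(innovation_cov), tolerance = 1e-8))) {
    abort("innovation_cov must be symmetric")
  }
  ok <- tryCatch({ chol(innovation_cov); TRUE }, error = function(e) FALSE)
  if (!ok) abort("innovation_cov must be positive definite")

  spec <- structure(
    list(
      region_names = region_names, n_regions = r, edges = edges,
      ar_self = ar_self, innovation_cov = innovation_cov,
      band_center_hz = band_center_hz,
      band_half_width_hz = band_half_width_hz, tr_s = tr_s
    ),
    class = "network_spec"
  )
  rad <- companion_radius(coef_array(spec))
  if (rad >= 1) {
    abort(sprintf(
      "network_spec is non-stationary: companion spectral radius %.4f >= 1", rad
    ))
  }
  attr(spec, "spectral_radius") <- rad
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> %d regions (%s), %d directed edges, radius %.3f, TR %g s\n",
    x$n_regions, paste(x$region_names, collapse = ", "), nrow(x$edges),
    attr(x, "spectral_radius"), x$tr_s
  ))
  invisible(x)
}

# Lag-coefficient array R x R x P from a network_spec.
coef_array <- function(spec) {
  r <- spec$n_regions
  p <- max(c(1L, spec$edges$lag))
  a <- array(0, dim = c(r, r, p),
             dimnames = list(spec$region_names, spec$region_names, NULL))
  a[, , 1] <- a[, , 1] + diag(spec$ar_self, r)
  for (i in seq_len(nrow(spec$edges))) {
    e <- spec$edges[i, ]
    a[e$target, e$source, e$lag] <- a[e$target, e$source, e$lag] + e$coef
  }
  a
}

# Spectral radius of the VAR companion matrix for an R x R x P array.
companion_radius <- function(a) {
  r <- dim(a)[1]; p <- dim(a)[3]
  comp <- matrix(0, r * p, r * p)
  for (k in seq_len(p)) comp[1:r, (k - 1) * r + 1:r] <- a[, , k]
  if (p > 1) comp[(r + 1):(r * p), 1:(r * (p - 1))] <- diag(r * (p - 1))
  max(abs(eigen(comp, only.values = TRUE)$values))
}

#' Five-node motor-execution network
#'
#' The default ground-truth network: LM1, RM1, LPMC, RPMC and SMA with the
#' seven directed couplings found significant in able-bodied participants
#' (LM1<->SMA, RPMC<->SMA, RPMC->LM1, SMA->RM1, SMA->LPMC), all at lag 1.
#'
#' @param coupling lag-1 coupling coefficient placed on each of the seven
#'   edges (before any group scaling).
#' @param coupling_scale multiplier applied to `coupling` (group attenuation
#'   or restoration; 1 = able-bodied).
#' @param ar_self per-region self-regression coefficient.
#' @inheritParams network_spec
#' @return A [network_spec()].
#' @export
motor_network_spec <- function(coupling = 0.35, coupling_scale = 1,
                               ar_self = 0.35, band_center_hz = 0.07,
                               band_half_width_hz = 0.025, tr_s = 2.0) {
  edges <- motor_network_edges()
  edges$coef <- coupling * coupling_scale
  network_spec(
    region_names = c("LM1", "RM1", "LPMC", "RPMC", "SMA"),
    edges = edges, ar_self = ar_self,
    band_center_hz = band_center_hz,
    band_half_width_hz = band_half_width_hz, tr_s = tr_s
  )
}

#' The seven significant motor-network connections
#'
#' @return Tibble with columns `source`, `target`, `coef` (NA placeholder),
#'   `lag`.
#' @export
motor_network_edges <- function() {
  tibble(
    source = c("LM1", "SMA", "RPMC", "SMA", "RPMC", "SMA", "SMA"),
    target = c("SMA", "LM1", "SMA", "RPMC", "LM1", "RM1", "LPMC"),
    coef = NA_real_, lag = 1L
  )
}

# Rescale all edge coefficients; error (with diagnostic) if the scaled
# process is non-stationary.
scale_spec <- function(spec, coupling_scale) {
  if (coupling_scale < 0) abort("coupling_scale must be >= 0")
  edges <- spec$edges
  edges$coef <- edges$coef * coupling_scale
  tryCatch(
    network_spec(spec$region_names, edges, spec$ar_self, spec$innovation_cov,
                 spec$band_center_hz, spec$band_half_width_hz, spec$tr_s),
    error = function(e) {
      abort(sprintf("coupling_scale %.3g destabilizes the network: %s",
                    coupling_scale, conditionMessage(e)))
    }
  )
}

#' Ground-truth spectral Granger causality of a two-region specification
#'
#' Plugs the true coefficients and innovation covariance of a two-region
#' `network_spec` into the Geweke formulas, yielding the directed causal
#' flow of the generating process itself (no estimation).  Used to verify
#' that estimated flow recovers the truth and that flow grows with coupling.
#'
#' @param spec a two-region [network_spec()].
#' @param band integration band `c(f1, f2)` in Hz.
#' @param n_freq frequency-grid size on `(0, Nyquist]`.
#' @return Tibble with one row per direction: `source`, `target`, `igc`.
#' @export
theoretical_gc <- function(spec, band = c(0.04, 0.1), n_freq = 512) {
  if (spec$n_regions != 2L) {
    abort("theoretical_gc is defined for two-region specifications only")
  }
  a <- coef_array(spec)
  model <- new_var_fit(
    coeffs = a, sigma = spec$innovation_cov, order_p = dim(a)[3],
    n_samples_fit = NA_integer_, region_names = spec$region_names,
    tr_s = spec$tr_s, criterion_trace = NULL
  )
  # A block-diagonal truth has exactly zero causal flow; report it exactly.
  off_zero <- all(a[1, 2, ] == 0) && all(a[2, 1, ] == 0) &&
    spec$innovation_cov[1, 2] == 0
  if (off_zero) {
    return(tibble(
      source = c(spec$region_names[1], spec$region_names[2]),
      target = c(spec$region_names[2], spec$region_names[1]),
      igc = c(0, 0)
    ))
  }
  freqs <- gc_freq_grid(spec$tr_s, n_freq)
  sp <- var_spectrum(model, freqs_hz = freqs)
  meas <- geweke_measures(sp, model$sigma)
  tibble(
    source = c(spec$region_names[1], spec$region_names[2]),
    target = c(spec$region_names[2], spec$region_names[1]),
    igc = c(
      band_average(freqs, meas$m_forward, band),
      band_average(freqs, meas$m_backward, band)
    )
  )
}
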