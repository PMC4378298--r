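# Shared fixtures and independent oracles for the suite.

two_region_spec <- function(coef = 0.4, ar_self = 0.5, lag = 1L,
                            sigma = NULL, ...) {
  edges <- if (coef == 0) NULL else {
    data.frame(source = "x", target = "y", coef = coef, lag = lag)
  }
  network_spec(c("x", "y"), edges = edges, ar_self = ar_self,
               innovation_cov = sigma, ...)
}

decoupled_band_spec <- function() {
  network_spec(c("x", "y"), ar_self = 0.35)
}

# Stationary covariance of a VAR(1) by solving the discrete Lyapunov
# equation vec(P) = (I - A (x) A)^-1 vec(Sigma).  Independent of the
# package's simulation/estimation code.
lyapunov_cov <- function(a_mat, sigma) {
  r <- nrow(a_mat)
  matrix(solve(diag(r^2) - kronecker(a_mat, a_mat), as.vector(sigma)), r)
}

# Closed-form directed spectrum of the unidirectional model
#   x_t = a x_{t-1} + ex,  y_t = a y_{t-1} + c x_{t-1} + ey,  Sigma = I,
# written out by hand from the 2x2 transfer function.
unidirectional_truth <- function(freqs, tr, a = 0.5, c = 0.4) {
  e <- exp(-1i * 2 * pi * freqs * tr)
  h21 <- c * e / (1 - a * e)^2
  h22 <- 1 / (1 - a * e)
  log(1 + Mod(h21)^2 / Mod(h22)^2)
}

# Simple periodogram mass of a vector (no taper), for spectral-support
# checks independent of the package's parametric spectra.
periodogram <- function(x, tr) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  list(freq = k / (n * tr), power = p[k + 1])
}

quiet_var_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-stationary", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
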