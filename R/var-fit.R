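new_var_fit <- function(coeffs, sigma, order_p, n_samples_fit, region_names,
                        tr_s, criterion_trace = NULL) {
  structure(
    list(
      order_p = order_p, coeffs = coeffs, sigma = sigma,
      n_samples_fit = n_samples_fit, region_names = region_names,
      tr_s = tr_s, criterion_trace = criterion_trace
    ),
    class = "var_fit"
  )
}

#' Fit a vector-autoregressive model by least squares
#'
#' Multivariate regression of each time point on its `order_p`
#' predecessors (no intercept: inputs are expected detrended, so columns
#' are mean-zero).  The innovation covariance is the residual covariance
#' with the unbiased denominator `T - p - R*p`.
#'
#' @param series a [roi_ts()] (any number of regions).
#' @param order_p model order p; `T > R*p + 1` is required.
#' @return A `var_fit` object: lag coefficients (R x R x p array `coeffs`,
#'   `coeffs[i, j, k]` weighting region j at lag k in region i's
#'   equation), innovation covariance `sigma`, and fit metadata.  A
#'   warning (not an error) is raised if the fitted model is
#'   non-stationary.
#' @seealso [select_order()], [var_spectrum()], [tidy.var_fit()]
#' @export
fit_var <- function(series, order_p) {
  m <- ts_matrix(series)
  t_n <- nrow(m); r <- ncol(m)
  order_p <- as.integer(order_p)
  if (order_p < 1) abort("order_p must be >= 1")
  if (t_n <= r * order_p + 1) {
    abort(sprintf("series too short: need T > R*p + 1 = %d, have %d",
                  r * order_p + 1, t_n))
  }
  yx <- build_lagged(m, order_p)
  xtx <- crossprod(yx$x)
  if (rcond(xtx) < 1e-12) {
    abort("singular regressor matrix; try a lower model order")
  }
  b <- solve(xtx, crossprod(yx$x, yx$y))
  resid <- yx$y - yx$x %*% b
  denom <- t_n - order_p - r * order_p
  if (denom < 1) abort("too few observations for the unbiased covariance")
  sigma <- crossprod(resid) / denom
  dimnames(sigma) <- list(colnames(m), colnames(m))

  coeffs <- array(0, dim = c(r, r, order_p),
                  dimnames = list(colnames(m), colnames(m), NULL))
  for (k in seq_len(order_p)) {
    coeffs[, , k] <- t(b[(k - 1) * r + seq_len(r), , drop = FALSE])
  }
  rad <- companion_radius(coeffs)
  if (rad >= 1) {
    warn(sprintf("fitted VAR is non-stationary (companion radius %.4f)", rad))
  }
  fit <- new_var_fit(coeffs, sigma, order_p, t_n, colnames(m), tr_of(series))
  attr(fit, "spectral_radius") <- rad
  fit
}

build_lagged <- function(m, p) {
  t_n <- nrow(m); r <- ncol(m)
  y <- m[(p + 1):t_n, , drop = FALSE]
  x <- matrix(0, t_n - p, r * p)
  for (k in seq_len(p)) {
    x[, (k - 1) * r + seq_len(r)] <- m[(p + 1 - k):(t_n - k), , drop = FALSE]
  }
  list(y = y, x = x)
}

#' Select the VAR model order by information criterion
#'
#' Fits orders `1..p_max` on the common effective sample (rows
#' `p_max+1..T`) and returns the criterion-minimizing order.
#' `AIC(p) = log det(Sigma_ML) + 2 p R^2 / T_eff`;
#' BIC replaces `2` with `log(T_eff)`.
#'
#' @inheritParams fit_var
#' @param p_max largest order considered.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return The selected order (integer) with the full criterion trace as
#'   attribute `"criterion_trace"` (tibble `order`, `value`).
#' @export
select_order <- function(series, p_max = 10, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  m <- ts_matrix(series)
  t_n <- nrow(m); r <- ncol(m)
  p_max <- as.integer(p_max)
  if (t_n <= r * p_max + p_max + 1) {
    abort(sprintf(
      "p_max = %d infeasible for T = %d, R = %d (need T > R*p_max + p_max + 1 = %d)",
      p_max, t_n, r, r * p_max + p_max + 1
    ))
  }
  t_eff <- t_n - p_max
  vals <- vapply(seq_len(p_max), function(p) {
    x_full <- build_lagged(m, p_max)
    # common sample: regress rows p_max+1..T on lags 1..p
    x <- x_full$x[, seq_len(r * p), drop = FALSE]
    y <- x_full$y
    b <- qr.solve(x, y)
    resid <- y - x %*% b
    sig_ml <- crossprod(resid) / t_eff
    pen <- if (criterion == "AIC") 2 else log(t_eff)
    as.numeric(determinant(sig_ml, logarithm = TRUE)$modulus) +
      pen * p * r^2 / t_eff
  }, numeric(1))
  best <- which.min(vals)
  structure(as.integer(best),
            criterion = criterion,
            criterion_trace = tibble(order = seq_len(p_max), value = vals))
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> VAR(%d) on %d regions, T = %s, companion radius %.3f\n",
              x$order_p, length(x$region_names),
              format(x$n_samples_fit), attr(x, "spectral_radius")))
  invisible(x)
}

#' Tidy a fitted VAR model
#'
#' @param x a `var_fit`.
#' @param ... unused.
#' @return One row per coefficient: `equation` (target region), `regressor`
#'   (source region), `lag`, `estimate`.
#' @export
tidy.var_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$order_p), function(k) {
    a <- x$coeffs[, , k]
    tibble(
      equation = rep(rownames(a), times = ncol(a)),
      regressor = rep(colnames(a), each = nrow(a)),
      lag = k, estimate = as.vector(a)
    )
  })
}

#' One-row summary of a fitted VAR model
#'
#' @param x a `var_fit`.
#' @param ... unused.
#' @return Tibble with `order_p`, `n_regions`, `n_samples`,
#'   `spectral_radius`, `log_det_sigma`.
#' @export
glance.var_fit <- function(x, ...) {
  tibble(
    order_p = x$order_p, n_regions = length(x$region_names),
    n_samples = x$n_samples_fit,
    spectral_radius = attr(x, "spectral_radius"),
    log_det_sigma = as.numeric(determinant(x$sigma, logarithm = TRUE)$modulus)
  )
}
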