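#' Permutation significance threshold for integrated causal flow
#'
#' Builds the null distribution of band-integrated causal flow by, per
#' permutation draw, randomly permuting the time indices of one member of
#' the region pair in every pooled subject (destroying the cross-lag
#' structure causality measures while preserving the marginal amplitude
#' distribution), recomputing both directed flows per subject, and pooling
#' every draw.  The threshold is the empirical `1 - alpha` quantile of the
#' pooled null.
#'
#' Two permutation schemes are provided.  The default `"cyclic"` draws a
#' random rotation of the time axis: still a permutation of time indices,
#' but one that preserves the permuted member's autocorrelation (up to the
#' wrap-around), so the null matches the sampling distribution of the flow
#' estimator on band-limited data and the threshold is calibrated
#' (type-I error at the nominal level).  `"full"` draws an unrestricted
#' permutation, which whitens the permuted member; on band-limited series
#' this understates the null flow and is strongly anti-conservative, so it
#' is provided for comparison only.
#'
#' @param series_list list of [roi_ts()] pooled over the two groups being
#'   compared (e.g. 13 AB + 13 SS subjects).
#' @param pair character 2-vector of region names.
#' @param band integration band `c(f1, f2)` Hz.
#' @param n_perm number of permutation draws; `n_perm * alpha < 10` (too
#'   few null exceedances) triggers a quantile-instability warning.
#' @param alpha significance level (the study uses 0.01).
#' @param seed integer seed; the threshold is deterministic given it.
#' @param order,p_max,criterion VAR-order settings: `"auto"` selects the
#'   order per subject on the unpermuted pair and reuses it for that
#'   subject's permutations.
#' @param n_freq frequency-grid size.
#' @param scheme `"cyclic"` (calibrated default) or `"full"`.
#' @param return_null also return the pooled null values?
#' @return The threshold (scalar).  Attributes: `alpha`, `n_perm`,
#'   `n_null`, `scheme`, and (optionally) `null_values`.
#' @export
permutation_threshold <- function(series_list, pair, band = c(0.04, 0.1),
                                  n_perm = 1000, alpha = 0.01, seed = 1L,
                                  order = "auto", p_max = 10,
                                  criterion = "AIC", n_freq = 512,
                                  scheme = c("cyclic", "full"),
                                  return_null = FALSE) {
  scheme <- match.arg(scheme)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (n_perm * alpha < 10) {
    warn(sprintf(
      "n_perm * alpha = %.1f < 10: the %.3g quantile of the null is unstable",
      n_perm * alpha, 1 - alpha
    ))
  }
  tr <- tr_of(series_list[[1]])
  freqs <- gc_freq_grid(tr, n_freq)
  mats <- lapply(series_list, function(s) ts_matrix(s)[, pair, drop = FALSE])
  orders <- vapply(series_list, function(s) {
    resolve_order(s, pair, order, p_max, criterion)
  }, integer(1))
  null_mat <- with_seed(seed, {
    perm_null_cpp(mats, orders, as.integer(n_perm), freqs, tr,
                  band[1], band[2], scheme == "cyclic")
  })
  null_values <- as.numeric(null_mat)  # both directions pooled
  thr <- as.numeric(quantile(null_values, probs = 1 - alpha, type = 7))
  attr(thr, "alpha") <- alpha
  attr(thr, "n_perm") <- n_perm
  attr(thr, "n_null") <- length(null_values)
  attr(thr, "scheme") <- scheme
  if (return_null) attr(thr, "null_values") <- null_values
  thr
}

#' Percent difference in connectivity (stroke vs able-bodied)
#'
#' `D = (iGC_SS - iGC_AB) / iGC_AB * 100`, the percent change of a
#' connection's integrated causal flow relative to the able-bodied
#' reference.
#'
#' @param igc_ss,igc_ab integrated causal flow for the comparison (stroke)
#'   and reference (able-bodied) condition; `igc_ab` must be > 0.
#' @return Percent difference (vectorized).
#' @export
percent_difference <- function(igc_ss, igc_ab) {
  if (any(igc_ab <= 0)) {
    abort("reference flow igc_ab must be > 0 for a percent difference")
  }
  (igc_ss - igc_ab) / igc_ab * 100
}

#' Percent modulation after intervention
#'
#' `M = (iGC_post - iGC_SS) / iGC_post * 100`.  Note the denominator is
#' the post-treatment value (asymmetric with [percent_difference()]),
#' so M is bounded above by 100% but unbounded below.
#'
#' @param igc_post post-intervention flow (MP or MP+PT); must be nonzero.
#' @param igc_ss pre-intervention (stroke) flow.
#' @return Percent modulation (vectorized).
#' @export
percent_modulation <- function(igc_post, igc_ss) {
  if (any(igc_post == 0)) {
    abort("post-treatment flow igc_post must be nonzero for a percent modulation")
  }
  (igc_post - igc_ss) / igc_post * 100
}

#' Network-level t test
#'
#' Classic (pooled-variance) t test comparing per-subject network
#' summaries - each subject's sum of integrated causal flow over the
#' significant connections - between two conditions.
#'
#' @param igc_a,igc_b per-subject network values for the two conditions.
#' @param paired paired test? (requires equal lengths).
#' @return One-row tibble: `t`, `p` (two-tailed), `df`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `paired`.
#' @export
network_ttest <- function(igc_a, igc_b, paired = FALSE) {
  if (length(igc_a) < 2 || length(igc_b) < 2) abort("need n >= 2 per group")
  if (paired && length(igc_a) != length(igc_b)) {
    abort("paired test requires equal group sizes")
  }
  degenerate <- if (paired) {
    var(igc_a - igc_b) == 0
  } else {
    var(igc_a) == 0 && var(igc_b) == 0
  }
  if (degenerate) {
    if (isTRUE(all.equal(mean(igc_a), mean(igc_b)))) {
      warn("degenerate variance; returning t = 0, p = 1")
      return(tibble(t = 0, p = 1, df = NA_real_,
                    n_a = length(igc_a), n_b = length(igc_b),
                    mean_a = mean(igc_a), mean_b = mean(igc_b),
                    paired = paired))
    }
    abort("zero variance with unequal means")
  }
  ht <- t.test(igc_a, igc_b, paired = paired, var.equal = TRUE,
               alternative = "two.sided")
  tibble(
    t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
    n_a = length(igc_a), n_b = length(igc_b),
    mean_a = mean(igc_a), mean_b = mean(igc_b), paired = paired
  )
}

#' Paired t test on difference scores
#'
#' One-sample t test of per-subject post-minus-pre differences against
#' zero: `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-tailed.
#'
#' @param deltas numeric vector of difference scores (n >= 2).
#' @return One-row tibble: `t`, `p`, `df`, `n`, `mean_delta`.
#' @export
paired_delta_ttest <- function(deltas) {
  n <- length(deltas)
  if (n < 2) abort("need n >= 2 difference scores")
  if (sd(deltas) == 0) {
    warn("degenerate variance: all difference scores identical")
    return(tibble(t = if (deltas[1] == 0) 0 else Inf,
                  p = if (deltas[1] == 0) 1 else 0,
                  df = n - 1, n = n, mean_delta = deltas[1]))
  }
  ht <- t.test(deltas, mu = 0, alternative = "two.sided")
  tibble(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter), n = n, mean_delta = mean(deltas))
}

#' Brain-behavior correlation
#'
#' Pearson correlation between behavioral change scores (e.g. Fugl-Meyer
#' Assessment differences) and connectivity change scores, with the
#' two-tailed p-value from `t = r sqrt(n-2) / sqrt(1-r^2)`, `df = n - 2`.
#'
#' @param delta_fma,delta_gc equal-length numeric vectors (n >= 3).
#' @return One-row tibble: `r`, `p`, `t`, `df`, `n`.
#' @export
correlate_brain_behavior <- function(delta_fma, delta_gc) {
  if (length(delta_fma) != length(delta_gc)) abort("inputs must match in length")
  if (length(delta_fma) < 3) abort("need n >= 3 for a correlation test")
  if (sd(delta_fma) == 0 || sd(delta_gc) == 0) {
    abort("zero variance in one of the inputs")
  }
  ht <- cor.test(delta_fma, delta_gc, method = "pearson",
                 alternative = "two.sided")
  tibble(
    r = unname(ht$estimate), p = ht$p.value, t = unname(ht$statistic),
    df = unname(ht$parameter), n = length(delta_fma)
  )
}

#' Load the clinical tables
#'
#' Reads the packaged stroke-cohort tables: demographics (participant,
#' age, sex, months post-stroke, MMSE, lesion note) and the per-subject
#' change scores (intervention group, Fugl-Meyer change, connectivity
#' change for LM1->SMA, SMA->LM1, SMA->LPMC), joined on participant.
#'
#' @param table1_path,table2_path TSV paths; default to the packaged
#'   fixtures mirroring the printed tables.
#' @return Tibble with 13 rows, one per stroke survivor.
#' @export
load_clinical_tables <- function(table1_path = NULL, table2_path = NULL) {
  table1_path <- table1_path %||%
    system.file("extdata", "table1_demographics.tsv", package = "lfogcnet")
  table2_path <- table2_path %||%
    system.file("extdata", "table2_delta_scores.tsv", package = "lfogcnet")
  t1 <- readr::read_tsv(table1_path, show_col_types = FALSE)
  t2 <- readr::read_tsv(table2_path, show_col_types = FALSE)
  validate_clinical(t1, c("participant", "age_years", "sex",
                          "post_stroke_months", "mmse", "stroke_location"),
                    table1_path)
  validate_clinical(t2, c("participant", "intervention", "delta_fma",
                          "dgc_lm1_sma", "dgc_sma_lm1", "dgc_sma_lpmc"),
                    table2_path)
  bad_mmse <- which(t1$mmse > 30 | t1$mmse < 0)
  if (length(bad_mmse) > 0) {
    abort(sprintf("row %d of %s: MMSE outside 0..30", bad_mmse[1], table1_path))
  }
  bad_int <- which(!t2$intervention %in% c("MP", "MPPT"))
  if (length(bad_int) > 0) {
    abort(sprintf("row %d of %s: intervention must be MP or MPPT",
                  bad_int[1], table2_path))
  }
  left_join(t1, t2, by = "participant")
}

validate_clinical <- function(tbl, cols, path) {
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(tbl[cols[cols != "stroke_location"]]))
  if (length(bad) > 0) {
    abort(sprintf("malformed row %d in %s", bad[1], path))
  }
  invisible(tbl)
}
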