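#' Simulate a stationary VAR process
#'
#' Draws one subject's T x R series from the exact vector-autoregressive
#' process defined by `spec`.  Innovations are Gaussian with covariance
#' `spec$innovation_cov`; when `band_limited = TRUE` each innovation column
#' is additionally passed through the zero-phase Butterworth band-pass
#' centred on `spec$band_center_hz` (corners `band_center_hz` +/-
#' `spec$band_half_width_hz`)
#' and rescaled to its pre-filter standard deviation, so that region power
#' concentrates in the low-frequency band the analysis targets.
#'
#' @param spec a [network_spec()].
#' @param n_samples number of retained samples T (>= 50).
#' @param burn_in discarded leading samples (>= 10 x model order).
#' @param seed integer seed; the draw is deterministic given
#'   `(spec, n_samples, burn_in, seed)`.
#' @param band_limited shape innovations into the low-frequency band?
#' @param subject_id,group_label metadata attached to the result.
#' @return A [roi_ts()] of dimension `n_samples` x R.
#' @export
simulate_var <- function(spec, n_samples, burn_in = NULL, seed = 1L,
                         band_limited = FALSE, subject_id = "s01",
                         group_label = NA_character_) {
  stopifnot(inherits(spec, "network_spec"))
  if (n_samples < 50) abort("n_samples must be >= 50 for downstream fitting")
  a <- coef_array(spec)
  p <- dim(a)[3]
  if (is.null(burn_in)) burn_in <- max(10L * p, 100L)
  if (burn_in < 10L * p) abort("burn_in must be >= 10x the model order")
  r <- spec$n_regions
  total <- n_samples + burn_in

  innov <- with_seed(seed, {
    z <- matrix(rnorm(total * r), total, r) %*% chol(spec$innovation_cov)
    if (band_limited) {
      half_width <- spec$band_half_width_hz %||% 0.025
      lo <- spec$band_center_hz - half_width
      hi <- spec$band_center_hz + half_width
      z <- apply(z, 2, function(col) {
        f <- zero_phase_bandpass(col, lo, hi, spec$tr_s)
        s <- sd(f)
        if (s > 0) f * (sd(col) / s) else f
      })
    }
    z
  })

  x <- matrix(0, total, r)
  for (t in seq_len(total)) {
    xt <- innov[t, ]
    for (k in seq_len(min(p, t - 1))) {
      xt <- xt + a[, , k] %*% x[t - k, ]
    }
    x[t, ] <- xt
  }
  out <- x[(burn_in + 1):total, , drop = FALSE]
  colnames(out) <- spec$region_names
  roi_ts(out, tr_s = spec$tr_s, subject_id = subject_id,
         group_label = group_label)
}

#' Define a group scenario
#'
#' A cohort of subjects drawn from a common network specification with the
#' edge couplings scaled by a group factor.  Defaults follow the study
#' design this package emulates: 13 able-bodied subjects at full coupling
#' recorded for 237 volumes (7 min 54 s at TR 2 s), stroke sessions of 130
#' volumes with attenuated coupling (scale 0.2), partially restored under
#' mental practice (0.3) and mental practice plus physical therapy (0.8).
#'
#' @param group_label one of `"AB"`, `"SS"`, `"MP"`, `"MPPT"`.
#' @param n_subjects number of subjects (>= 1).
#' @param coupling_scale multiplier on the base edge couplings (>= 0).
#' @param n_samples volumes per subject; defaults to 237 for AB, 130
#'   otherwise.
#' @param seed scenario seed; per-subject seeds are derived from it.
#' @param subject_ids optional explicit subject labels (length
#'   `n_subjects`), used to pair pre/post sessions across scenarios.
#' @return A list of class `group_scenario`.
#' @export
group_scenario <- function(group_label = c("AB", "SS", "MP", "MPPT"),
                           n_subjects = NULL, coupling_scale = NULL,
                           n_samples = NULL, seed = 1L, subject_ids = NULL) {
  group_label <- match.arg(group_label)
  defaults <- list(
    AB = list(n = 13L, scale = 1.0, t = 237L),
    SS = list(n = 13L, scale = 0.2, t = 130L),
    MP = list(n = 6L, scale = 0.3, t = 130L),
    MPPT = list(n = 7L, scale = 0.8, t = 130L)
  )[[group_label]]
  n_subjects <- n_subjects %||% defaults$n
  coupling_scale <- coupling_scale %||% defaults$scale
  n_samples <- n_samples %||% defaults$t
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (coupling_scale < 0) abort("coupling_scale must be >= 0")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("%s%02d", tolower(group_label), seq_len(n_subjects))
  }
  if (length(subject_ids) != n_subjects) {
    abort("subject_ids must have length n_subjects")
  }
  structure(
    list(group_label = group_label, n_subjects = as.integer(n_subjects),
         coupling_scale = coupling_scale, n_samples = as.integer(n_samples),
         seed = as.integer(seed), subject_ids = subject_ids),
    class = "group_scenario"
  )
}

#' Simulate a cohort from a group scenario
#'
#' Scales the base network's couplings by the scenario's group factor
#' (rejecting scales that destabilize the model), then draws each subject
#' with a reproducible per-subject seed and band-limited innovations.
#'
#' @param scenario a [group_scenario()].
#' @param base_spec the unscaled [network_spec()]; default
#'   [motor_network_spec()].
#' @return Named list of [roi_ts()] (one per subject) with the scaled
#'   `network_spec` attached as attribute `"spec"`.
#' @export
simulate_group <- function(scenario, base_spec = motor_network_spec()) {
  stopifnot(inherits(scenario, "group_scenario"))
  spec <- scale_spec(base_spec, scenario$coupling_scale)
  out <- lapply(seq_len(scenario$n_subjects), function(i) {
    simulate_var(
      spec, n_samples = scenario$n_samples,
      seed = child_seed(scenario$seed, i), band_limited = TRUE,
      subject_id = scenario$subject_ids[i],
      group_label = scenario$group_label
    )
  })
  names(out) <- scenario$subject_ids
  attr(out, "spec") <- spec
  attr(out, "scenario") <- scenario
  out
}

#' Simulate per-volume head-motion tables
#'
#' Generates six-parameter motion traces (translations in mm, rotations in
#' degrees, relative to the first volume) for a cohort in which a chosen
#' fraction of subjects violate the exclusion limits (2 mm translation or
#' 1.5 deg rotation) on at least one axis and one volume, while all other
#' subjects stay strictly below both limits.
#'
#' @param n_volumes volumes per subject.
#' @param n_subjects number of subjects.
#' @param violator_fraction fraction in `[0, 1]`; `round(fraction *
#'   n_subjects)` subjects are made violators.
#' @param seed integer seed.
#' @param trans_limit_mm,rot_limit_deg the exclusion limits being violated.
#' @return Tibble with columns `subject_id`, `volume`, `tx`, `ty`, `tz`
#'   (mm), `rx`, `ry`, `rz` (degrees).
#' @export
simulate_motion <- function(n_volumes, n_subjects, violator_fraction = 0,
                            seed = 1L, trans_limit_mm = 2.0,
                            rot_limit_deg = 1.5) {
  if (violator_fraction < 0 || violator_fraction > 1) {
    abort("violator_fraction must be in [0, 1]")
  }
  n_viol <- round(violator_fraction * n_subjects)
  with_seed(seed, {
    violators <- sample(n_subjects, n_viol)
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      # Smooth drift, bounded strictly below 60% of either limit.
      drift <- function(limit) {
        w <- cumsum(rnorm(n_volumes, sd = limit / 50))
        w <- w - w[1]
        peak <- max(abs(w), limit / 1e6)
        w * (0.6 * limit * runif(1, 0.3, 1) / peak)
      }
      m <- cbind(
        drift(trans_limit_mm), drift(trans_limit_mm), drift(trans_limit_mm),
        drift(rot_limit_deg), drift(rot_limit_deg), drift(rot_limit_deg)
      )
      if (i %in% violators) {
        axis <- sample(6, 1)
        vol <- sample(2:n_volumes, 1)
        limit <- if (axis <= 3) trans_limit_mm else rot_limit_deg
        m[vol, axis] <- sign(rnorm(1)) * limit * runif(1, 1.1, 1.8)
      }
      tibble(
        subject_id = sprintf("s%02d", i), volume = seq_len(n_volumes),
        tx = m[, 1], ty = m[, 2], tz = m[, 3],
        rx = m[, 4], ry = m[, 5], rz = m[, 6]
      )
    })
  })
}

#' Simulate behavioral change scores from connectivity change
#'
#' Generates Fugl-Meyer Assessment change scores linearly coupled to
#' per-subject connectivity change with additive Gaussian noise,
#' `dFMA_i = intercept + slope * dGC_i + e_i`, rounded half-away-from-zero
#' to integers (the FMA is integer-scored).
#'
#' @param delta_gc per-subject connectivity change (numeric vector).
#' @param slope,intercept linear coupling (FMA units per iGC unit; FMA
#'   units).
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed.
#' @return Tibble with columns `subject`, `delta_gc`, `delta_fma_raw`
#'   (pre-rounding), `delta_fma` (integer).
#' @export
simulate_behavior <- function(delta_gc, slope = 25, intercept = 2,
                              noise_sd = 3, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  raw <- with_seed(seed, {
    intercept + slope * delta_gc + rnorm(length(delta_gc), sd = noise_sd)
  })
  tibble(
    subject = seq_along(delta_gc), delta_gc = delta_gc,
    delta_fma_raw = raw,
    delta_fma = as.integer(sign(raw) * floor(abs(raw) + 0.5))
  )
}

#' Write a scenario to disk
#'
#' Writes each subject's series in the TSV + JSON sidecar format plus a
#' manifest JSON listing subjects and the ground-truth edges.
#'
#' @param subjects result of [simulate_group()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scenario <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scenario <- attr(subjects, "scenario")
  spec <- attr(subjects, "spec")
  for (id in names(subjects)) {
    write_roi_ts(subjects[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  manifest <- list(
    group_label = scenario$group_label,
    coupling_scale = scenario$coupling_scale,
    seed = scenario$seed,
    subjects = names(subjects),
    region_names = spec$region_names,
    true_edges = as.data.frame(spec$edges)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
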