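#' Study configuration
#'
#' Validated configuration object driving [run_study()]: input mode,
#' analysis band, significance settings, model-order settings, generator
#' settings (synthetic mode) or input paths (files mode), and the seed
#' from which all stage seeds are derived.
#'
#' @param mode `"synthetic"` (simulate the four-group study) or `"files"`
#'   (read series and/or clinical tables from disk).
#' @param band analysis band `c(f1, f2)` in Hz.
#' @param alpha permutation significance level.
#' @param n_perm permutation draws per connection.
#' @param order VAR model order used throughout the study analysis: a
#'   fixed integer (default 3: two poles for the band resonance plus one
#'   coupling lag; information criteria overfit badly on short
#'   band-limited sessions) or `"auto"` for per-fit criterion selection.
#' @param scheme permutation-null scheme, `"cyclic"` (calibrated) or
#'   `"full"`; see [permutation_threshold()].
#' @param n_bias_draws cyclic-surrogate draws used to estimate each
#'   subject's flow-estimator bias (the `igc_corrected` column feeding the
#'   network contrasts); 0 disables correction.
#' @param p_max,criterion VAR order-selection settings (used when `order =
#'   "auto"`).
#' @param n_freq frequency-grid size on `(0, Nyquist]`.
#' @param seed master integer seed.
#' @param coupling,ar_self,band_center_hz,tr_s generator network settings
#'   (see [motor_network_spec()]).
#' @param scales named group coupling scales.
#' @param n_ab_scanned able-bodied subjects scanned (before motion
#'   exclusion).
#' @param violator_fraction fraction of scanned AB subjects violating the
#'   motion limits.
#' @param n_stroke stroke survivors (scanned pre and post).
#' @param n_mp how many of the stroke survivors undergo mental practice
#'   only (the rest undergo MP+PT).
#' @param n_samples named lengths: `AB` and `stroke` session volumes.
#' @param behavior list: `slope`, `intercept`, `noise_sd` of the linear
#'   behavior model and `connection = c(source, target)` used for the
#'   brain-behavior stage.
#' @param network_connections `"truth"` (scenario ground-truth edges;
#'   synthetic mode) or `"ab_significant"` (data-driven set) for the
#'   per-subject network summary.
#' @param apply_filter detrend/band-pass the series before analysis.
#' @param allow_unfiltered permit causality estimation on series that were
#'   never band-pass filtered (refused by default).
#' @param engine `"compiled"` or `"reference"` integrated-flow path.
#' @param paths files mode inputs: `series` (named list, group ->
#'   character vector of TSV paths), optional `table1`, `table2` clinical
#'   TSV paths.
#' @return A list of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "files"),
                         band = c(0.04, 0.1), alpha = 0.01, n_perm = 1000,
                         order = 3L, scheme = c("cyclic", "full"),
                         n_bias_draws = 20L,
                         p_max = 10, criterion = "AIC", n_freq = 512,
                         seed = 1L, coupling = 0.35, ar_self = 0.35,
                         band_center_hz = 0.07, tr_s = 2.0,
                         scales = c(AB = 1.0, SS = 0.2, MP = 0.3, MPPT = 0.8),
                         n_ab_scanned = 17L, violator_fraction = 4 / 17,
                         n_stroke = 13L, n_mp = 6L,
                         n_samples = c(AB = 237L, stroke = 130L),
                         behavior = list(slope = 25, intercept = 2,
                                         noise_sd = 3,
                                         connection = c("SMA", "LPMC")),
                         network_connections = c("truth", "ab_significant"),
                         apply_filter = TRUE, allow_unfiltered = FALSE,
                         engine = c("compiled", "reference"),
                         paths = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  scheme <- match.arg(scheme)
  network_connections <- match.arg(network_connections)
  if (!identical(order, "auto") &&
      (!is.numeric(order) || order < 1 || order != round(order))) {
    abort("order must be a positive integer or \"auto\"")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1)")
  nyq <- 1 / (2 * tr_s)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    abort(sprintf("band must satisfy 0 < f1 < f2 < Nyquist = %g Hz", nyq))
  }
  if (!all(c("AB", "SS", "MP", "MPPT") %in% names(scales))) {
    abort("scales must name AB, SS, MP, MPPT")
  }
  if (n_mp >= n_stroke) abort("n_mp must be below n_stroke")
  if (mode == "files" && is.null(paths)) {
    abort("files mode requires `paths`")
  }
  structure(
    list(mode = mode, band = band, alpha = alpha, n_perm = n_perm,
         order = if (identical(order, "auto")) order else as.integer(order),
         scheme = scheme, n_bias_draws = as.integer(n_bias_draws),
         p_max = p_max, criterion = criterion, n_freq = n_freq,
         seed = as.integer(seed), coupling = coupling, ar_self = ar_self,
         band_center_hz = band_center_hz, tr_s = tr_s, scales = scales,
         n_ab_scanned = as.integer(n_ab_scanned),
         violator_fraction = violator_fraction,
         n_stroke = as.integer(n_stroke), n_mp = as.integer(n_mp),
         n_samples = n_samples, behavior = behavior,
         network_connections = network_connections,
         apply_filter = apply_filter, allow_unfiltered = allow_unfiltered,
         engine = engine, paths = paths),
    class = "study_config"
  )
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate_ab = 1L, motion = 2L, simulate_ss = 3L,
               simulate_mp = 4L, simulate_mppt = 5L, thresholds = 6L,
               behavior_mp = 7L, behavior_mppt = 8L)
  child_seed(config$seed, offsets[[stage]])
}

#' Run the full directed-connectivity study
#'
#' Executes the analysis stages in order: generate or load subject series;
#' motion-based exclusion; linear detrend and band-pass; per-pair causal
#' flow spectra and band integration for every directed region pair;
#' permutation thresholds from the pooled AB + SS sample; group
#' significance and percent difference/modulation; network-level t tests;
#' and the brain-behavior block (paired Fugl-Meyer tests and the
#' connectivity-change correlation).  Every stage seed derives from the
#' master seed, so a rerun with the same configuration reproduces the
#' bundle exactly.
#'
#' @param config a [study_config()].
#' @return A list of class `study_result`; see [report_study()] for the
#'   tabular views.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  log <- character()
  t0 <- Sys.time()

  if (config$mode == "synthetic") {
    loaded <- generate_study_inputs(config)
    log <- c(log, loaded$log)
  } else {
    loaded <- load_study_inputs(config)
    log <- c(log, loaded$log)
  }
  groups <- loaded$groups  # named list of lists of roi_ts (possibly empty)
  clinical <- loaded$clinical

  result <- list(
    config = config,
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("lfogcnet")),
      run_at = format(t0, "%Y-%m-%d")
    )
  )

  if (length(groups) > 0) {
    # -- preprocessing ---------------------------------------------------
    if (config$apply_filter) {
      groups <- purrr::map(groups, function(subjects) {
        purrr::map(subjects, detrend_bandpass,
                   f_lo = config$band[1], f_hi = config$band[2])
      })
    } else {
      unfiltered <- any(purrr::map_lgl(groups, function(subjects) {
        any(!purrr::map_lgl(subjects, ~ isTRUE(attr(.x, "filtered"))))
      }))
      if (unfiltered && !config$allow_unfiltered) {
        abort(paste0(
          "stage preprocess: causal-flow estimation on unfiltered series ",
          "refused; set allow_unfiltered = TRUE to override"
        ))
      }
    }

    # -- per-subject integrated flow ------------------------------------
    subj_index <- 0L
    igc <- purrr::map_dfr(groups, function(subjects) {
      purrr::map_dfr(subjects, function(s) {
        subj_index <<- subj_index + 1L
        one <- tryCatch(
          subject_igc(s, band = config$band, order = config$order,
                      p_max = config$p_max, criterion = config$criterion,
                      n_freq = config$n_freq, engine = config$engine),
          error = function(e) {
            abort(sprintf("stage igc, subject %s: %s",
                          attr(s, "subject_id"), conditionMessage(e)))
          }
        )
        if (config$n_bias_draws > 0) {
          prs <- all_region_pairs(names(s))
          bias <- purrr::map_dfr(seq_len(nrow(prs)), function(i) {
            pr <- c(prs$region1[i], prs$region2[i])
            b <- igc_surrogate_bias(
              s, pr, band = config$band, order = config$order,
              n_draws = config$n_bias_draws,
              seed = child_seed(config$seed, 100L + subj_index),
              p_max = config$p_max, criterion = config$criterion,
              n_freq = config$n_freq
            )
            tibble(source = c(pr[1], pr[2]), target = c(pr[2], pr[1]),
                   igc_bias = as.numeric(b))
          })
          one <- left_join(one, bias, by = c("source", "target")) |>
            mutate(igc_corrected = .data$igc - .data$igc_bias)
        }
        one
      })
    })
    result$subject_igc <- igc

    # -- group-mean power and peaks -------------------------------------
    result$power <- group_power(groups, config)

    # -- permutation thresholds (pooled AB + SS) ------------------------
    pool <- c(groups$AB, groups$SS)
    result$pool_size <- length(pool)
    log <- c(log, sprintf("permutation pool: %d subjects", length(pool)))
    pairs <- all_region_pairs(names(pool[[1]]))
    thr <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      pr <- c(pairs$region1[i], pairs$region2[i])
      th <- permutation_threshold(
        pool, pr, band = config$band, n_perm = config$n_perm,
        alpha = config$alpha, seed = child_seed(stage_seed(config, "thresholds"), i),
        order = config$order, p_max = config$p_max,
        criterion = config$criterion, n_freq = config$n_freq,
        scheme = config$scheme
      )
      tibble(source = c(pr[1], pr[2]), target = c(pr[2], pr[1]),
             threshold = as.numeric(th))
    })
    result$thresholds <- thr

    # -- significance per connection per group --------------------------
    group_means <- igc |>
      group_by(.data$group_label, .data$source, .data$target) |>
      summarise(igc = mean(.data$igc), n = dplyr::n(), .groups = "drop") |>
      left_join(thr, by = c("source", "target")) |>
      mutate(significant = .data$igc > .data$threshold)
    result$group_igc <- group_means

    ab_sig <- group_means |>
      filter(.data$group_label == "AB", .data$significant) |>
      select("source", "target")
    result$significant_ab <- ab_sig
    log <- c(log, sprintf("AB-significant connections: %d", nrow(ab_sig)))

    network_edges <- if (config$network_connections == "truth" &&
                         !is.null(loaded$true_edges)) {
      loaded$true_edges[c("source", "target")]
    } else {
      ab_sig
    }
    result$network_edges <- as_tibble(network_edges)

    # -- percent difference / modulation --------------------------------
    result$percent_changes <- percent_change_table(igc, network_edges, config)

    # -- network-level t tests (on bias-corrected flow when available) ---
    net_col <- if ("igc_corrected" %in% names(igc)) "igc_corrected" else "igc"
    net <- igc |>
      dplyr::semi_join(as_tibble(network_edges), by = c("source", "target")) |>
      group_by(.data$group_label, .data$subject_id) |>
      summarise(network_igc = sum(.data[[net_col]]), .groups = "drop")
    net_value <- function(g) net$network_igc[net$group_label == g]
    comparisons <- list(c("AB", "SS"), c("SS", "MP"), c("SS", "MPPT"),
                        c("MP", "MPPT"))
    result$network_tests <- purrr::map_dfr(comparisons, function(cmp) {
      a <- net_value(cmp[1]); b <- net_value(cmp[2])
      if (length(a) < 2 || length(b) < 2) return(tibble())
      network_ttest(a, b) |>
        mutate(group_a = cmp[1], group_b = cmp[2], .before = 1)
    })
    result$network_subject <- net
  }

  # -- brain-behavior block ----------------------------------------------
  result$behavior <- behavior_block(result, groups, clinical, config)
  result$log <- log
  result$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(result) <- "study_result"
  result
}

generate_study_inputs <- function(config) {
  log <- character()
  spec <- motor_network_spec(
    coupling = config$coupling, ar_self = config$ar_self,
    band_center_hz = config$band_center_hz, tr_s = config$tr_s
  )
  stroke_ids <- sprintf("p%02d", seq_len(config$n_stroke))
  mp_idx <- seq_len(config$n_mp)
  mppt_idx <- setdiff(seq_len(config$n_stroke), mp_idx)

  ab_all <- simulate_group(
    group_scenario("AB", n_subjects = config$n_ab_scanned,
                   coupling_scale = config$scales[["AB"]],
                   n_samples = config$n_samples[["AB"]],
                   seed = stage_seed(config, "simulate_ab")),
    spec
  )
  motion <- simulate_motion(
    n_volumes = config$n_samples[["AB"]], n_subjects = config$n_ab_scanned,
    violator_fraction = config$violator_fraction,
    seed = stage_seed(config, "motion")
  )
  # align motion subject labels with the AB scenario labels
  motion$subject_id <- names(ab_all)[as.integer(sub("^s", "", motion$subject_id))]
  decisions <- motion_exclude(motion, n_volumes = config$n_samples[["AB"]])
  kept <- decisions$subject_id[decisions$keep]
  excluded <- setdiff(names(ab_all), kept)
  log <- c(log, sprintf(
    "motion exclusion: kept %d of %d able-bodied subjects (excluded: %s)",
    length(kept), config$n_ab_scanned,
    if (length(excluded)) paste(excluded, collapse = ", ") else "none"
  ))
  ab <- ab_all[intersect(names(ab_all), kept)]

  make <- function(group, ids, idx, stage) {
    sims <- simulate_group(
      group_scenario(group, n_subjects = length(ids),
                     coupling_scale = config$scales[[group]],
                     n_samples = config$n_samples[["stroke"]],
                     seed = stage_seed(config, stage), subject_ids = ids),
      spec
    )
    sims
  }
  ss <- make("SS", stroke_ids, seq_len(config$n_stroke), "simulate_ss")
  mp <- make("MP", stroke_ids[mp_idx], mp_idx, "simulate_mp")
  mppt <- make("MPPT", stroke_ids[mppt_idx], mppt_idx, "simulate_mppt")

  list(
    groups = list(AB = ab, SS = ss, MP = mp, MPPT = mppt),
    clinical = NULL,
    true_edges = spec$edges,
    motion = motion, motion_decisions = decisions, log = log
  )
}

load_study_inputs <- function(config) {
  paths <- config$paths
  log <- character()
  groups <- list()
  if (!is.null(paths$series)) {
    groups <- purrr::imap(paths$series, function(files, group) {
      subjects <- lapply(files, read_roi_ts)
      names(subjects) <- vapply(subjects, attr, "", "subject_id")
      log <<- c(log, sprintf("loaded %d series for group %s",
                             length(subjects), group))
      subjects
    })
  }
  clinical <- NULL
  if (!is.null(paths$table1) || !is.null(paths$table2)) {
    clinical <- load_clinical_tables(paths$table1, paths$table2)
    log <- c(log, sprintf("loaded clinical tables: %d records", nrow(clinical)))
  }
  list(groups = groups, clinical = clinical, true_edges = NULL, log = log)
}

group_power <- function(groups, config) {
  purrr::imap_dfr(groups, function(subjects, group) {
    spectra <- purrr::map(subjects, function(s) {
      p <- if (identical(config$order, "auto")) {
        as.integer(select_order(s, p_max = config$p_max,
                                criterion = config$criterion))
      } else {
        config$order
      }
      var_spectrum(fit_var(s, p),
                   gc_freq_grid(tr_of(s), config$n_freq))$power
    })
    mean_power <- Reduce(`+`, spectra) / length(spectra)
    freqs <- gc_freq_grid(tr_of(subjects[[1]]), config$n_freq)
    purrr::map_dfr(colnames(mean_power), function(region) {
      tibble(
        group_label = group, region = region, freq_hz = freqs,
        power = mean_power[, region]
      )
    })
  })
}

#' Group-mean power peaks
#'
#' Peak frequency of each group-mean region power spectrum inside the
#' analysis band.
#'
#' @param result a `study_result`.
#' @return Tibble `group_label`, `region`, `peak_hz`.
#' @export
power_peaks <- function(result) {
  stopifnot(inherits(result, "study_result"))
  result$power |>
    group_by(.data$group_label, .data$region) |>
    summarise(
      peak_hz = peak_frequency(.data$freq_hz, .data$power,
                               band = result$config$band),
      .groups = "drop"
    )
}

percent_change_table <- function(igc, network_edges, config) {
  means <- igc |>
    dplyr::semi_join(as_tibble(network_edges), by = c("source", "target")) |>
    group_by(.data$group_label, .data$source, .data$target) |>
    summarise(igc = mean(.data$igc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group_label", values_from = "igc")

  # Matched pre-treatment references: SS means over the subjects who later
  # underwent each intervention.
  mp_ids <- sprintf("p%02d", seq_len(config$n_mp))
  ss_sub <- igc |>
    filter(.data$group_label == "SS") |>
    dplyr::semi_join(as_tibble(network_edges), by = c("source", "target")) |>
    mutate(arm = ifelse(.data$subject_id %in% mp_ids, "SS_mp", "SS_mppt")) |>
    group_by(.data$arm, .data$source, .data$target) |>
    summarise(igc = mean(.data$igc), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "igc")
  means <- left_join(means, ss_sub, by = c("source", "target"))

  means |>
    mutate(
      D_ss = if (all(c("SS", "AB") %in% names(means))) {
        percent_difference(.data$SS, .data$AB)
      } else NA_real_,
      M_mp = if (all(c("MP", "SS_mp") %in% names(means))) {
        percent_modulation(.data$MP, .data$SS_mp)
      } else NA_real_,
      M_mppt = if (all(c("MPPT", "SS_mppt") %in% names(means))) {
        percent_modulation(.data$MPPT, .data$SS_mppt)
      } else NA_real_
    )
}

behavior_block <- function(result, groups, clinical, config) {
  conn <- config$behavior$connection
  if (!is.null(clinical)) {
    col <- paste0("dgc_", tolower(conn[1]), "_", tolower(conn[2]))
    if (!col %in% names(clinical)) {
      abort(sprintf("clinical tables carry no change scores for %s->%s",
                    conn[1], conn[2]))
    }
    per_group <- purrr::map_dfr(c("MP", "MPPT"), function(g) {
      rows <- clinical[clinical$intervention == g, ]
      ct <- correlate_brain_behavior(rows$delta_fma, rows[[col]])
      pt <- paired_delta_ttest(rows$delta_fma)
      tibble(intervention = g, connection = paste0(conn[1], "->", conn[2]),
             n = nrow(rows), r = ct$r, r_p = ct$p,
             fma_t = pt$t, fma_p = pt$p)
    })
    return(list(source = "clinical_tables", table = per_group,
                records = clinical))
  }
  if (length(groups) == 0 || is.null(result$subject_igc)) return(NULL)

  igc <- result$subject_igc
  conn_igc <- igc |>
    filter(.data$source == conn[1], .data$target == conn[2]) |>
    select("group_label", "subject_id", "igc")
  pre <- conn_igc |> filter(.data$group_label == "SS")
  per_group <- purrr::map_dfr(c("MP", "MPPT"), function(g) {
    post <- conn_igc |> filter(.data$group_label == g)
    if (nrow(post) < 3) return(tibble())
    matched <- pre[match(post$subject_id, pre$subject_id), ]
    delta_gc <- post$igc - matched$igc
    beh <- simulate_behavior(
      delta_gc, slope = config$behavior$slope,
      intercept = config$behavior$intercept,
      noise_sd = config$behavior$noise_sd,
      seed = stage_seed(config, paste0("behavior_", tolower(g)))
    )
    ct <- correlate_brain_behavior(beh$delta_fma, delta_gc)
    pt <- paired_delta_ttest(beh$delta_fma)
    tibble(intervention = g, connection = paste0(conn[1], "->", conn[2]),
           n = nrow(post), r = ct$r, r_p = ct$p, fma_t = pt$t, fma_p = pt$p)
  })
  list(source = "synthetic", table = per_group)
}
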