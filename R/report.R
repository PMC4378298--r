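#' Tabular report of a study run
#'
#' Collapses a [run_study()] bundle into the numeric content of the
#' study's figures: integrated causal flow per connection and group with
#' significance stars, percent difference and modulation per connection
#' (rounded to whole percent, as conventionally reported), network-level
#' t tests, power peaks, and the brain-behavior block.
#'
#' @param result a `study_result`.
#' @return Named list of tibbles: `igc_table`, `percent_table`,
#'   `network_table`, `power_peaks`, `behavior_table` (those applicable).
#' @export
report_study <- function(result) {
  stopifnot(inherits(result, "study_result"))
  has_series <- !is.null(result$subject_igc)
  required <- if (has_series) {
    c("group_igc", "thresholds", "percent_changes", "network_tests", "power")
  } else {
    "behavior"
  }
  absent <- required[vapply(required, function(k) is.null(result[[k]]),
                            logical(1))]
  if (length(absent) > 0) {
    abort(paste0("result bundle is missing stage outputs: ",
                 paste(absent, collapse = ", ")))
  }
  out <- list()
  if (has_series) {
    out$igc_table <- result$group_igc |>
      mutate(
        connection = paste0(.data$source, "->", .data$target),
        star = ifelse(.data$significant, "*", "")
      ) |>
      select("connection", "group_label", "igc", "threshold",
             "significant", "star")
    out$percent_table <- result$percent_changes |>
      mutate(
        connection = paste0(.data$source, "->", .data$target),
        across(dplyr::any_of(c("D_ss", "M_mp", "M_mppt")), round)
      ) |>
      select("connection", dplyr::any_of(c("D_ss", "M_mp", "M_mppt")))
    out$network_table <- result$network_tests
    out$power_peaks <- power_peaks(result)
  }
  if (!is.null(result$behavior)) {
    out$behavior_table <- result$behavior$table |>
      mutate(r_p = round(.data$r_p, 2))
  }
  out
}

#' Write a study bundle to disk
#'
#' Writes the report tables as TSV plus a JSON bundle carrying the
#' provenance (config hash, seed, package version), thresholds,
#' group-mean flows, tests, and the run log.
#'
#' @param result a `study_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- report_study(result)
  for (name in names(rep)) {
    readr::write_tsv(rep[[name]], file.path(dir, paste0(name, ".tsv")))
  }
  bundle <- list(
    provenance = result$provenance,
    config = unclass(result$config),
    pool_size = result$pool_size,
    thresholds = result$thresholds,
    group_igc = result$group_igc,
    network_tests = result$network_tests,
    behavior = result$behavior$table,
    log = result$log
  )
  jsonlite::write_json(bundle, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> mode %s, seed %d, config %s\n",
              x$config$mode, x$config$seed,
              substr(x$provenance$config_hash, 1, 8)))
  if (!is.null(x$pool_size)) {
    cat(sprintf("  permutation pool: %d subjects\n", x$pool_size))
  }
  if (!is.null(x$significant_ab)) {
    cat(sprintf("  AB-significant connections: %d\n", nrow(x$significant_ab)))
  }
  if (!is.null(x$behavior)) {
    cat(sprintf("  behavior block: %s\n", x$behavior$source))
  }
  invisible(x)
}
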