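#' ROI time-series container
#'
#' One subject's region-by-time recording: a tibble with one column per
#' region and one row per volume, carrying the sampling interval and subject
#' metadata as attributes.  All analysis functions in the package accept and
#' return this shape.
#'
#' @param data numeric matrix or data frame, T rows (volumes) by R columns
#'   (regions).  Column names become region names.
#' @param tr_s sampling interval (repetition time) in seconds.
#' @param subject_id subject label.
#' @param group_label group label, one of `"AB"`, `"SS"`, `"MP"`, `"MPPT"`,
#'   or `NA`.
#' @param filtered logical; has the series been detrended and band-pass
#'   filtered?
#'
#' @return A tibble of class `roi_ts`.
#' @export
roi_ts <- function(data, tr_s, subject_id = "s01", group_label = NA_character_,
                   filtered = FALSE) {
  data <- as.data.frame(data)
  if (any(!vapply(data, is.numeric, logical(1)))) {
    abort("all region columns must be numeric")
  }
  if (anyNA(data)) abort("ROI time series must not contain missing values")
  if (is.null(names(data)) || anyDuplicated(names(data))) {
    abort("region names must be present and unique")
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    abort("tr_s must be a positive scalar (seconds)")
  }
  if (!is.na(group_label) &&
      !group_label %in% c("AB", "SS", "MP", "MPPT")) {
    abort("group_label must be one of AB, SS, MP, MPPT (or NA)")
  }
  out <- as_tibble(data)
  attr(out, "tr_s") <- tr_s
  attr(out, "subject_id") <- subject_id
  attr(out, "group_label") <- group_label
  attr(out, "filtered") <- isTRUE(filtered)
  class(out) <- c("roi_ts", class(out))
  out
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf(
    "<roi_ts> subject %s, group %s, %d volumes x %d regions, TR %g s%s\n",
    attr(x, "subject_id"), attr(x, "group_label"), nrow(x), ncol(x),
    attr(x, "tr_s"), if (isTRUE(attr(x, "filtered"))) ", filtered" else ""
  ))
  NextMethod()
}

ts_matrix <- function(series) {
  m <- as.matrix(as.data.frame(lapply(series, as.numeric)))
  colnames(m) <- names(series)
  m
}

tr_of <- function(series) {
  tr <- attr(series, "tr_s")
  if (is.null(tr)) abort("series has no tr_s attribute; build it with roi_ts()")
  tr
}

#' Nyquist frequency of a series
#'
#' @param series a [roi_ts()] object (or anything carrying a `tr_s` attribute).
#' @return Nyquist frequency in Hz, `1 / (2 * tr_s)`.
#' @export
nyquist <- function(series) 1 / (2 * tr_of(series))

#' Write / read ROI time series as TSV with a JSON sidecar
#'
#' The on-disk format is a plain TSV (columns = region names, one row per
#' volume) plus `<path>.json` holding `tr_s`, `subject_id`, `group_label`,
#' `filtered`, and optionally the generating seed.
#'
#' @param series a [roi_ts()] object.
#' @param path TSV file path.
#' @param seed optional generating seed recorded in the sidecar.
#' @return `write_roi_ts()` returns `path` invisibly; `read_roi_ts()`
#'   returns a [roi_ts()].
#' @export
write_roi_ts <- function(series, path, seed = NULL) {
  readr::write_tsv(as_tibble(as.data.frame(series)), path)
  side <- list(
    tr_s = tr_of(series),
    subject_id = attr(series, "subject_id"),
    group_label = attr(series, "group_label"),
    filtered = isTRUE(attr(series, "filtered"))
  )
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_roi_ts
#' @export
read_roi_ts <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) abort(paste0("missing sidecar ", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  dat <- readr::read_tsv(path, show_col_types = FALSE)
  roi_ts(dat,
    tr_s = side$tr_s, subject_id = side$subject_id,
    group_label = side$group_label %||% NA_character_,
    filtered = isTRUE(side$filtered)
  )
}
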