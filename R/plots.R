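#' Plot causal-flow spectra for a region pair
#'
#' The four Geweke interdependence spectra (total, both directed flows,
#' instantaneous) against frequency, with the analysis band shaded.
#'
#' @param object a `gc_spectrum` from [pairwise_gc()].
#' @param band optional band `c(f1, f2)` Hz to shade.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gc_spectrum <- function(object, band = c(0.04, 0.1), ...) {
  pair <- attr(object, "pair")
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"freq_hz", names_to = "measure",
                        values_to = "value") |>
    mutate(measure = dplyr::recode(.data$measure,
      m_total = "total",
      m_forward = paste0(pair[1], " → ", pair[2]),
      m_backward = paste0(pair[2], " → ", pair[1]),
      m_inst = "instantaneous"
    ))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$freq_hz, y = .data$value,
                                          colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "interdependence",
                  colour = NULL,
                  title = paste0("Spectral causal flow: ", pair[1], " / ",
                                 pair[2]))
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}

#' Plot region power spectra of a fitted model
#'
#' @param object a `var_spectrum` from [var_spectrum()].
#' @param band optional band to shade.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.var_spectrum <- function(object, band = c(0.04, 0.1), ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$freq_hz, y = .data$power,
                                    colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power", colour = NULL)
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08)
  }
  p
}

#' Plot group-mean integrated causal flow per connection
#'
#' Bar chart of the group-mean band-integrated flow for each connection,
#' with the permutation threshold marked.
#'
#' @param result a `study_result` from [run_study()].
#' @return A ggplot object.
#' @export
plot_group_igc <- function(result) {
  stopifnot(inherits(result, "study_result"))
  dat <- result$group_igc |>
    mutate(connection = paste0(.data$source, "→", .data$target))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group_label, y = .data$igc,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~connection) +
    ggplot2::labs(x = NULL, y = "integrated causal flow",
                  fill = "significant")
}
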