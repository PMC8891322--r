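# ggplot2 views of the package's result types.

#' Plot a blood sample table
#'
#' Radioactivity curves (plasma, whole blood) on one panel and metabolite
#' fractions on another, against time on the shared reference scale.
#'
#' @param table A blood sample tibble with a `time` column.
#' @return A ggplot object.
#' @export
plot_blood_table <- function(table) {
  stopifnot(is.data.frame(table), "time" %in% names(table))
  long <- tidyr::pivot_longer(as_tibble(table), -"time",
                              names_to = "quantity", values_to = "value")
  long <- filter(long, !is.na(.data$value))
  long$panel <- ifelse(grepl("fraction", long$quantity),
                       "fraction", "radioactivity (Bq/mL)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since time zero (s)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated time-activity curve
#'
#' @param spec A [study_spec()].
#' @param region_scale,stream Passed to [simulate_tac()].
#' @return A ggplot object of frame activity vs frame midpoint time.
#' @export
plot_tac <- function(spec, region_scale = 1, stream = 0L) {
  tac <- simulate_tac(spec, region_scale, stream)
  dat <- tibble(time = spec$frame_times_start + spec$frame_durations / 2,
                activity = tac)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$activity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "frame midpoint (s since time zero)",
                  y = "activity (Bq/mL)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a validation report
#'
#' Bar chart of finding counts per code, coloured by severity.
#'
#' @param object A `petbids_report` from [validate_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.petbids_report <- function(object, ...) {
  counts <- dplyr::count(object$findings, .data$code, .data$severity)
  if (nrow(counts) == 0L) {
    counts <- tibble(code = "none", severity = "ok", n = 0L)
  }
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$code, y = .data$n,
                                       fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(error = "#b2182b",
                                          warning = "#ef8a62",
                                          ok = "#67a9cf")) +
    ggplot2::labs(x = NULL, y = "findings", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
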