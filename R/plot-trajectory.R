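#' Plot a solved PKPD trajectory
#'
#' Faceted time profiles of a [solve_pk()] / [solve_pkpd()] result: activity
#' amounts per compartment, tumor concentration and (when present) the
#' effect-compartment level and PSA. Dose times show as vertical marks when
#' a regimen is supplied.
#'
#' @param trajectory A trajectory tibble.
#' @param regimen Optional [regimen()] whose dose times are marked.
#' @param log_y Use a log10 PSA/amount axis (default linear).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, regimen = NULL, log_y = FALSE) {
  keep <- intersect(c("A1", "A2", "A3", "A4", "A5", "C_tumor", "Ce", "PSA"),
                    names(trajectory))
  labels <- c(A1 = "central (MBq)", A2 = "salivary glands (MBq)",
              A3 = "kidneys (MBq)", A4 = "tumor (MBq)",
              A5 = "remaining tissue (MBq)", C_tumor = "C_tumor (MBq/L)",
              Ce = "effect compartment (MBq/L)", PSA = "PSA (ug/L)")
  long <- trajectory |>
    dplyr::select(dplyr::all_of(c("time", keep))) |>
    tidyr::pivot_longer(-"time", names_to = "state") |>
    dplyr::mutate(state = factor(labels[.data$state],
                                 levels = unname(labels[keep])))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time / (7 * 24),
                                          .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (weeks)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(regimen)) {
    p <- p + ggplot2::geom_vline(xintercept = regimen$dose_events$time /
                                   (7 * 24),
                                 linetype = "dotted", alpha = 0.5)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}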