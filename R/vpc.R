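#' Simulation-band visual predictive check summary
#'
#' Plain (non-prediction-corrected) simulation bands: the population is
#' re-simulated `n_reps` times with fresh random effects, and per observation
#' time the median and the 10th/90th percentiles of simulated PSA are
#' summarised across subjects within each replicate; 95 percent confidence
#' intervals of each percentile are taken across replicates.
#'
#' @param regimen A [regimen()] / [build_regimen()].
#' @param times Observation times (h) at which bands are computed.
#' @param n_subjects Subjects per replicate.
#' @param n_reps Number of simulation replicates (>= 100 for stable CIs; the
#'   function accepts fewer for exploratory use).
#' @param params,pd Population parameter objects.
#' @param spec,vp Covariate and variability specifications.
#' @param seed Integer seed.
#' @param probs Percentiles to track (default median and 10th/90th).
#' @return A tibble of class `vpc_summary`: `time`, `percentile`, `estimate`
#'   (mean across replicates), `lower`, `upper` (95 percent CI across
#'   replicates).
#' @export
vpc_summary <- function(regimen, times, n_subjects, n_reps = 100,
                        params = pk_parameters(), pd = pd_parameters(),
                        spec = covariate_spec(),
                        vp = variability_parameters(), seed = NULL,
                        probs = c(0.1, 0.5, 0.9)) {
  if (!is.null(seed)) set.seed(seed)
  reps <- purrr::map(seq_len(n_reps), function(r) {
    pop <- generate_virtual_population(n_subjects, seed = NULL, spec = spec,
                                       vp = vp,
                                       n_occasions = nrow(regimen$dose_events))
    sim <- simulate_population(pop, regimen, params, pd, times = times,
                               keep_trajectories = TRUE)
    sim$trajectories |>
      dplyr::filter(.data$time %in% times) |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(value = list(stats::quantile(.data$PSA, probs)),
                       .groups = "drop") |>
      tidyr::unnest_longer("value", indices_to = "percentile") |>
      dplyr::mutate(rep = r)
  })
  dplyr::bind_rows(reps) |>
    dplyr::group_by(.data$time, .data$percentile) |>
    dplyr::summarise(estimate = mean(.data$value),
                     lower = stats::quantile(.data$value, 0.025),
                     upper = stats::quantile(.data$value, 0.975),
                     .groups = "drop") |>
    structure(class = c("vpc_summary", "tbl_df", "tbl", "data.frame"))
}

#' Plot a visual predictive check band
#'
#' @param object A [vpc_summary()] result.
#' @param observations Optional tibble of observed PSA (`time`, `value`) to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vpc_summary <- function(object, observations = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time / (7 * 24))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      group = .data$percentile),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate,
                                    group = .data$percentile,
                                    linetype = .data$percentile)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (weeks)", y = "PSA (ug/L)",
                  linetype = "percentile") +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(data = observations,
                                 ggplot2::aes(.data$time / (7 * 24),
                                              .data$value),
                                 inherit.aes = FALSE, alpha = 0.5)
  }
  p
}
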