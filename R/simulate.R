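#' Classify PSA response of a simulated trajectory
#'
#' End-of-treatment endpoints on the model-predicted (noise-free) PSA:
#' response is a >= 50 percent decrease versus baseline (inclusive at exactly
#' half), stable disease is no increase (inclusive at exactly baseline);
#' response implies stable disease.
#'
#' @param trajectory A tibble from [solve_pkpd()] (needs `time` and `PSA`).
#' @param baseline_PSA Baseline PSA (ug/L); defaults to PSA at the earliest
#'   time point.
#' @param t_end Evaluation time (h); must be covered by the trajectory.
#' @return A one-row tibble: `psa_end`, `pct_change`, `response`, `stable`,
#'   `progression`.
#' @export
classify_response <- function(trajectory, baseline_PSA = NULL, t_end = NULL) {
  stopifnot(all(c("time", "PSA") %in% names(trajectory)))
  if (is.null(t_end)) t_end <- max(trajectory$time)
  if (t_end > max(trajectory$time) || t_end < min(trajectory$time)) {
    stop("t_end outside the simulated time range", call. = FALSE)
  }
  if (is.null(baseline_PSA)) {
    baseline_PSA <- trajectory$PSA[which.min(trajectory$time)]
  }
  psa_end <- stats::approx(trajectory$time, trajectory$PSA, xout = t_end)$y
  tibble::tibble(
    psa_end = psa_end,
    pct_change = 100 * (psa_end - baseline_PSA) / baseline_PSA,
    response = psa_end <= 0.5 * baseline_PSA,
    stable = psa_end <= baseline_PSA,
    progression = psa_end > baseline_PSA
  )
}

#' Simulate a virtual population under a dosing regimen
#'
#' Solves the individual PKPD system for every subject of a virtual
#' population (own covariates, inter-individual effects and per-cycle
#' inter-occasion effects; everyone completes the full regimen) and
#' classifies the end-of-treatment PSA endpoints on the noise-free
#' individual prediction. Residual error plays no role here; it belongs to
#' dataset emulation ([generate_spect_dataset()], [generate_psa_series()]).
#' The PSA kill terms are driven by the decay-corrected tumor concentration
#' (the estimation scale of the kill coefficients; see [solve_pkpd()]).
#'
#' @param pop A [generate_virtual_population()] tibble.
#' @param regimen A [regimen()] / [build_regimen()].
#' @param params Population [pk_parameters()].
#' @param pd Population [pd_parameters()].
#' @param t_end Endpoint evaluation time (h); default the regimen horizon
#'   (24 weeks after start for the clinical regimens).
#' @param times Output grid passed to the solver; default covers dose events
#'   plus weekly points and `t_end` (endpoints only need `t_end`, a coarse
#'   grid keeps population runs fast).
#' @param keep_trajectories Keep per-subject trajectories (memory-heavy for
#'   large `n`); default `FALSE`.
#' @param engine Solver engine, see [solve_pkpd()].
#' @param psa0_form Baseline-PSA covariate form, see [individualize()].
#' @return An object of class `population_simulation`: list with `endpoints`
#'   (tibble: id, WT, TV, baseline PSA, end PSA, flags), `rates` (response /
#'   stable-disease percentages), `regimen`, `n`, and optionally
#'   `trajectories` (tibble with `id` column).
#' @seealso [tidy.population_simulation()], [glance.population_simulation()],
#'   [autoplot.population_simulation()]
#' @export
simulate_population <- function(pop, regimen, params = pk_parameters(),
                                pd = pd_parameters(), t_end = NULL,
                                times = NULL, keep_trajectories = FALSE,
                                engine = c("C", "R"),
                                psa0_form = c("literal", "centered")) {
  engine <- match.arg(engine)
  psa0_form <- match.arg(psa0_form)
  stopifnot(inherits(pop, "virtual_population") || is.data.frame(pop))
  if (is.null(t_end)) t_end <- regimen$horizon
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, regimen$horizon, by = 7 * 24), t_end)))
  }
  eta_cols <- grep("^eta_", names(pop), value = TRUE)
  n <- nrow(pop)

  rows <- purrr::map(seq_len(n), function(i) {
    eta <- stats::setNames(as.numeric(pop[i, eta_cols]), eta_cols)
    ind <- individualize(params, pd,
                         covariate_set(WT = pop$WT[i], TV = pop$TV[i]),
                         eta = eta, iov_k14 = pop$iov_k14[[i]],
                         n_cycles = nrow(regimen$dose_events),
                         psa0_form = psa0_form)
    traj <- tryCatch(
      .solve_core(ind, regimen, times, "corrected", engine, with_pd = TRUE),
      error = function(e) {
        stop(sprintf("subject %s: %s", pop$id[i], conditionMessage(e)),
             call. = FALSE)
      })
    cls <- classify_response(traj, baseline_PSA = ind$pd$PSA0, t_end = t_end)
    list(endpoint = dplyr::bind_cols(
      tibble::tibble(id = pop$id[i], WT = pop$WT[i], TV = pop$TV[i],
                     baseline_PSA = ind$pd$PSA0), cls),
      traj = if (keep_trajectories) dplyr::mutate(traj, id = pop$id[i],
                                                  .before = 1) else NULL)
  })
  endpoints <- dplyr::bind_rows(purrr::map(rows, "endpoint"))
  res <- structure(
    list(endpoints = endpoints,
         rates = c(response = 100 * mean(endpoints$response),
                   stable = 100 * mean(endpoints$stable)),
         regimen = regimen$name, n = n, t_end = t_end),
    class = "population_simulation"
  )
  if (keep_trajectories) {
    res$trajectories <- dplyr::bind_rows(purrr::map(rows, "traj"))
  }
  res
}

#' @export
print.population_simulation <- function(x, ...) {
  cat("<population_simulation>", x$n, "subjects, regimen", x$regimen, "\n")
  cat(sprintf("  response (>=50%% PSA decrease at %.0f wk): %.1f%%\n",
              x$t_end / (7 * 24), x$rates[["response"]]))
  cat(sprintf("  stable disease (no PSA increase):          %.1f%%\n",
              x$rates[["stable"]]))
  invisible(x)
}

#' Tidy a population simulation into per-subject endpoints
#'
#' @param x A `population_simulation`.
#' @param ... Unused.
#' @return The per-subject endpoint tibble.
#' @export
tidy.population_simulation <- function(x, ...) x$endpoints

#' One-row summary of a population simulation
#'
#' @param x A `population_simulation`.
#' @param ... Unused.
#' @return A one-row tibble: regimen, n, response and stable-disease rates
#'   (percent) with binomial Monte-Carlo standard errors.
#' @export
glance.population_simulation <- function(x, ...) {
  p_r <- x$rates[["response"]] / 100
  p_s <- x$rates[["stable"]] / 100
  tibble::tibble(
    regimen = x$regimen, n = x$n,
    response_pct = 100 * p_r, stable_pct = 100 * p_s,
    response_se_pct = 100 * sqrt(p_r * (1 - p_r) / x$n),
    stable_se_pct = 100 * sqrt(p_s * (1 - p_s) / x$n)
  )
}

#' Plot simulated per-subject PSA endpoints
#'
#' Waterfall-style plot of percent PSA change at the evaluation time, colored
#' by endpoint class.
#'
#' @param object A `population_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_simulation <- function(object, ...) {
  df <- dplyr::arrange(object$endpoints, .data$pct_change)
  df$rank <- seq_len(nrow(df))
  df$class <- dplyr::case_when(df$response ~ "response (>= -50%)",
                               df$stable ~ "stable disease",
                               TRUE ~ "progression")
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, pmin(.data$pct_change, 200),
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(0, -50), linetype = "dashed") +
    ggplot2::labs(x = "subject (ranked)", y = "PSA change vs baseline (%)",
                  fill = NULL,
                  title = paste0("Simulated PSA endpoints - ",
                                 object$regimen)) +
    ggplot2::theme_minimal()
}
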