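#' Tumor time-integrated activity over a window
#'
#' Trapezoid integral of the tumor activity concentration over
#' `[t0, t_end]`, converted to MBq h/mL. The default window for the clinical
#' regimens is the first twelve weeks (first two treatment cycles, including
#' wash-out before any third exposure). On a decay-corrected trajectory
#' (canonical mode) the result is on the same scale as the clinical
#' exposure-response thresholds; a physical-mode trajectory yields the true
#' dosimetric time-integrated activity instead.
#'
#' @param trajectory A tibble from [solve_pk()] / [solve_pkpd()], with
#'   columns `time` and `C_tumor` (MBq/L).
#' @param window Numeric length-2 `(t0, t_end)` in hours; must be covered by
#'   the trajectory.
#' @return Time-integrated activity concentration, MBq h/mL.
#' @export
tumor_auc <- function(trajectory, window = c(0, 12 * 7 * 24)) {
  stopifnot(all(c("time", "C_tumor") %in% names(trajectory)),
            length(window) == 2, window[2] > window[1])
  tr <- trajectory[order(trajectory$time), ]
  if (window[1] < min(tr$time) - 1e-9 || window[2] > max(tr$time) + 1e-9) {
    stop("integration window outside the trajectory", call. = FALSE)
  }
  ## close the window exactly by interpolation
  tt <- sort(unique(c(window, tr$time[tr$time > window[1] &
                                        tr$time < window[2]])))
  cc <- stats::approx(tr$time, tr$C_tumor, xout = tt)$y
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2) / 1000
}

#' Exposure-response regression of PSA change on tumor AUC
#'
#' Ordinary least squares of the percent PSA change (nadir or last
#' measurement versus baseline) on the tumor time-integrated activity over
#' the first two cycles. Formal inference is intentionally not reported:
#' individually estimated exposures are not independent observations.
#'
#' @param exposures A tibble with columns `auc_tumor` and the chosen endpoint
#'   column (`pct_change_nadir` or `pct_change_last`), one row per subject.
#' @param endpoint `"nadir"` or `"last"`.
#' @return A list of class `exposure_response_fit`: `slope`, `intercept`,
#'   `endpoint`, `n`, `r_squared` and the underlying `lm` fit.
#' @export
fit_exposure_response <- function(exposures, endpoint = c("nadir", "last")) {
  endpoint <- match.arg(endpoint)
  col <- paste0("pct_change_", endpoint)
  stopifnot(all(c("auc_tumor", col) %in% names(exposures)))
  df <- tibble::tibble(auc = exposures$auc_tumor,
                       pct = exposures[[col]])
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3 || length(unique(df$auc)) < 2) {
    stop("need >= 3 records with distinct AUC values", call. = FALSE)
  }
  fit <- stats::lm(pct ~ auc, data = df)
  tss <- sum((df$pct - mean(df$pct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         endpoint = endpoint, n = nrow(df),
         r_squared = r2, fit = fit),
    class = "exposure_response_fit"
  )
}

#' Tumor AUC threshold for a target PSA change
#'
#' Inverts the fitted exposure-response line to the exposure at which the
#' expected PSA change reaches `target_pct` (default -50, the response
#' definition). Requires a negative slope; a non-negative slope means no
#' attainable threshold.
#'
#' @param fit An [fit_exposure_response()] result, or a list with `slope` and
#'   `intercept`.
#' @param target_pct Target percent PSA change (default -50).
#' @return Threshold exposure, MBq h/mL.
#' @export
auc_threshold <- function(fit, target_pct = -50) {
  if (fit$slope >= 0) {
    stop("slope must be negative for an attainable threshold", call. = FALSE)
  }
  (target_pct - fit$intercept) / fit$slope
}

#' Per-subject exposure-response records from a simulated cohort
#'
#' Builds the exposure-response analysis table for a virtual cohort: each
#' subject's tumor AUC over the exposure window and the percent PSA change at
#' nadir and at the last time point of the observation window.
#'
#' @param pop A [generate_virtual_population()] tibble.
#' @param regimen A regimen.
#' @param params,pd Population parameters.
#' @param auc_window Exposure window (h), default first 12 weeks.
#' @param psa_window PSA observation window (h) for nadir/last endpoints,
#'   default the regimen horizon.
#' @param engine Solver engine.
#' @return A tibble: `id`, `auc_tumor`, `baseline_PSA`, `pct_change_nadir`,
#'   `pct_change_last`.
#' @export
exposure_records <- function(pop, regimen, params = pk_parameters(),
                             pd = pd_parameters(),
                             auc_window = c(0, 12 * 7 * 24),
                             psa_window = NULL, engine = c("C", "R")) {
  engine <- match.arg(engine)
  if (is.null(psa_window)) psa_window <- c(0, regimen$horizon)
  eta_cols <- grep("^eta_", names(pop), value = TRUE)
  times <- sort(unique(c(seq(0, regimen$horizon, by = 24), auc_window,
                         psa_window)))
  purrr::map_dfr(seq_len(nrow(pop)), function(i) {
    eta <- stats::setNames(as.numeric(pop[i, eta_cols]), eta_cols)
    ind <- individualize(params, pd,
                         covariate_set(WT = pop$WT[i], TV = pop$TV[i]),
                         eta = eta, iov_k14 = pop$iov_k14[[i]],
                         n_cycles = nrow(regimen$dose_events))
    traj <- .solve_core(ind, regimen, times, "corrected", engine,
                        with_pd = TRUE)
    in_win <- traj$time >= psa_window[1] & traj$time <= psa_window[2]
    psa <- traj$PSA[in_win]
    base <- ind$pd$PSA0
    tibble::tibble(
      id = pop$id[i],
      auc_tumor = tumor_auc(traj, auc_window),
      baseline_PSA = base,
      pct_change_nadir = 100 * (min(psa) - base) / base,
      pct_change_last = 100 * (psa[length(psa)] - base) / base
    )
  })
}

#' @export
print.exposure_response_fit <- function(x, ...) {
  cat("<exposure_response_fit> endpoint:", x$endpoint, " n =", x$n, "\n")
  cat(sprintf("  pct change = %.3g %+.3g x AUC (R^2 = %.3f)\n",
              x$intercept, x$slope, x$r_squared))
  if (x$slope < 0) {
    cat(sprintf("  AUC threshold for -50%%: %.1f MBq h/mL\n",
                auc_threshold(x)))
  }
  invisible(x)
}

#' @export
tidy.exposure_response_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.exposure_response_fit <- function(x, ...) {
  tibble::tibble(endpoint = x$endpoint, n = x$n, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 auc_threshold_50 = if (x$slope < 0) auc_threshold(x)
                 else NA_real_)
}

#' Plot an exposure-response fit
#'
#' @param object An `exposure_response_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposure_response_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$auc, .data$pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::geom_hline(yintercept = -50, linetype = "dashed") +
    ggplot2::labs(x = "tumor AUC (MBq h/mL, first two cycles)",
                  y = paste0("PSA change at ", object$endpoint, " (%)")) +
    ggplot2::theme_minimal()
}
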