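#' Clinical sampling schedule
#'
#' Timing structure of the emulated study data: per cycle, SPECT scans at
#' three post-injection offsets drawn from normal distributions (defaults
#' 4.6 +/- 0.95 h, 23.8 +/- 4.5 h and 163.2 +/- 11.0 h, i.e. 6.8 +/- 0.46
#' days), and PSA draws at a fixed weekly interval with one baseline value
#' inside a window before the first dose.
#'
#' @param scan_mean,scan_sd Mean and SD (h) of the three scan offsets.
#' @param psa_interval_weeks Weeks between PSA draws.
#' @param baseline_psa_window_weeks Width (weeks, < 6) of the pre-dose window
#'   in which the baseline PSA is drawn.
#' @return A list of class `sampling_schedule`.
#' @export
sampling_schedule <- function(scan_mean = c(4.6, 23.8, 163.2),
                              scan_sd = c(0.95, 4.5, 11.0),
                              psa_interval_weeks = 4,
                              baseline_psa_window_weeks = 4) {
  stopifnot(length(scan_mean) == length(scan_sd))
  if (any(scan_mean <= 0) || is.unsorted(scan_mean, strictly = TRUE)) {
    stop("scan offsets must be positive and increasing", call. = FALSE)
  }
  if (any(scan_sd < 0)) stop("scan_sd must be >= 0", call. = FALSE)
  if (baseline_psa_window_weeks >= 6) {
    stop("baseline window must be < 6 weeks before the first dose",
         call. = FALSE)
  }
  structure(list(scan_mean = scan_mean, scan_sd = scan_sd,
                 psa_interval_weeks = psa_interval_weeks,
                 baseline_psa_window_weeks = baseline_psa_window_weeks),
            class = "sampling_schedule")
}

#' SPECT-derived blood concentration correction
#'
#' The clinical blood concentrations derived from SPECT images were corrected
#' with a fixed linear regression (intercept 6.27 MBq/L, slope 0.828):
#' corrected = (raw - 6.27) / 0.828. Low raw values can map to negative
#' corrected concentrations, which the study excluded. `to_raw` is the exact
#' inverse, used to emulate the measurement chain.
#'
#' @param x Concentration(s), MBq/L.
#' @param direction `"to_corrected"` or `"to_raw"`.
#' @param intercept,slope Correction coefficients.
#' @return Transformed concentration(s), MBq/L.
#' @export
blood_correction <- function(x, direction = c("to_corrected", "to_raw"),
                             intercept = 6.27, slope = 0.828) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(x)))
  switch(direction,
         to_corrected = (x - intercept) / slope,
         to_raw = x * slope + intercept)
}

.dose_rows <- function(id, regimen, WT, TV) {
  ev <- regimen$dose_events
  tibble::tibble(ID = id, TIME = ev$time, EVID = 1L, AMT = ev$amt, CMT = 1L,
                 DV = NA_real_, MDV = 1L, WT = WT, TV = TV,
                 CYCLE = ev$cycle, OCC = ev$cycle)
}

#' Generate a synthetic SPECT observation dataset
#'
#' Emulates the study measurement chain on a virtual population: for each
#' subject and treatment cycle, scan times are drawn from the sampling
#' schedule; the true decay-corrected values (blood concentration in MBq/L,
#' salivary/kidney/tumor amounts in MBq) are read from the subject's
#' corrected-mode trajectory; residual error is applied per compartment;
#' blood values additionally pass through the SPECT-blood
#' correction round trip (`to_raw` then `to_corrected`). With
#' `apply_filters = TRUE`, negative corrected blood values are dropped,
#' mirroring the study's exclusions; filtering only removes rows.
#'
#' @param pop A [generate_virtual_population()] tibble.
#' @param regimen A regimen.
#' @param params,pd,vp Population parameter and variability objects.
#' @param schedule A [sampling_schedule()].
#' @param seed Integer seed.
#' @param apply_filters Drop negative corrected blood observations.
#' @param noise Apply residual error (set `FALSE` for noise-free datasets).
#' @param engine Solver engine.
#' @return A NONMEM-style event tibble with columns `ID`, `TIME` (h), `EVID`,
#'   `AMT` (MBq), `CMT` (1 central, 2 salivary, 3 kidneys, 4 tumor), `DV`,
#'   `MDV`, `WT`, `TV`, `CYCLE`, `OCC`, containing dosing and observation
#'   records sorted by subject and time.
#' @export
generate_spect_dataset <- function(pop, regimen, params = pk_parameters(),
                                   pd = pd_parameters(),
                                   vp = variability_parameters(),
                                   schedule = sampling_schedule(),
                                   seed = NULL, apply_filters = FALSE,
                                   noise = TRUE, engine = "C") {
  if (!is.null(seed)) set.seed(seed)
  em <- compartment_error_models(vp)
  eta_cols <- grep("^eta_", names(pop), value = TRUE)
  ev <- regimen$dose_events
  n_scan <- length(schedule$scan_mean)

  out <- purrr::map_dfr(seq_len(nrow(pop)), function(i) {
    eta <- stats::setNames(as.numeric(pop[i, eta_cols]), eta_cols)
    ind <- individualize(params, pd,
                         covariate_set(WT = pop$WT[i], TV = pop$TV[i]),
                         eta = eta, iov_k14 = pop$iov_k14[[i]],
                         n_cycles = nrow(ev))
    scan_t <- purrr::map(seq_len(nrow(ev)), function(cyc) {
      off <- stats::rnorm(n_scan, schedule$scan_mean, schedule$scan_sd)
      off <- pmax(off, 0.5)
      ev$time[cyc] + sort(off)
    })
    times <- sort(unique(unlist(scan_t)))
    times <- times[times <= regimen$horizon]
    traj <- .solve_core(ind, regimen, times, "corrected", engine,
                        with_pd = FALSE)
    V1 <- ind$pk_by_cycle[[1]]$V1
    obs <- purrr::map_dfr(seq_len(nrow(ev)), function(cyc) {
      st <- scan_t[[cyc]][scan_t[[cyc]] <= regimen$horizon]
      idx <- match(st, traj$time)
      tidyr::expand_grid(TIME = st, CMT = c(1L, 2L, 3L, 4L)) |>
        dplyr::mutate(
          ID = pop$id[i], EVID = 0L, AMT = NA_real_, MDV = 0L,
          WT = pop$WT[i], TV = pop$TV[i], CYCLE = cyc, OCC = cyc,
          DV = {
            j <- match(.data$TIME, traj$time)
            dplyr::case_when(
              .data$CMT == 1L ~ traj$A1[j] / V1,
              .data$CMT == 2L ~ traj$A2[j],
              .data$CMT == 3L ~ traj$A3[j],
              .data$CMT == 4L ~ traj$A4[j]
            )
          })
    })
    if (noise) {
      for (cmt in 1:4) {
        sel <- obs$CMT == cmt
        nm <- .cmt_names[[as.character(cmt)]]
        obs$DV[sel] <- apply_residual_error(obs$DV[sel], em[[nm]])
      }
    }
    ## blood goes through the SPECT correction chain (exact round trip)
    sel <- obs$CMT == 1L
    obs$DV[sel] <- blood_correction(blood_correction(obs$DV[sel], "to_raw"),
                                    "to_corrected")
    dplyr::bind_rows(.dose_rows(pop$id[i], regimen, pop$WT[i], pop$TV[i]),
                     obs[names(.dose_rows(1, regimen, 1, 1))])
  })
  if (apply_filters) {
    out <- out[!(out$EVID == 0L & out$CMT == 1L & out$DV < 0), ]
  }
  dplyr::arrange(out, .data$ID, .data$TIME, .data$EVID, .data$CMT)
}

#' Generate a synthetic PSA observation series
#'
#' One baseline PSA observation drawn inside the pre-dose window, then draws
#' every `psa_interval_weeks` through the regimen horizon, on each subject's
#' noise-free PSA trajectory, perturbed with the proportional PSA residual
#' error. Observations after an optional `truncate_at` time (a subsequent
#' non-study treatment) are dropped.
#'
#' @inheritParams generate_spect_dataset
#' @param truncate_at Optional time (h) after which observations are dropped.
#' @return A NONMEM-style event tibble (CMT 6 = PSA, ug/L) including the
#'   dosing records.
#' @export
generate_psa_series <- function(pop, regimen, params = pk_parameters(),
                                pd = pd_parameters(),
                                vp = variability_parameters(),
                                schedule = sampling_schedule(),
                                seed = NULL, noise = TRUE,
                                truncate_at = NULL, engine = "C") {
  if (!is.null(seed)) set.seed(seed)
  em <- compartment_error_models(vp)
  eta_cols <- grep("^eta_", names(pop), value = TRUE)
  wk <- 7 * 24
  draw_t <- seq(schedule$psa_interval_weeks * wk, regimen$horizon,
                by = schedule$psa_interval_weeks * wk)

  purrr::map_dfr(seq_len(nrow(pop)), function(i) {
    eta <- stats::setNames(as.numeric(pop[i, eta_cols]), eta_cols)
    ind <- individualize(params, pd,
                         covariate_set(WT = pop$WT[i], TV = pop$TV[i]),
                         eta = eta, iov_k14 = pop$iov_k14[[i]],
                         n_cycles = nrow(regimen$dose_events))
    t_base <- -stats::runif(1, 0, schedule$baseline_psa_window_weeks * wk)
    traj <- .solve_core(ind, regimen, draw_t, "corrected", engine,
                        with_pd = TRUE)
    psa_t <- c(t_base, draw_t)
    ## pre-dose PSA follows untreated exponential growth backwards
    psa_v <- c(ind$pd$PSA0 * exp(ind$pd$kG * t_base),
               traj$PSA[match(draw_t, traj$time)])
    if (noise) psa_v <- apply_residual_error(psa_v, em$psa)
    obs <- tibble::tibble(ID = pop$id[i], TIME = psa_t, EVID = 0L,
                          AMT = NA_real_, CMT = 6L, DV = psa_v, MDV = 0L,
                          WT = pop$WT[i], TV = pop$TV[i],
                          CYCLE = NA_integer_, OCC = NA_integer_)
    if (!is.null(truncate_at)) obs <- obs[obs$TIME <= truncate_at, ]
    dplyr::bind_rows(.dose_rows(pop$id[i], regimen, pop$WT[i], pop$TV[i]),
                     obs) |>
      dplyr::arrange(.data$TIME)
  })
}
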