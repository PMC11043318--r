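## Observation-unit conventions (NONMEM-style CMT codes):
## 1 central (MBq/L), 2 salivary (MBq), 3 kidneys (MBq), 4 tumor (MBq),
## 6 PSA (ug/L). Radioactivity observations are on the decay-corrected
## scale, as the clinical data were; predictions therefore read the
## corrected-mode state directly.
.cmt_names <- c("1" = "central", "2" = "salivary", "3" = "kidneys",
                "4" = "tumor", "6" = "psa")

.predict_obs <- function(ind, regimen, obs, engine = "C") {
  times <- sort(unique(c(0, obs$TIME, regimen$horizon)))
  traj <- .solve_core(ind, regimen, times, "corrected", engine,
                      with_pd = any(obs$CMT == 6))
  idx <- match(round(obs$TIME, 9), round(traj$time, 9))
  V1 <- ind$pk_by_cycle[[1]]$V1
  t0 <- regimen$dose_events$time[1]
  vapply(seq_len(nrow(obs)), function(i) {
    if (obs$TIME[i] < t0) {
      ## pre-dose: amounts are zero, PSA follows untreated growth
      if (obs$CMT[i] == 6L) {
        return(ind$pd$PSA0 * exp(ind$pd$kG * (obs$TIME[i] - t0)))
      }
      return(0)
    }
    r <- traj[idx[i], ]
    switch(as.character(obs$CMT[i]),
           "1" = r$A1 / V1,
           "2" = r$A2,
           "3" = r$A3,
           "4" = r$A4,
           "6" = r$PSA,
           stop("unsupported CMT ", obs$CMT[i], call. = FALSE))
  }, numeric(1))
}

## -2 log likelihood of observations under the residual model. The residual
## variance is evaluated at the observed value, not the prediction, so the
## objective is exactly self-consistent: noise-free data are minimised at
## the generating random effects (a prediction-based variance would trade
## residual misfit against a smaller log-variance term).
.neg2ll <- function(dv, pred, cmt, vp) {
  em <- compartment_error_models(vp)
  v <- vapply(seq_along(dv), function(i) {
    m <- em[[.cmt_names[[as.character(cmt[i])]]]]
    (m$sigma_prop * dv[i])^2 + m$sigma_add^2
  }, numeric(1))
  if (any(v <= 0)) {
    mismatch <- abs(dv - pred) > 1e-12
    if (any(v <= 0 & mismatch)) return(Inf)
    v[v <= 0] <- 1e-300
  }
  sum(log(2 * pi * v) + (dv - pred)^2 / v)
}

#' Penalized deviance for individual empirical-Bayes estimation
#'
#' The maximum-a-posteriori (MAP) objective for one subject's random
#' effects: -2 log likelihood of the observations under the residual-error
#' model plus the normal prior penalty `sum(eta^2 / omega^2)` (with the
#' inter-occasion variance for per-cycle `iov_k14_*` components).
#' Deterministic given its inputs. The residual variance is evaluated at the
#' observed value, which makes the objective exactly self-consistent:
#' noise-free data attain their global minimum at the generating effects.
#'
#' @param eta Named numeric of random effects: IIV components (`eta_k10`,
#'   `eta_k14`, ..., `eta_PSA0`, ...) and optionally per-cycle `iov_k14_1`,
#'   `iov_k14_2`, ....
#' @param obs Observation tibble with `TIME`, `CMT`, `DV` for one subject.
#' @param regimen The subject's [regimen()].
#' @param params,pd Population parameter objects.
#' @param vp A [variability_parameters()] object (omegas and sigmas).
#' @param cov The subject's [covariate_set()].
#' @param engine Solver engine.
#' @return Scalar penalized deviance.
#' @export
map_objective <- function(eta, obs, regimen, params = pk_parameters(),
                          pd = pd_parameters(), vp = variability_parameters(),
                          cov = covariate_set(), engine = "C") {
  iov_idx <- grepl("^iov_k14_", names(eta))
  iiv <- eta[!iov_idx]
  iov <- eta[iov_idx]
  iov_vec <- rep(0, nrow(regimen$dose_events))
  if (length(iov) > 0) {
    occ <- as.integer(sub("^iov_k14_", "", names(iov)))
    iov_vec[occ] <- iov
  }
  omegas <- vp$omega[sub("^eta_", "", names(iiv))]
  if (any(is.na(omegas)) || any(omegas <= 0)) {
    stop("every estimated eta needs a positive omega", call. = FALSE)
  }
  ind <- individualize(params, pd, cov, eta = iiv, iov_k14 = iov_vec,
                       n_cycles = nrow(regimen$dose_events))
  pred <- .predict_obs(ind, regimen, obs, engine)
  pen <- sum(iiv^2 / omegas^2)
  if (length(iov) > 0) pen <- pen + sum(iov^2 / vp$omega_iov_k14^2)
  .neg2ll(obs$DV, pred, obs$CMT, vp) + pen
}

#' Individual MAP (empirical-Bayes) estimate
#'
#' Minimises [map_objective()] over the requested random-effect components
#' for one subject, from three starting points (0 and +/- 0.3 on every
#' component) to guard against local minima, and returns the estimated
#' effects together with the individual predictions.
#'
#' @inheritParams map_objective
#' @param which Names of the effects to estimate; defaults to the PK IIV
#'   components plus one `iov_k14_<occasion>` per dose when tumor data are
#'   present, and the PD components when PSA data are present.
#' @param control Passed to [stats::optim()] (`method = "BFGS"`); the
#'   default sets `reltol = 1e-10`.
#' @return A list of class `map_fit`: `eta` (named estimates), `objective`,
#'   `predictions` (obs tibble plus `PRED` column), `convergence`.
#' @export
map_estimate <- function(obs, regimen, params = pk_parameters(),
                         pd = pd_parameters(), vp = variability_parameters(),
                         cov = covariate_set(), which = NULL,
                         engine = "C", control = list(reltol = 1e-10)) {
  stopifnot(nrow(obs) >= 1)
  if (is.null(which)) {
    which <- c("eta_k10", "eta_k13", "eta_k14", "eta_k15", "eta_Bmax_sal")
    if (any(obs$CMT == 4)) {
      which <- c(which,
                 paste0("iov_k14_", seq_len(nrow(regimen$dose_events))))
    }
    if (any(obs$CMT == 6)) {
      which <- c(which, "eta_PSA0", "eta_kG", "eta_kD_direct",
                 "eta_kD_delay")
    }
  }
  obj <- function(x) {
    # guard wild line-search excursions that would blow up the kinetics
    if (any(abs(x) > 8)) return(1e10)
    v <- tryCatch(
      map_objective(stats::setNames(x, which), obs, regimen, params, pd, vp,
                    cov, engine),
      error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(rep(0, length(which)), rep(0.3, length(which)),
                 rep(-0.3, length(which)))
  fits <- purrr::map(starts, function(s) {
    stats::optim(s, obj, method = "BFGS", control = control)
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  eta <- stats::setNames(best$par, which)
  iov_idx <- grepl("^iov_k14_", which)
  iov_vec <- rep(0, nrow(regimen$dose_events))
  if (any(iov_idx)) {
    occ <- as.integer(sub("^iov_k14_", "", which[iov_idx]))
    iov_vec[occ] <- eta[iov_idx]
  }
  ind <- individualize(params, pd, cov, eta = eta[!iov_idx],
                       iov_k14 = iov_vec,
                       n_cycles = nrow(regimen$dose_events))
  structure(
    list(eta = eta, objective = best$value,
         predictions = dplyr::mutate(obs,
                                     PRED = .predict_obs(ind, regimen, obs,
                                                         engine)),
         convergence = best$convergence),
    class = "map_fit"
  )
}

#' @export
tidy.map_fit <- function(x, ...) {
  tibble::tibble(term = names(x$eta), estimate = unname(x$eta))
}

#' @export
glance.map_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_obs = nrow(x$predictions),
                 convergence = x$convergence)
}

## reconstruct per-subject regimen and covariates from an event dataset
.split_dataset <- function(data) {
  data |>
    dplyr::group_by(.data$ID) |>
    dplyr::group_map(function(d, key) {
      doses <- d[d$EVID == 1, ]
      obs <- d[d$EVID == 0 & d$MDV == 0, ]
      list(id = key$ID,
           regimen = regimen(doses$TIME, doses$AMT,
                             horizon = max(d$TIME) + 1,
                             name = "from-data"),
           cov = covariate_set(WT = d$WT[1], TV = d$TV[1]),
           obs = obs)
    })
}

#' Naive-pooled structural parameter fit
#'
#' Fits selected fixed-effect parameters by pooling all subjects (random
#' effects ignored) and minimising the residual-variance-weighted sum of
#' squares implied by the observation error model. Positive parameters are
#' optimised on the log scale; the cycle fractions (`cycle2`, `cycle3`,
#' `cycle4_7`) and PD parameters (`kG`, `kD_direct`, `kD_delay`, `ke0`) are
#' addressable alongside the PK rate constants. The central volume stays
#' fixed (as in estimation on the clinical data). This is a deliberately
#' simple recovery surface for validating the model equations, not a
#' replacement for full nonlinear mixed-effects estimation.
#'
#' @param data An event dataset as produced by [generate_spect_dataset()] /
#'   [generate_psa_series()] (or read with [read_dataset()]).
#' @param free Character vector of parameter names to estimate.
#' @param params,pd Population parameter objects supplying the fixed values
#'   and the starting point.
#' @param vp Variability object supplying the residual weights.
#' @param start Optional named numeric of starting values for the free
#'   parameters.
#' @param engine Solver engine.
#' @return A list of class `pooled_fit`: `estimates` (named numeric),
#'   `objective`, `convergence`, `n_obs`, plus the fixed `params`/`pd`
#'   actually used.
#' @export
naive_pooled_fit <- function(data, free, params = pk_parameters(),
                             pd = pd_parameters(),
                             vp = variability_parameters(), start = NULL,
                             engine = "C") {
  pk_names <- c("k10", "k12", "k21", "k13", "k31", "k14", "k41", "k15",
                "k51", "Bmax_sal")
  cyc_names <- c("cycle2", "cycle3", "cycle4_7")
  pd_names <- c("kG", "kD_direct", "kD_delay", "ke0", "PSA0")
  bad <- setdiff(free, c(pk_names, cyc_names, pd_names))
  if (length(bad) > 0) {
    stop("unknown free parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  subjects <- .split_dataset(data)
  n_obs <- sum(purrr::map_int(subjects, ~ nrow(.x$obs)))
  if (n_obs == 0) stop("dataset contains no observations", call. = FALSE)

  current <- function(theta) {
    p <- params; q <- pd
    for (nm in names(theta)) {
      v <- exp(theta[[nm]])
      if (nm %in% pk_names) p[[nm]] <- v
      else if (nm %in% cyc_names) p$cycle_fractions[[nm]] <- v
      else q[[nm]] <- v
    }
    list(p = p, q = q)
  }
  objective <- function(theta) {
    th <- stats::setNames(theta, free)
    pq <- current(th)
    if (any(pq$p$cycle_fractions > 1)) return(1e10)
    tot <- 0
    for (s in subjects) {
      ind <- individualize(pq$p, pq$q, s$cov,
                           n_cycles = nrow(s$regimen$dose_events))
      pred <- .predict_obs(ind, s$regimen, s$obs, engine)
      em <- compartment_error_models(vp)
      w <- vapply(seq_len(nrow(s$obs)), function(i) {
        m <- em[[.cmt_names[[as.character(s$obs$CMT[i])]]]]
        max((m$sigma_prop * pred[i])^2 + m$sigma_add^2, 1e-12)
      }, numeric(1))
      tot <- tot + sum((s$obs$DV - pred)^2 / w)
    }
    tot
  }
  if (length(free) == 0) {
    return(structure(list(estimates = numeric(0),
                          objective = objective(numeric(0)),
                          convergence = 0L, n_obs = n_obs,
                          params = params, pd = pd),
                     class = "pooled_fit"))
  }
  if (is.null(start)) {
    start <- vapply(free, function(nm) {
      if (nm %in% pk_names) params[[nm]]
      else if (nm %in% cyc_names) params$cycle_fractions[[nm]]
      else pd[[nm]]
    }, numeric(1))
  }
  fit <- stats::nlminb(log(start), objective,
                       control = list(abs.tol = 1e-8, rel.tol = 1e-10,
                                      iter.max = 500))
  est <- stats::setNames(exp(fit$par), free)
  structure(
    list(estimates = est, objective = fit$objective,
         convergence = fit$convergence, n_obs = n_obs,
         params = current(stats::setNames(fit$par, free))$p,
         pd = current(stats::setNames(fit$par, free))$q),
    class = "pooled_fit"
  )
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("<pooled_fit>", x$n_obs, "observations, objective",
      signif(x$objective, 4), "\n")
  if (length(x$estimates) > 0) print(signif(x$estimates, 4))
  invisible(x)
}

#' @export
tidy.pooled_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @export
glance.pooled_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_obs = x$n_obs,
                 convergence = x$convergence)
}
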