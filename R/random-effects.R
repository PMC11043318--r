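#' Convert a coefficient of variation in percent to a random-effect SD
#'
#' Population variability is reported as CV% of log-normally distributed
#' individual parameters `P_i = P_pop * exp(eta_i)`. The default mapping is
#' the exact lognormal relation `omega = sqrt(log(1 + (CV/100)^2))`, under
#' which `exp(eta)` has exactly the stated coefficient of variation; the
#' common reporting approximation `omega = CV/100` is available via `mode`.
#' The two differ appreciably only for large CV (for CV = 179% the exact
#' omega is 1.32 rather than 1.79), which matters for distribution tails.
#'
#' @param cv_percent CV in percent (vectorised, may be named).
#' @param mode `"direct"` or `"exact"`.
#' @return omega, the standard deviation of eta.
#' @export
cv_to_omega <- function(cv_percent, mode = c("exact", "direct")) {
  mode <- match.arg(mode)
  if (any(cv_percent < 0)) stop("cv_percent must be >= 0", call. = FALSE)
  switch(mode,
         direct = cv_percent / 100,
         exact = sqrt(log(1 + (cv_percent / 100)^2)))
}

#' Box-Cox transform of a random effect
#'
#' Skews a normal random effect before exponentiation:
#' `eta* = ((exp(eta))^shape - 1) / shape`, with the identity limit
#' `eta* -> eta` as `shape -> 0`. Used on the PSA growth-rate random effect
#' (shape -0.822), whose raw distribution deviated from log-normality.
#'
#' @param eta Normal random effect(s).
#' @param shape Box-Cox shape parameter.
#' @return Transformed effect(s); the individual parameter is
#'   `P_pop * exp(boxcox_eta(eta, shape))`.
#' @export
boxcox_eta <- function(eta, shape) {
  if (abs(shape) < 1e-8) return(eta)
  (exp(eta)^shape - 1) / shape
}

#' Sample inter-individual and inter-occasion random effects
#'
#' Draws independent normal effects with mean 0 and the SDs configured in
#' [variability_parameters()] for `n_subjects` subjects, plus one
#' inter-occasion effect on the tumor uptake rate per treatment cycle
#' (occasion). No correlation structure is imposed (none was identified).
#'
#' @param vp A [variability_parameters()] object.
#' @param n_subjects Number of subjects.
#' @param n_occasions Number of occasions (treatment cycles) per subject.
#' @param seed Optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used.
#' @return A tibble with one row per subject: column `id`, one `eta_*` column
#'   per IIV effect, and a list-column `iov_k14` of length-`n_occasions`
#'   vectors.
#' @export
sample_random_effects <- function(vp, n_subjects, n_occasions = 1, seed = NULL) {
  stopifnot(inherits(vp, "variability_parameters"),
            n_subjects >= 1, n_occasions >= 1)
  if (!is.null(seed)) set.seed(seed)
  om <- vp$omega
  etas <- purrr::map(om, ~ stats::rnorm(n_subjects, 0, .x))
  names(etas) <- paste0("eta_", names(om))
  iov <- purrr::map(seq_len(n_subjects),
                    ~ stats::rnorm(n_occasions, 0, vp$omega_iov_k14))
  tibble::tibble(id = seq_len(n_subjects), !!!etas, iov_k14 = iov)
}

#' Residual (observation-level) error model
#'
#' `residual_error_model()` describes the unexplained variability of one
#' observed compartment: `combined` (proportional plus additive, used for the
#' central compartment) or `proportional` (all other compartments and PSA),
#' following `C_obs = C_pred * (1 + eps_p) + eps_add` with independent normal
#' errors. `apply_residual_error()` perturbs noise-free predictions
#' accordingly; with a combined model, early low observations can come out
#' negative, mirroring the negative decay-corrected blood values excluded in
#' the clinical dataset.
#'
#' @param kind `"combined"` or `"proportional"`.
#' @param sigma_prop Proportional error SD as a fraction (e.g. 0.555).
#' @param sigma_add Additive error SD (same units as the observation).
#' @return For `residual_error_model()`, a list of class
#'   `residual_error_model`.
#' @export
residual_error_model <- function(kind = c("combined", "proportional"),
                                 sigma_prop, sigma_add = 0) {
  kind <- match.arg(kind)
  if (sigma_prop < 0 || sigma_add < 0) {
    stop("sigma values must be >= 0", call. = FALSE)
  }
  if (kind == "proportional" && sigma_add != 0) {
    stop("proportional model has no additive component", call. = FALSE)
  }
  structure(list(kind = kind, sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "residual_error_model")
}

#' @rdname residual_error_model
#' @param pred Numeric vector of noise-free predictions.
#' @param model A `residual_error_model`.
#' @param seed Optional integer seed.
#' @return For `apply_residual_error()`, the perturbed observations.
#' @export
apply_residual_error <- function(pred, model, seed = NULL) {
  stopifnot(inherits(model, "residual_error_model"), all(is.finite(pred)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, model$sigma_prop))
  if (model$kind == "combined") {
    obs <- obs + stats::rnorm(n, 0, model$sigma_add)
  }
  obs
}

#' Residual error models per observed compartment
#'
#' Convenience constructor mapping a [variability_parameters()] object to the
#' per-compartment [residual_error_model()]s used by the dataset generator
#' and the estimation likelihood.
#'
#' @param vp A [variability_parameters()] object.
#' @return Named list of `residual_error_model`s for `central`, `salivary`,
#'   `kidneys`, `tumor`, `psa`.
#' @export
compartment_error_models <- function(vp) {
  stopifnot(inherits(vp, "variability_parameters"))
  sp <- vp$sigma_prop
  list(
    central = residual_error_model("combined", sp[1], vp$sigma_add_central),
    salivary = residual_error_model("proportional", sp[2]),
    kidneys = residual_error_model("proportional", sp[3]),
    tumor = residual_error_model("proportional", sp[4]),
    psa = residual_error_model("proportional", sp[5])
  )
}
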