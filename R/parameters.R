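#' Physical decay constant of lutetium-177
#'
#' First-order physical decay rate of the radionuclide, `log(2) / 159.528` per
#' hour (physical half-life 6.647 days, nuclide reference data).
#'
#' @format A length-one numeric, units h^-1.
#' @export
lu177_lambda <- log(2) / (6.647 * 24)

#' Population pharmacokinetic parameters
#'
#' Constructs the fixed-effect parameter set of the five-compartment
#' radioligand kinetic model: a central (blood) compartment exchanging with
#' salivary glands (saturable, capacity `Bmax_sal`), kidneys, tumor and a
#' lumped remaining-tissue compartment, with first-order renal excretion
#' `k10` from the central compartment. Defaults are the final population
#' estimates for [177Lu]Lu-PSMA-I&T.
#'
#' Covariate coefficients carried here: power exponents of segmented tumor
#' volume on the salivary (`theta_tv_k12`) and tumor (`theta_tv_k14`) uptake
#' rates, and the structural per-cycle attenuation of tumor uptake
#' (`cycle_fractions`: multipliers of first-cycle `k14` for cycle 2, cycle 3
#' and cycles 4-7). Reference covariate values are the cohort medians
#' (`wt_median` 79 kg, `tv_median` 0.0443 L).
#'
#' @param k10,k12,k21,k13,k31,k14,k41,k15,k51 First-order transfer rate
#'   constants (h^-1). `k10` is renal excretion; `k12`/`k21` central-salivary,
#'   `k13`/`k31` central-kidney, `k14`/`k41` central-tumor, `k15`/`k51`
#'   central-remaining tissue.
#' @param Bmax_sal Maximum salivary-gland binding capacity (MBq).
#' @param V1 Central volume of distribution (L), fixed in estimation.
#' @param theta_tv_k12,theta_tv_k14 Power-function exponents of tumor volume.
#' @param cycle_fractions Named numeric: fraction of cycle-1 `k14` applying in
#'   cycle 2, cycle 3 and cycles 4-7.
#' @param wt_median,tv_median Reference (median) body weight (kg) and
#'   segmented tumor volume (L).
#' @param lambda_phys Physical decay constant (h^-1); see [lu177_lambda].
#'
#' @return A list of class `pk_parameters`.
#' @seealso [pd_parameters()], [variability_parameters()], [individualize()]
#' @examples
#' p <- pk_parameters()
#' renal_clearance(p)   # k10 * V1 = 2.61 L/h
#' @export
pk_parameters <- function(k10 = 0.253,
                          k12 = 0.0105,
                          k21 = 0.0629,
                          k13 = 0.0321,
                          k31 = 0.0625,
                          k14 = 0.00967,
                          k41 = 0.0150,
                          k15 = 0.275,
                          k51 = 0.0247,
                          Bmax_sal = 134,
                          V1 = 10.3,
                          theta_tv_k12 = 0.0910,
                          theta_tv_k14 = 1.08,
                          cycle_fractions = c(cycle2 = 0.731,
                                              cycle3 = 0.498,
                                              cycle4_7 = 0.436),
                          wt_median = 79,
                          tv_median = 0.0443,
                          lambda_phys = lu177_lambda) {
  rates <- c(k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31,
             k14 = k14, k41 = k41, k15 = k15, k51 = k51)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(V1) || V1 <= 0) stop("V1 must be > 0", call. = FALSE)
  if (!is.finite(Bmax_sal) || Bmax_sal <= 0) {
    stop("Bmax_sal must be > 0", call. = FALSE)
  }
  cf <- as.numeric(cycle_fractions)
  if (length(cf) != 3L || any(cf <= 0) || any(cf > 1)) {
    stop("cycle_fractions must be three values in (0, 1]", call. = FALSE)
  }
  if (lambda_phys <= 0) stop("lambda_phys must be > 0", call. = FALSE)
  structure(
    list(k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31,
         k14 = k14, k41 = k41, k15 = k15, k51 = k51,
         Bmax_sal = Bmax_sal, V1 = V1,
         theta_tv_k12 = theta_tv_k12, theta_tv_k14 = theta_tv_k14,
         cycle_fractions = c(cycle2 = cf[1], cycle3 = cf[2], cycle4_7 = cf[3]),
         wt_median = wt_median, tv_median = tv_median,
         lambda_phys = lambda_phys),
    class = "pk_parameters"
  )
}

#' Population pharmacodynamic (PSA dynamics) parameters
#'
#' Parameters of the PSA turnover model: exponential growth at rate `kG`,
#' a direct kill term proportional to the tumor activity concentration, and a
#' delayed kill term driven by an effect compartment that equilibrates with
#' the tumor concentration at rate `ke0`. Defaults are the final population
#' estimates; the direct and delayed drug effects are linear in the final
#' model (Emax / sigmoid-Emax alternatives are selectable in [drug_effect()]
#' via `EMAX`, `EC50`, `gamma`).
#'
#' `kD_direct` and `kD_delay` are stored in their reported units
#' (L day^-1 GBq^-1 and L day^-1 MBq^-1 respectively, deliberately asymmetric
#' as printed) and converted internally to per-hour, per-(MBq/L) rates; see
#' [kd_direct_hourly()].
#'
#' @param PSA0 Typical baseline PSA (ug/L); fixed in estimation.
#' @param theta_tv_PSA0 Linear tumor-volume covariate on baseline PSA (ug/L).
#' @param kG Exponential PSA growth rate (h^-1).
#' @param kD_direct Direct drug-effect coefficient (L day^-1 GBq^-1).
#' @param ke0 Effect-compartment equilibration rate (h^-1).
#' @param kD_delay Delayed drug-effect coefficient (L day^-1 MBq^-1).
#' @param boxcox_shape Box-Cox shape of the random effect on `kG`.
#' @param EMAX,EC50,gamma Optional maximum-effect model parameters (only used
#'   when a nonlinear `form` is requested; not part of the final model).
#' @return A list of class `pd_parameters`.
#' @examples
#' pd <- pd_parameters()
#' log(2) / pd$kG / 24   # PSA doubling time ~ 70.8 days untreated
#' @export
pd_parameters <- function(PSA0 = 140,
                          theta_tv_PSA0 = 57.5,
                          kG = 0.000408,
                          kD_direct = 0.00335,
                          ke0 = 0.00128,
                          kD_delay = 0.0000328,
                          boxcox_shape = -0.822,
                          EMAX = NA_real_,
                          EC50 = NA_real_,
                          gamma = 1) {
  if (kG <= 0) stop("kG must be > 0", call. = FALSE)
  num <- c(PSA0, theta_tv_PSA0, kD_direct, ke0, kD_delay)
  if (any(num < 0)) {
    stop("PD parameters other than boxcox_shape must be >= 0", call. = FALSE)
  }
  structure(
    list(PSA0 = PSA0, theta_tv_PSA0 = theta_tv_PSA0, kG = kG,
         kD_direct = kD_direct, ke0 = ke0, kD_delay = kD_delay,
         boxcox_shape = boxcox_shape, EMAX = EMAX, EC50 = EC50, gamma = gamma),
    class = "pd_parameters"
  )
}

#' Convert the reported drug-effect coefficients to internal per-hour units
#'
#' The PSA system is integrated in hours with tumor concentration in MBq/L.
#' The direct coefficient is reported in L day^-1 GBq^-1 and therefore
#' divides by 24 (day to hour) and 1000 (GBq to MBq); the delayed coefficient
#' is reported in L day^-1 MBq^-1 and divides by 24 only.
#'
#' @param kD_direct Direct coefficient as reported (L day^-1 GBq^-1).
#' @param kD_delay Delayed coefficient as reported (L day^-1 MBq^-1).
#' @return The rate coefficient in L h^-1 MBq^-1, so that multiplying by a
#'   concentration in MBq/L yields h^-1.
#' @export
kd_direct_hourly <- function(kD_direct) kD_direct / (24 * 1000)

#' @rdname kd_direct_hourly
#' @export
kd_delay_hourly <- function(kD_delay) kD_delay / 24

#' Inter-individual, inter-occasion and residual variability
#'
#' Bundles the random-effect magnitudes of the population model, reported as
#' coefficients of variation in percent (converted to standard deviations of
#' the log-scale effects via [cv_to_omega()]), and the residual-error model
#' per observed compartment.
#'
#' IIV applies to `k10`, `k13`, `k14`, `k15` and `Bmax_sal` on the PK side
#' and to baseline PSA, `kG` (Box-Cox transformed), `kD_direct` and
#' `kD_delay` on the PD side; IOV applies to `k14` per treatment cycle.
#' Residual error is combined (proportional + additive) for the central
#' compartment and proportional for salivary glands, kidneys, tumor and PSA.
#'
#' @param iiv_cv Named numeric, CV% of the inter-individual random effects.
#' @param iov_cv_k14 CV% of the cycle-to-cycle (inter-occasion) effect on k14.
#' @param sigma_prop_cv Named numeric, proportional residual error CV% per
#'   compartment (`central`, `salivary`, `kidneys`, `tumor`, `psa`).
#' @param sigma_add_central Additive residual SD for the central compartment
#'   (MBq/L).
#' @param cv_mode How CV% maps to omega: `"exact"` (omega =
#'   sqrt(log(1 + CV^2)), so that exp(eta) has exactly the stated CV; the
#'   default) or `"direct"` (omega = CV/100, a common reporting
#'   approximation that widens the tails for large CV).
#' @return A list of class `variability_parameters` with elements `omega`
#'   (named SDs of IIV effects), `omega_iov_k14`, `sigma_prop` (fractions),
#'   `sigma_add_central` and `cv_mode`.
#' @export
variability_parameters <- function(iiv_cv = c(k10 = 33.1, k13 = 33.4,
                                              k14 = 63.4, k15 = 29.1,
                                              Bmax_sal = 67.0,
                                              PSA0 = 179, kG = 90.9,
                                              kD_direct = 140,
                                              kD_delay = 87.5),
                                   iov_cv_k14 = 37.8,
                                   sigma_prop_cv = c(central = 55.5,
                                                     salivary = 39.7,
                                                     kidneys = 31.9,
                                                     tumor = 32.7,
                                                     psa = 29.3),
                                   sigma_add_central = 9.57,
                                   cv_mode = c("exact", "direct")) {
  cv_mode <- match.arg(cv_mode)
  if (any(iiv_cv < 0) || iov_cv_k14 < 0 || any(sigma_prop_cv < 0) ||
      sigma_add_central < 0) {
    stop("variability magnitudes must be >= 0", call. = FALSE)
  }
  structure(
    list(omega = cv_to_omega(iiv_cv, mode = cv_mode),
         omega_iov_k14 = cv_to_omega(iov_cv_k14, mode = cv_mode),
         sigma_prop = unname(sigma_prop_cv)[match(
           c("central", "salivary", "kidneys", "tumor", "psa"),
           names(sigma_prop_cv))] / 100,
         sigma_add_central = sigma_add_central,
         cv_mode = cv_mode),
    class = "variability_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters> five-compartment radioligand model\n")
  rates <- unlist(x[c("k10", "k12", "k21", "k13", "k31",
                      "k14", "k41", "k15", "k51")])
  print(signif(rates, 3))
  cat("Bmax_sal:", x$Bmax_sal, "MBq  V1:", x$V1, "L  lambda_phys:",
      signif(x$lambda_phys, 4), "h^-1\n")
  cat("cycle fractions on k14:",
      paste(signif(x$cycle_fractions, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("<pd_parameters> PSA dynamics model\n")
  cat("PSA0:", x$PSA0, "ug/L (+", x$theta_tv_PSA0, "x TV/TV_med)  kG:",
      x$kG, "h^-1\n")
  cat("kD_direct:", x$kD_direct, "L/day/GBq  ke0:", x$ke0,
      "h^-1  kD_delay:", x$kD_delay, "L/day/MBq\n")
  invisible(x)
}

#' Reference exposure thresholds from the clinical cohort
#'
#' Tumor time-integrated-activity thresholds (MBq h/mL over the first two
#' treatment cycles) associated with a >= 50 percent PSA decrease in the
#' original patient cohort, using nadir PSA (709.5) or the last measurement
#' after the first two cycles (1188) as the response endpoint. These are
#' reference constants from patient data; they cannot be recomputed from
#' synthetic cohorts and are provided for context only (see
#' [auc_threshold()] for the threshold procedure itself).
#'
#' @format Named numeric of length two (`nadir`, `last`), MBq h/mL.
#' @export
reference_auc_thresholds <- c(nadir = 709.5, last = 1188)
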