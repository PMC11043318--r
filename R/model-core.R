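#' Right-hand side of the five-compartment radioligand PK system
#'
#' Derivatives of the compartment amounts (MBq): central `A1`, salivary
#' glands `A2` (saturable uptake against capacity `Bmax_sal`), kidneys `A3`,
#' tumor `A4` and remaining tissue `A5`. The central-to-salivary flux is
#' `k12 * A1 * (1 - A2/Bmax_sal)` on both sides of the transfer, so mass
#' leaves the system only through renal excretion (`k10`) and, in physical
#' mode, radioactive decay (`lambda_phys` applied uniformly to every
#' compartment). In `"corrected"` mode (amounts decay-corrected to injection
#' time, as the clinical data were) no decay term is applied.
#'
#' @param state Named numeric with elements `A1`..`A5` (MBq), nonnegative.
#' @param params A [pk_parameters()] object with the effective (already
#'   individualized) rate constants for the current subject and cycle.
#' @param decay_mode `"physical"` or `"corrected"`.
#' @return Named numeric of derivatives `dA1`..`dA5` (MBq/h).
#' @examples
#' pk_rhs(c(A1 = 7400, A2 = 0, A3 = 0, A4 = 0, A5 = 0), pk_parameters())
#' @export
pk_rhs <- function(state, params, decay_mode = c("physical", "corrected")) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(inherits(params, "pk_parameters"))
  a <- unname(state[c("A1", "A2", "A3", "A4", "A5")])
  if (any(!is.finite(a)) || any(a < 0)) {
    stop("state amounts must be finite and >= 0", call. = FALSE)
  }
  lam <- if (decay_mode == "physical") params$lambda_phys else 0
  d <- .pk_deriv(a, params, lam)
  stats::setNames(d, c("dA1", "dA2", "dA3", "dA4", "dA5"))
}

## unvalidated core used by the R solver path
.pk_deriv <- function(a, p, lam) {
  sat <- 1 - a[2] / p$Bmax_sal
  f12 <- p$k12 * a[1] * sat
  c(-(p$k10 + p$k13 + p$k14 + p$k15) * a[1] - f12 +
      p$k21 * a[2] + p$k31 * a[3] + p$k41 * a[4] + p$k51 * a[5] - lam * a[1],
    f12 - p$k21 * a[2] - lam * a[2],
    p$k13 * a[1] - p$k31 * a[3] - lam * a[3],
    p$k14 * a[1] - p$k41 * a[4] - lam * a[4],
    p$k15 * a[1] - p$k51 * a[5] - lam * a[5])
}

#' Drug-induced PSA elimination rate
#'
#' The direct drug effect as a first-order elimination contribution on the
#' PSA compartment, as a function of the tumor activity concentration:
#' linear `kD * C`, maximum-effect `EMAX * C / (EC50 + C)` or sigmoid
#' `EMAX * C^gamma / (EC50^gamma + C^gamma)`. The final model is linear; the
#' nonlinear forms are retained as evaluable alternatives.
#'
#' @param form `"linear"`, `"emax"` or `"sigmoid"`.
#' @param C_tumor Tumor concentration (MBq/L), >= 0.
#' @param pd A [pd_parameters()] object (`kD_direct` is taken in its reported
#'   units and converted internally; `EMAX` is interpreted as h^-1).
#' @return Elimination rate contribution (h^-1).
#' @export
drug_effect <- function(form = c("linear", "emax", "sigmoid"), C_tumor, pd) {
  form <- match.arg(form)
  stopifnot(inherits(pd, "pd_parameters"), all(C_tumor >= 0))
  if (form != "linear") {
    if (!is.finite(pd$EC50) || pd$EC50 <= 0) {
      stop("EC50 must be > 0 for emax/sigmoid forms", call. = FALSE)
    }
    if (!is.finite(pd$EMAX)) stop("EMAX must be set", call. = FALSE)
  }
  switch(form,
         linear = kd_direct_hourly(pd$kD_direct) * C_tumor,
         emax = pd$EMAX * C_tumor / (pd$EC50 + C_tumor),
         sigmoid = pd$EMAX * C_tumor^pd$gamma /
           (pd$EC50^pd$gamma + C_tumor^pd$gamma))
}

#' Right-hand side of the PSA / effect-compartment system
#'
#' The effect compartment equilibrates with the tumor concentration at rate
#' `ke0`; PSA grows exponentially at `kG` and is eliminated by the direct
#' effect (on `C_tumor`) and the delayed effect (linear in the
#' effect-compartment level `Ce`):
#' `dPSA/dt = (kG - E_drug - kD_delay * Ce) * PSA`.
#' Without any dose, `C_tumor` and `Ce` stay zero and PSA grows untreated.
#'
#' @param state Named numeric with `Ce` (MBq/L) and `PSA` (ug/L, > 0).
#' @param pd_ind Individual PD values as produced by [individualize()]
#'   (element `pd`; internal-unit kill coefficients `kD_direct_h`,
#'   `kD_delay_h`).
#' @param C_tumor Current tumor concentration (MBq/L).
#' @param form Direct-effect form, as [drug_effect()].
#' @return Named numeric `c(dCe, dPSA)`.
#' @export
pd_rhs <- function(state, pd_ind, C_tumor,
                   form = c("linear", "emax", "sigmoid")) {
  form <- match.arg(form)
  Ce <- unname(state[["Ce"]])
  PSA <- unname(state[["PSA"]])
  stopifnot(PSA > 0, C_tumor >= 0)
  E_drug <- switch(form,
                   linear = pd_ind$kD_direct_h * C_tumor,
                   emax = pd_ind$EMAX * C_tumor / (pd_ind$EC50 + C_tumor),
                   sigmoid = pd_ind$EMAX * C_tumor^pd_ind$gamma /
                     (pd_ind$EC50^pd_ind$gamma + C_tumor^pd_ind$gamma))
  c(dCe = pd_ind$ke0 * (C_tumor - Ce),
    dPSA = (pd_ind$kG - E_drug - pd_ind$kD_delay_h * Ce) * PSA)
}

#' Effective half-life in a peripheral compartment
#'
#' `log(2) / k_out` for the first-order return rate of a compartment; with
#' the final estimates this gives roughly 46 h for tumor (`k41`) and 11 h for
#' the organs at risk (`k21`).
#'
#' @param k_out Return rate constant (h^-1), > 0.
#' @return Half-life in hours.
#' @export
effective_half_life <- function(k_out) {
  if (any(k_out <= 0)) stop("k_out must be > 0", call. = FALSE)
  log(2) / k_out
}

#' Renal clearance implied by the central compartment
#'
#' @param params A [pk_parameters()] object.
#' @return `k10 * V1` in L/h (2.61 L/h at the population estimates).
#' @export
renal_clearance <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  params$k10 * params$V1
}

#' Tumor activity concentration
#'
#' Converts a tumor compartment amount to a concentration. In physical mode
#' the state already carries radioactive decay and the concentration is
#' `A4 / TV`; for decay-corrected amounts the physical concentration is
#' recovered as `A4 * exp(-lambda * t_abs) / TV`, with `t_abs` the time since
#' the injection the amount was corrected to.
#'
#' @param A4 Tumor amount (MBq).
#' @param tumor_volume Segmented tumor volume (L), > 0.
#' @param t_abs Hours since the reference injection (used in corrected mode).
#' @param decay_mode `"physical"` or `"corrected"`.
#' @param lambda_phys Physical decay constant (h^-1).
#' @return Concentration in MBq/L.
#' @export
tumor_concentration <- function(A4, tumor_volume, t_abs = 0,
                                decay_mode = c("physical", "corrected"),
                                lambda_phys = lu177_lambda) {
  decay_mode <- match.arg(decay_mode)
  if (any(tumor_volume <= 0)) stop("tumor_volume must be > 0", call. = FALSE)
  if (decay_mode == "physical") A4 / tumor_volume
  else A4 * exp(-lambda_phys * t_abs) / tumor_volume
}
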