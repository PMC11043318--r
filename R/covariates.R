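#' Covariate set for one subject
#'
#' @param WT Body weight (kg).
#' @param TV Segmented tumor volume (L).
#' @param cycle_index Current treatment cycle (integer >= 1).
#' @param GFR Creatinine-based glomerular filtration rate (mL/min). Carried
#'   for completeness; renal function was tested and rejected as a covariate,
#'   so it never influences any model output.
#' @return A list of class `covariate_set`.
#' @export
covariate_set <- function(WT = 79, TV = 0.0443, cycle_index = 1L,
                          GFR = 80.9) {
  if (!is.finite(WT) || WT <= 0) stop("WT must be > 0", call. = FALSE)
  if (!is.finite(TV) || TV <= 0) stop("TV must be > 0", call. = FALSE)
  if (cycle_index < 1) stop("cycle_index must be >= 1", call. = FALSE)
  structure(list(WT = WT, TV = TV, cycle_index = as.integer(cycle_index),
                 GFR = GFR),
            class = "covariate_set")
}

#' Covariate adjustment of a population parameter
#'
#' Evaluates the three standard covariate parameterisations on a population
#' value: power `P * (cov/med)^theta`, linear `P + theta * (cov/med)` and
#' exponential `P * exp(theta * (cov/med))`.
#'
#' @param form One of `"power"`, `"linear"`, `"exponential"`.
#' @param P_pop Population parameter value.
#' @param theta_cov Covariate coefficient.
#' @param cov Individual covariate value.
#' @param cov_median Reference (median) covariate value, > 0.
#' @return The covariate-adjusted parameter value.
#' @examples
#' covariate_factor("power", 1, 1.08, 2 * 0.0443, 0.0443)  # 2^1.08 = 2.11
#' @export
covariate_factor <- function(form = c("power", "linear", "exponential"),
                             P_pop, theta_cov, cov, cov_median) {
  form <- match.arg(form)
  if (cov_median <= 0) stop("cov_median must be > 0", call. = FALSE)
  ratio <- cov / cov_median
  switch(form,
         power = {
           if (any(cov <= 0)) {
             stop("power covariate requires cov > 0", call. = FALSE)
           }
           P_pop * ratio^theta_cov
         },
         linear = P_pop + theta_cov * ratio,
         exponential = P_pop * exp(theta_cov * ratio))
}

#' Structural cycle effect on the tumor uptake rate
#'
#' Tumor uptake declines over treatment cycles: relative to cycle 1, k14 is
#' multiplied by 0.731 in cycle 2, 0.498 in cycle 3 and 0.436 in cycles 4-7.
#' Cycles beyond 7 reuse the 4-7 fraction with a warning (later cycles were
#' lumped in estimation; at most 8 cycles were observed).
#'
#' @param k14_base First-cycle tumor uptake rate (h^-1).
#' @param cycle_index Treatment cycle, integer >= 1.
#' @param cycle_fractions Length-3 numeric as in [pk_parameters()].
#' @return k14 applying in the given cycle.
#' @export
cycle_effect <- function(k14_base, cycle_index,
                         cycle_fractions = pk_parameters()$cycle_fractions) {
  if (cycle_index < 1) stop("cycle_index must be >= 1", call. = FALSE)
  if (cycle_index > 7) {
    warning("cycle_index > 7: reusing the cycle 4-7 fraction", call. = FALSE)
  }
  frac <- c(1, cycle_fractions[[1]], cycle_fractions[[2]],
            rep(cycle_fractions[[3]], 5))[min(cycle_index, 8)]
  k14_base * frac
}

#' Allometric body-weight scaling of the PK parameters
#'
#' Scales every rate constant by `(WT/WT_median)^-0.25` and the central
#' volume by `(WT/WT_median)^1`, the standard fixed allometric exponents.
#' The salivary binding capacity is an amount, not a rate or volume, and is
#' left unscaled.
#'
#' @param params A [pk_parameters()] object.
#' @param WT Body weight (kg).
#' @param WT_median Reference weight (kg); defaults to the value carried in
#'   `params`.
#' @return A `pk_parameters` object with scaled rates and volume.
#' @export
allometric_scale <- function(params, WT, WT_median = params$wt_median) {
  stopifnot(inherits(params, "pk_parameters"))
  if (WT <= 0) stop("WT must be > 0", call. = FALSE)
  r <- WT / WT_median
  out <- params
  for (k in c("k10", "k12", "k21", "k13", "k31", "k14", "k41", "k15", "k51")) {
    out[[k]] <- params[[k]] * r^(-0.25)
  }
  out$V1 <- params$V1 * r
  out
}

#' Individualized per-cycle parameter set
#'
#' Composes the population parameters, covariate effects, allometric scaling,
#' inter-individual random effects, inter-occasion effects and the structural
#' cycle effect into the effective parameters of one subject for each
#' treatment cycle. All retained factors are multiplicative, so the order of
#' application does not alter the result; the canonical order is population
#' value, covariate factor, allometric scaling, IIV, IOV (k14 only), cycle
#' effect (k14 only).
#'
#' On the PD side, baseline PSA receives the linear tumor-volume covariate
#' (literal form `PSA0 + theta * TV/TV_median` by default, giving 197.5 ug/L
#' at the median volume; the centered form `PSA0 + theta * (TV/TV_median - 1)`
#' is selectable) followed by its exponential random effect; the growth rate
#' uses a Box-Cox-transformed random effect; the two kill coefficients use
#' exponential random effects.
#'
#' @param params A [pk_parameters()] object (population values).
#' @param pd A [pd_parameters()] object, or `NULL` for PK-only use.
#' @param cov A [covariate_set()].
#' @param eta Named numeric of IIV effects (`eta_k10`, `eta_k13`, `eta_k14`,
#'   `eta_k15`, `eta_Bmax_sal`, `eta_PSA0`, `eta_kG`, `eta_kD_direct`,
#'   `eta_kD_delay`); missing names default to 0.
#' @param iov_k14 Numeric vector of per-occasion effects on k14, one per
#'   cycle; missing/short vectors are padded with 0.
#' @param n_cycles Number of treatment cycles to prepare.
#' @param psa0_form `"literal"` or `"centered"` baseline-PSA covariate form.
#' @param salivary_cycle_fractions Optional length-2 numeric (cycle-2 and
#'   cycle-3 fractions) switching on the exploratory salivary-gland cycle
#'   effect reported descriptively (0.846, 0.981) but absent from the final
#'   model; off (`NULL`) by default.
#' @return A list of class `individual_parameters` with elements
#'   `pk_by_cycle` (list of per-cycle `pk_parameters`), `pd` (individual PD
#'   values with internal-unit kill coefficients), `cov`, `eta`, `iov_k14`.
#' @export
individualize <- function(params, pd = NULL, cov = covariate_set(),
                          eta = NULL, iov_k14 = NULL, n_cycles = 1L,
                          psa0_form = c("literal", "centered"),
                          salivary_cycle_fractions = NULL) {
  stopifnot(inherits(params, "pk_parameters"), inherits(cov, "covariate_set"))
  psa0_form <- match.arg(psa0_form)
  for (f in c("WT", "TV")) {
    if (is.null(cov[[f]]) || !is.finite(cov[[f]])) {
      stop("missing covariate: ", f, call. = FALSE)
    }
  }
  get_eta <- function(name) {
    if (!is.null(eta) && name %in% names(eta)) eta[[name]] else 0
  }
  iov <- rep(0, n_cycles)
  if (!is.null(iov_k14)) iov[seq_along(iov_k14)] <- iov_k14

  ## covariate factors (tumor volume), then allometry, then IIV
  base <- params
  base$k12 <- covariate_factor("power", params$k12, params$theta_tv_k12,
                               cov$TV, params$tv_median)
  base$k14 <- covariate_factor("power", params$k14, params$theta_tv_k14,
                               cov$TV, params$tv_median)
  base <- allometric_scale(base, cov$WT)
  base$k10 <- base$k10 * exp(get_eta("eta_k10"))
  base$k13 <- base$k13 * exp(get_eta("eta_k13"))
  base$k14 <- base$k14 * exp(get_eta("eta_k14"))
  base$k15 <- base$k15 * exp(get_eta("eta_k15"))
  base$Bmax_sal <- base$Bmax_sal * exp(get_eta("eta_Bmax_sal"))

  pk_by_cycle <- purrr::map(seq_len(n_cycles), function(cyc) {
    p <- base
    p$k14 <- cycle_effect(p$k14 * exp(iov[cyc]), cyc, params$cycle_fractions)
    if (!is.null(salivary_cycle_fractions)) {
      sf <- c(1, salivary_cycle_fractions[1], salivary_cycle_fractions[2],
              rep(1, 5))[min(cyc, 8)]
      p$k12 <- p$k12 * sf
    }
    p
  })

  pd_ind <- NULL
  if (!is.null(pd)) {
    stopifnot(inherits(pd, "pd_parameters"))
    ratio <- cov$TV / params$tv_median
    psa0_typ <- switch(psa0_form,
                       literal = pd$PSA0 + pd$theta_tv_PSA0 * ratio,
                       centered = pd$PSA0 + pd$theta_tv_PSA0 * (ratio - 1))
    pd_ind <- list(
      PSA0 = psa0_typ * exp(get_eta("eta_PSA0")),
      kG = pd$kG * exp(boxcox_eta(get_eta("eta_kG"), pd$boxcox_shape)),
      kD_direct_h = kd_direct_hourly(pd$kD_direct) *
        exp(get_eta("eta_kD_direct")),
      ke0 = pd$ke0,
      kD_delay_h = kd_delay_hourly(pd$kD_delay) * exp(get_eta("eta_kD_delay")),
      EMAX = pd$EMAX, EC50 = pd$EC50, gamma = pd$gamma
    )
  }

  structure(list(pk_by_cycle = pk_by_cycle, pd = pd_ind, cov = cov,
                 eta = eta, iov_k14 = iov),
            class = "individual_parameters")
}
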