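#' Covariate distribution specification
#'
#' Medians and ranges of the clinical covariates used to build virtual
#' subjects. Each covariate is drawn from a split (two-piece) lognormal
#' distribution: on the log scale the lower and upper halves get their own
#' spread, calibrated so each range endpoint sits at the 0.5 percent tail of
#' its side; draws are truncated to the range. This preserves the median
#' exactly while respecting the strong asymmetry of the tumor-volume range.
#'
#' @param wt_median,wt_range Body weight median (kg) and range.
#' @param tv_median,tv_range Segmented tumor volume median (L) and range.
#' @return A list of class `covariate_spec`.
#' @export
covariate_spec <- function(wt_median = 79, wt_range = c(61, 116),
                           tv_median = 0.0443,
                           tv_range = c(0.000122, 0.546)) {
  for (x in list(c(wt_range[1], wt_median, wt_range[2]),
                 c(tv_range[1], tv_median, tv_range[2]))) {
    if (any(x <= 0) || is.unsorted(x)) {
      stop("ranges must be positive and bracket the median", call. = FALSE)
    }
  }
  structure(list(wt_median = wt_median, wt_range = wt_range,
                 tv_median = tv_median, tv_range = tv_range),
            class = "covariate_spec")
}

## split-lognormal sampler: median m, range (lo, hi) at the two-sided 99%
## level (0.5% tail each side)
.rsplitlnorm <- function(n, m, lo, hi) {
  z99 <- stats::qnorm(0.995)
  s_lo <- log(m / lo) / z99
  s_up <- log(hi / m) / z99
  if (s_lo == 0 && s_up == 0) return(rep(m, n))
  z <- stats::rnorm(n)
  x <- m * exp(ifelse(z < 0, s_lo, s_up) * z)
  pmin(pmax(x, lo), hi)
}

#' Generate a virtual patient population
#'
#' Draws `n` subjects with body weight and tumor volume from the covariate
#' specification (independently; no correlation was reported) and attaches
#' inter-individual and per-cycle inter-occasion random effects sampled from
#' the variability model.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the population is reproducible given the seed.
#' @param spec A [covariate_spec()].
#' @param vp A [variability_parameters()] object.
#' @param n_occasions Number of occasions (cycles) for which IOV is drawn.
#' @return A tibble of class `virtual_population`, one row per subject:
#'   `id`, `WT`, `TV`, the `eta_*` columns and list-column `iov_k14`.
#' @export
generate_virtual_population <- function(n, seed = NULL,
                                        spec = covariate_spec(),
                                        vp = variability_parameters(),
                                        n_occasions = 4L) {
  stopifnot(inherits(spec, "covariate_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  wt <- .rsplitlnorm(n, spec$wt_median, spec$wt_range[1], spec$wt_range[2])
  tv <- .rsplitlnorm(n, spec$tv_median, spec$tv_range[1], spec$tv_range[2])
  re <- sample_random_effects(vp, n, n_occasions = n_occasions, seed = NULL)
  out <- dplyr::bind_cols(tibble::tibble(id = seq_len(n), WT = wt, TV = tv),
                          re[-1])
  class(out) <- c("virtual_population", class(out))
  attr(out, "spec") <- spec
  out
}
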