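# a small two-cycle observation design shared across estimation tests
est_regimen <- function() regimen(c(0, 336), 7400, horizon = 800)

est_obs <- function(eta = NULL, iov = c(0, 0), cmts = 1:4) {
  pop <- zero_eta_pop(1, n_occ = 2)
  if (!is.null(eta)) for (nm in names(eta)) pop[[nm]] <- eta[[nm]]
  pop$iov_k14[[1]] <- iov
  schedule <- sampling_schedule(scan_sd = c(0, 0, 0))
  ds <- generate_spect_dataset(pop, est_regimen(), schedule = schedule,
                               seed = 1, noise = FALSE)
  ds[ds$EVID == 0 & ds$CMT %in% cmts, ]
}

test_that("the MAP objective is minimised at the generating random effects", {
  obs <- est_obs()
  which <- c("eta_k10", "eta_k14", "eta_Bmax_sal")
  at <- function(x) map_objective(stats::setNames(x, which), obs,
                                  est_regimen())
  f0 <- at(c(0, 0, 0))
  for (delta in list(c(0.3, 0, 0), c(0, -0.4, 0), c(0, 0, 0.5),
                     c(0.1, 0.1, -0.1))) {
    expect_gt(at(delta), f0)
  }
})

test_that("the likelihood term matches the closed-form normal deviance", {
  obs <- est_obs(cmts = 4)[1, ]  # single tumor observation
  pred <- obs$DV                 # noise-free data: prediction equals DV
  vp <- variability_parameters()
  om <- vp$omega[["k14"]]
  sg <- vp$sigma_prop[4]
  # exact match leaves only the log-variance constant
  f0 <- map_objective(c(eta_k14 = 0), obs, est_regimen())
  expect_equal(f0, log(2 * pi * (sg * pred)^2), tolerance = 1e-9)
  # hand-computed deviance for an arbitrary observed value
  obs2 <- obs
  obs2$DV <- 100
  v <- (sg * 100)^2
  f1 <- map_objective(c(eta_k14 = 0), obs2, est_regimen())
  expect_equal(f1, log(2 * pi * v) + (100 - pred)^2 / v, tolerance = 1e-9)
  # the prior penalty enters exactly as eta^2 / omega^2
  eta <- 0.25
  f2 <- map_objective(c(eta_k14 = eta), obs, est_regimen())
  f2_nopen <- f2 - eta^2 / om^2
  # removing the penalty leaves a pure (nonnegative-residual) deviance
  expect_gte(f2_nopen, log(2 * pi * (sg * pred)^2) - 1e-9)
})

test_that("duplicating observations doubles the likelihood contribution", {
  obs <- est_obs(cmts = c(2, 4))
  dup <- rbind(obs, obs)
  eta <- c(eta_k14 = 0.2, eta_Bmax_sal = -0.1)
  pen <- sum(eta^2 / variability_parameters()$omega[c("k14", "Bmax_sal")]^2)
  f1 <- map_objective(eta, obs, est_regimen())
  f2 <- map_objective(eta, dup, est_regimen())
  expect_equal(f2 - pen, 2 * (f1 - pen), tolerance = 1e-9)
})

# residual model tightened so the likelihood dominates the prior: the MAP
# estimate then converges to the maximum-likelihood effects, which clean
# data identify exactly (with the clinical sigmas the prior deliberately
# shrinks the estimate, tested separately below)
tight_vp <- function() {
  variability_parameters(sigma_prop_cv = c(central = 0.5, salivary = 0.5,
                                           kidneys = 0.5, tumor = 0.5,
                                           psa = 0.5),
                         sigma_add_central = 0.01)
}

test_that("MAP estimation recovers known random effects from clean data", {
  true_eta <- c(eta_k10 = 0.15, eta_k14 = 0.4, eta_Bmax_sal = -0.3)
  obs <- est_obs(eta = true_eta)
  fit <- map_estimate(obs, est_regimen(), vp = tight_vp(),
                      which = names(true_eta))
  expect_equal(unname(fit$eta[names(true_eta)]), unname(true_eta),
               tolerance = 1e-3)
  expect_equal(fit$predictions$PRED, obs$DV, tolerance = 1e-4)
  expect_s3_class(tidy(fit), "tbl_df")
  # per-occasion effects are recovered when they carry the signal
  true_iov <- c(0.25, -0.15)
  obs2 <- est_obs(iov = true_iov, cmts = 4)
  fit2 <- map_estimate(obs2, est_regimen(), vp = tight_vp(),
                       which = c("iov_k14_1", "iov_k14_2"))
  expect_equal(unname(fit2$eta), true_iov, tolerance = 1e-3)
})

test_that("with clinical variability the prior shrinks the MAP estimate", {
  true_eta <- c(eta_k14 = 0.4)
  obs <- est_obs(eta = true_eta, cmts = 4)
  fit <- map_estimate(obs, est_regimen(), which = "eta_k14")
  est <- fit$eta[["eta_k14"]]
  expect_gt(est, 0.3)   # data still dominate ...
  expect_lt(est, 0.4)   # ... but the estimate is pulled toward the prior
})

test_that("random effects shrink toward zero without informative data", {
  # tumor uptake effect generated at 0.6 but no tumor data observed
  obs <- est_obs(eta = c(eta_k14 = 0.6), cmts = c(1, 2, 3))
  fit <- map_estimate(obs, est_regimen(), which = c("eta_k14"))
  expect_lt(abs(fit$eta[["eta_k14"]]), 0.3)
})

test_that("naive-pooled fitting recovers structural truth from clean data", {
  pop <- zero_eta_pop(5, n_occ = 2)
  schedule <- sampling_schedule(scan_sd = c(0, 0, 0))
  ds <- generate_spect_dataset(pop, est_regimen(), schedule = schedule,
                               seed = 3, noise = FALSE)
  # renal excretion freed, started well away from the truth
  fit <- naive_pooled_fit(ds[ds$EVID != 0 | ds$CMT %in% c(1, 2, 3, 4), ],
                          free = "k10", start = c(k10 = 0.1))
  expect_equal(fit$estimates[["k10"]], 0.253, tolerance = 0.01)
  # cycle-2 tumor-uptake fraction freed on tumor data only
  tum <- ds[ds$EVID == 1 | ds$CMT == 4, ]
  fit2 <- naive_pooled_fit(tum, free = "cycle2", start = c(cycle2 = 0.5))
  expect_equal(fit2$estimates[["cycle2"]], 0.731, tolerance = 0.001)
  # with everything fixed the objective is the (zero) residual sum
  fit3 <- naive_pooled_fit(tum, free = character(0))
  expect_equal(fit3$objective, 0, tolerance = 1e-10)
  expect_error(naive_pooled_fit(tum, free = "k99"), "unknown free")
})

test_that("pooled PSA fitting recovers the growth rate", {
  pop <- zero_eta_pop(4)
  psa <- generate_psa_series(pop, build_regimen("2x2_repeated"), seed = 4,
                             noise = FALSE)
  fit <- naive_pooled_fit(psa, free = "kG", start = c(kG = 0.001))
  expect_equal(fit$estimates[["kG"]], 0.000408, tolerance = 0.001)
})
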