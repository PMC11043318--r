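test_that("drug-effect forms satisfy their defining identities", {
  pd <- pd_parameters(EMAX = 0.01, EC50 = 500, gamma = 2.5)
  expect_equal(drug_effect("linear", 0, pd), 0)
  expect_equal(drug_effect("emax", 0, pd), 0)
  expect_equal(drug_effect("sigmoid", 0, pd), 0)
  # half-maximal at C = EC50
  expect_equal(drug_effect("emax", 500, pd), 0.005)
  # sigmoid with unit hill coefficient reduces to emax
  pd1 <- pd_parameters(EMAX = 0.01, EC50 = 500, gamma = 1)
  for (C in c(1, 100, 500, 5000)) {
    expect_equal(drug_effect("sigmoid", C, pd1), drug_effect("emax", C, pd1))
  }
  # linear form uses the unit-converted reported coefficient
  expect_equal(drug_effect("linear", 1000, pd_parameters()),
               0.00335 / 24000 * 1000)
  expect_error(drug_effect("emax", 1, pd_parameters()), "EC50")
})

test_that("the effect compartment equilibrates and PSA follows its ODE", {
  ind <- individualize(pk_parameters(), pd_parameters(), covariate_set())
  # steady state: dCe/dt = 0 when Ce equals the driving concentration
  d <- pd_rhs(c(Ce = 750, PSA = 100), ind$pd, C_tumor = 750)
  expect_equal(unname(d[["dCe"]]), 0)
  # untreated growth: dPSA/dt = kG * PSA
  d0 <- pd_rhs(c(Ce = 0, PSA = 140), ind$pd, C_tumor = 0)
  expect_equal(unname(d0[["dPSA"]]), 0.000408 * 140)
})

test_that("untreated PSA grows exponentially with a 70.8-day doubling time", {
  reg <- regimen(0, activities = 0, horizon = 1699 * 2)
  traj <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                     times = c(0, 1699, 3398))
  expect_equal(log(2) / 0.000408, 1699, tolerance = 0.001)
  expect_equal(traj$PSA, 197.5 * exp(0.000408 * traj$time), tolerance = 1e-7)
})

test_that("zeroed kill coefficients leave PSA untouched by any regimen", {
  pd0 <- pd_parameters(kD_direct = 0, kD_delay = 0)
  traj <- solve_pkpd(build_regimen("4x6"), pk_parameters(), pd0,
                     times = seq(0, 4032, by = 336))
  expect_equal(traj$PSA, 197.5 * exp(0.000408 * traj$time), tolerance = 1e-7)
})

test_that("stronger kill coefficients strictly decrease PSA at every time", {
  base <- solve_pkpd(build_regimen("2x2_repeated"), pk_parameters(),
                     pd_parameters(), times = seq(24, 4032, by = 168))
  strong <- solve_pkpd(build_regimen("2x2_repeated"), pk_parameters(),
                       pd_parameters(kD_direct = 2 * 0.00335,
                                     kD_delay = 2 * 0.0000328),
                       times = seq(24, 4032, by = 168))
  after_start <- base$time > 0  # dose events are always in the output grid
  expect_true(all(strong$PSA[after_start] < base$PSA[after_start]))
  expect_true(all(base$PSA > 0))
})

test_that("log PSA obeys the analytic exposure identity for linear effects", {
  # log PSA(T) = log PSA0 + kG*T - kDd*AUC_Ctumor(T) - kDdel*AUC_Ce(T)
  reg <- build_regimen("2x2_repeated")
  traj <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                     times = seq(0, 4032, by = 0.5))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  ind <- individualize(pk_parameters(), pd_parameters(), covariate_set())
  lhs <- log(traj$PSA[nrow(traj)])
  rhs <- log(197.5) + 0.000408 * 4032 -
    ind$pd$kD_direct_h * trap(traj$time, traj$C_tumor) -
    ind$pd$kD_delay_h * trap(traj$time, traj$Ce)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("the effect compartment preserves exposure area in the long run", {
  # first-order filter: AUC(Ce) -> AUC(C_tumor) as T -> infinity
  reg <- regimen(0, 7400, horizon = 2 * 365 * 24)
  times <- c(seq(0, 504, by = 0.25), seq(505, 2 * 365 * 24, by = 4))
  traj <- solve_pkpd(reg, pk_parameters(), pd_parameters(), times = times)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  auc_c <- trap(traj$time, traj$C_tumor)
  auc_ce <- trap(traj$time, traj$Ce)
  expect_equal(auc_ce / auc_c, 1, tolerance = 1e-3)
})

test_that("the full PKPD trajectory matches the RK4 oracle", {
  reg <- build_regimen("2x2_repeated")
  ind <- individualize(pk_parameters(), pd_parameters(), covariate_set(),
                       n_cycles = 4)
  k14s <- vapply(ind$pk_by_cycle, function(p) p$k14, numeric(1))
  pd_o <- list(TV = 0.0443, ke0 = ind$pd$ke0, kG = ind$pd$kG,
               kD_direct_h = ind$pd$kD_direct_h,
               kD_delay_h = ind$pd$kD_delay_h)
  y <- oracle_solve(reg$dose_events$time, reg$dose_events$amt, k14s,
                    t_end = 4032, h = 0.05, k = oracle_k(), lam = 0,
                    pd = pd_o, psa0 = 197.5)
  traj <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                     times = c(0, 4032))
  got <- unlist(traj[traj$time == 4032,
                     c("A1", "A2", "A3", "A4", "A5", "Ce", "PSA")])
  expect_equal(unname(got), y, tolerance = 1e-6)
})
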