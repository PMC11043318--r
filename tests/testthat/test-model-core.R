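state0 <- c(A1 = 7400, A2 = 10, A3 = 5, A4 = 2, A5 = 100)

test_that("a closed system has zero derivatives", {
  p <- pk_parameters(k10 = 0, k12 = 0, k21 = 0, k13 = 0, k31 = 0, k14 = 0,
                     k41 = 0, k15 = 0, k51 = 0)
  d <- pk_rhs(state0, p, decay_mode = "corrected")
  expect_equal(unname(d), rep(0, 5))
})

test_that("saturable salivary uptake reduces to linear as Bmax grows", {
  p_lin <- pk_parameters(Bmax_sal = 1e12)
  d <- pk_rhs(state0, p_lin, decay_mode = "corrected")
  lin_dA2 <- p_lin$k12 * state0[["A1"]] - p_lin$k21 * state0[["A2"]]
  expect_equal(unname(d[["dA2"]]), lin_dA2, tolerance = 1e-9)
  # at finite Bmax the inflow is damped on both sides of the transfer
  p <- pk_parameters()
  d_sat <- pk_rhs(state0, p, decay_mode = "corrected")
  expect_lt(d_sat[["dA2"]], lin_dA2)
  # mass balance of the transfer: what salivary gains, central loses
  expect_equal(sum(d_sat) + p$k10 * state0[["A1"]], 0, tolerance = 1e-10)
})

test_that("physical mode adds uniform decay and rejects bad states", {
  p <- pk_parameters()
  d_c <- pk_rhs(state0, p, "corrected")
  d_p <- pk_rhs(state0, p, "physical")
  expect_equal(unname(d_p - d_c), unname(-p$lambda_phys * state0))
  expect_error(pk_rhs(c(A1 = -1, A2 = 0, A3 = 0, A4 = 0, A5 = 0), p),
               "finite and >= 0")
})

test_that("derived scalar quantities match the reported estimates", {
  expect_equal(effective_half_life(0.0150), 46.2, tolerance = 0.01)
  expect_equal(effective_half_life(0.0629), 11.0, tolerance = 0.01)
  expect_equal(effective_half_life(log(2)), 1.0)
  expect_error(effective_half_life(0), "> 0")
  expect_equal(renal_clearance(pk_parameters()), 2.61, tolerance = 0.005)
  expect_equal(renal_clearance(pk_parameters(k10 = 0)), 0)
  expect_equal(renal_clearance(pk_parameters(k10 = 1, V1 = 1)), 1)
})

test_that("tumor concentration handles both decay conventions", {
  expect_equal(tumor_concentration(0, 0.0443), 0)
  expect_equal(tumor_concentration(0, 0.0443, 100, "corrected"), 0)
  expect_equal(tumor_concentration(44.3, 0.0443), 1000)
  # a decay-corrected amount one physical half-life old halves
  t_half <- log(2) / lu177_lambda
  expect_equal(tumor_concentration(44.3, 0.0443, t_half, "corrected"), 500)
  expect_error(tumor_concentration(1, 0), "tumor_volume")
})

test_that("single-dose elimination-only kinetics match the closed form", {
  p <- pk_parameters(k12 = 0, k21 = 0, k13 = 0, k31 = 0, k14 = 0, k41 = 0,
                     k15 = 0, k51 = 0)
  reg <- regimen(0, 7400, horizon = 100)
  traj <- solve_pk(reg, p, times = seq(0, 100, by = 1),
                   decay_mode = "corrected")
  expect_equal(traj$conc_central[traj$time == 0], 7400 / 10.3,
               tolerance = 1e-8)
  expect_equal(7400 / 10.3, 718.4, tolerance = 1e-4)
  expect_equal(traj$conc_central,
               (7400 / 10.3) * exp(-0.253 * traj$time), tolerance = 1e-7)
})

test_that("zero-activity doses leave the system empty and PSA growing", {
  reg <- regimen(c(0, 336), activities = 0, horizon = 1000)
  traj <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                     times = seq(0, 1000, by = 50))
  expect_true(all(traj$A1 == 0 & traj$A4 == 0 & traj$Ce == 0))
  pd <- pd_parameters()
  psa0 <- 140 + 57.5  # literal baseline covariate at the median volume
  expect_equal(traj$PSA, psa0 * exp(pd$kG * traj$time), tolerance = 1e-8)
})

test_that("the linearized model superposes across doses", {
  # linear limit: saturation off and no per-cycle attenuation
  p <- pk_parameters(Bmax_sal = 1e12, cycle_fractions = c(1, 1, 1))
  times <- seq(0, 1512, by = 8)  # grid aligned with the 336 h dose shift
  two <- solve_pk(regimen(c(0, 336), 7400, horizon = 1512), p,
                  times = times, decay_mode = "corrected")
  one <- solve_pk(regimen(0, 7400, horizon = 1512), p, times = times,
                  decay_mode = "corrected")
  shift <- function(col) {
    stats::approx(one$time + 336, one[[col]], xout = times, yleft = 0)$y
  }
  for (col in c("A1", "A2", "A3", "A4", "A5")) {
    expect_equal(two[[col]], one[[col]] + shift(col), tolerance = 1e-8)
  }
})

test_that("mass is conserved without excretion and decay", {
  p <- pk_parameters(k10 = 0)
  reg <- regimen(c(0, 336, 1000), 7400, horizon = 2000)
  traj <- solve_pk(reg, p, times = seq(0, 2000, by = 40),
                   decay_mode = "corrected")
  total <- traj$A1 + traj$A2 + traj$A3 + traj$A4 + traj$A5
  injected <- 7400 * findInterval(traj$time, c(0, 336, 1000))
  expect_equal(total, injected, tolerance = 1e-8)
})

test_that("physical mode never exceeds injected activity and decays", {
  reg <- regimen(c(0, 336), 7400, horizon = 2000)
  traj <- solve_pk(reg, pk_parameters(), times = seq(0, 2000, by = 20),
                   decay_mode = "physical")
  total <- traj$A1 + traj$A2 + traj$A3 + traj$A4 + traj$A5
  injected <- 7400 * findInterval(traj$time, c(0, 336))
  expect_true(all(total <= injected + 1e-6))
  # with excretion off, decay alone bounds the envelope from below
  p0 <- pk_parameters(k10 = 0)
  tr0 <- solve_pk(reg, p0, times = seq(0, 2000, by = 20), "physical")
  tot0 <- tr0$A1 + tr0$A2 + tr0$A3 + tr0$A4 + tr0$A5
  lam <- p0$lambda_phys
  expected <- 7400 * exp(-lam * tr0$time) +
    ifelse(tr0$time >= 336, 7400 * exp(-lam * (tr0$time - 336)), 0)
  expect_equal(tot0, expected, tolerance = 1e-8)
})

test_that("the adaptive solver agrees with a brute-force RK4 oracle", {
  # 7-day single-dose horizon, full nonlinear model, both decay modes
  for (mode in c("corrected", "physical")) {
    lam <- if (mode == "physical") lu177_lambda else 0
    y_oracle <- oracle_solve(0, 7400, pk_parameters()$k14, t_end = 168,
                             h = 0.01, k = oracle_k(), lam = lam)
    traj <- solve_pk(regimen(0, 7400, horizon = 168), pk_parameters(),
                     times = c(0, 168), decay_mode = mode)
    got <- unlist(traj[traj$time == 168, c("A1", "A2", "A3", "A4", "A5")])
    expect_equal(unname(got), y_oracle, tolerance = 1e-6)
  }
})

test_that("compiled and reference engines agree", {
  reg <- build_regimen("2x2_repeated")
  a <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                  times = seq(0, 4032, by = 168))
  b <- solve_pkpd(reg, pk_parameters(), pd_parameters(),
                  times = seq(0, 4032, by = 168), engine = "R")
  expect_equal(a$PSA, b$PSA, tolerance = 1e-8)
  expect_equal(a$A4, b$A4, tolerance = 1e-8)
})

test_that("regimen construction and the clinical schedules are correct", {
  expect_equal(build_regimen("4x6")$dose_events$time,
               c(0, 1008, 2016, 3024))
  expect_equal(build_regimen("2x2_repeated")$dose_events$time,
               c(0, 336, 2016, 2352))
  expect_equal(build_regimen("4x6")$horizon, 4032)
  r <- regimen(0, 7400, horizon = 10)
  expect_equal(nrow(r$dose_events), 1)
  expect_error(regimen(c(10, 5), 7400, 100), "strictly increasing")
  expect_error(build_regimen("3x3"))
})
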