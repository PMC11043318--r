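test_that("SPECT-blood correction is linear and invertible", {
  expect_equal(blood_correction(6.27, "to_corrected"), 0)
  expect_equal(blood_correction(5.0, "to_corrected"), (5 - 6.27) / 0.828)
  expect_lt(blood_correction(5.0, "to_corrected"), 0)  # study would drop it
  x <- c(-3, 0, 6.27, 50, 1200)
  expect_equal(blood_correction(blood_correction(x, "to_corrected"),
                                "to_raw"), x)
  expect_equal(blood_correction(blood_correction(x, "to_raw"),
                                "to_corrected"), x)
})

test_that("sampling schedule validates its structure", {
  expect_error(sampling_schedule(scan_mean = c(24, 4.6, 163)), "increasing")
  expect_error(sampling_schedule(baseline_psa_window_weeks = 6), "< 6 weeks")
  s <- sampling_schedule()
  expect_equal(s$scan_mean, c(4.6, 23.8, 163.2))
  expect_equal(s$scan_sd, c(0.95, 4.5, 11.0))
})

test_that("noise-free datasets lie exactly on the model predictions", {
  pop <- zero_eta_pop(2, n_occ = 2)
  reg <- regimen(c(0, 336), 7400, horizon = 800)
  ds <- generate_spect_dataset(pop, reg, seed = 21, noise = FALSE)
  obs <- ds[ds$EVID == 0, ]
  ind <- individualize(pk_parameters(), NULL, covariate_set(), n_cycles = 2)
  for (id in unique(obs$ID)) {
    o <- obs[obs$ID == id, ]
    traj <- solve_pk(reg, pk_parameters(), times = sort(unique(o$TIME)),
                     decay_mode = "corrected")
    for (j in seq_len(nrow(o))) {
      row <- traj[traj$time == o$TIME[j], ]
      truth <- switch(as.character(o$CMT[j]),
                      "1" = row$conc_central, "2" = row$A2,
                      "3" = row$A3, "4" = row$A4)
      expect_equal(o$DV[j], truth, tolerance = 1e-10)
    }
  }
})

test_that("dataset dimensions follow the sampling design", {
  pop <- zero_eta_pop(76, n_occ = 2)
  reg <- regimen(c(0, 336), 7400, horizon = 800)
  ds <- generate_spect_dataset(pop, reg, seed = 5, noise = FALSE)
  # 76 subjects x 2 cycles x 3 scans x 4 compartments observation rows
  expect_equal(sum(ds$EVID == 0), 1824)
  expect_equal(sum(ds$EVID == 1), 76 * 2)
  psa <- generate_psa_series(pop, build_regimen("2x2_repeated"), seed = 5,
                             noise = FALSE)
  # one baseline + six 4-weekly draws per subject
  expect_equal(sum(psa$EVID == 0), 76 * 7)
})

test_that("generation is reproducible and filtering only removes rows", {
  pop <- generate_virtual_population(12, seed = 31, n_occasions = 2)
  reg <- regimen(c(0, 336), 7400, horizon = 800)
  a <- generate_spect_dataset(pop, reg, seed = 77)
  b <- generate_spect_dataset(pop, reg, seed = 77)
  expect_identical(a, b)
  f <- generate_spect_dataset(pop, reg, seed = 77, apply_filters = TRUE)
  expect_lte(nrow(f), nrow(a))
  expect_false(any(f$EVID == 0 & f$CMT == 1 & f$DV < 0))
  # surviving rows are untouched
  key <- function(d) paste(d$ID, d$TIME, d$CMT, d$EVID)
  expect_true(all(key(f) %in% key(a)))
  merged <- merge(f, a, by.x = c("ID", "TIME", "CMT", "EVID"),
                  by.y = c("ID", "TIME", "CMT", "EVID"))
  expect_equal(merged$DV.x, merged$DV.y)
  # write -> identical bytes under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(a, f1)
  write_dataset(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("scan-time jitter follows the configured distribution", {
  pop <- zero_eta_pop(400, n_occ = 1)
  reg <- regimen(0, 7400, horizon = 400)
  ds <- generate_spect_dataset(pop, reg, seed = 13, noise = FALSE)
  first_scan <- ds |>
    dplyr::filter(EVID == 0, CMT == 1) |>
    dplyr::group_by(ID) |>
    dplyr::summarise(t = min(TIME))
  expect_equal(mean(first_scan$t), 4.6, tolerance = 0.03)
  expect_equal(sd(first_scan$t), 0.95, tolerance = 0.12)
})

test_that("PSA series reflect growth and respond to truncation", {
  pop <- zero_eta_pop(3)
  psa <- generate_psa_series(pop, build_regimen("2x2_repeated"), seed = 9,
                             noise = FALSE,
                             pd = pd_parameters(kD_direct = 0, kD_delay = 0))
  # without drug effect every subject's series increases strictly
  for (id in unique(psa$ID)) {
    v <- psa$DV[psa$ID == id & psa$EVID == 0]
    expect_true(all(diff(v) > 0))
  }
  tr <- generate_psa_series(pop, build_regimen("2x2_repeated"), seed = 9,
                            noise = FALSE, truncate_at = 2016)
  expect_true(all(tr$TIME[tr$EVID == 0] <= 2016))
})

test_that("event datasets round-trip through CSV and validate on read", {
  pop <- generate_virtual_population(4, seed = 41, n_occasions = 2)
  reg <- regimen(c(0, 336), 7400, horizon = 800)
  ds <- generate_spect_dataset(pop, reg, seed = 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$DV, ds$DV, tolerance = 1e-12)
  expect_equal(back$TIME, ds$TIME, tolerance = 1e-12)
  expect_equal(back$CMT, ds$CMT)
  expect_equal(sum(is.na(back$AMT)), sum(ds$EVID == 0))

  bad <- ds
  bad$CMT[5] <- 9L
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(bad, p2)
  expect_error(read_dataset(p2), "unknown CMT code in row 5")

  oo <- ds[c(2, 1, 3:nrow(ds)), ]
  oo$TIME[1] <- 1e6
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(oo, p3)
  expect_error(read_dataset(p3), "non-monotone")
})
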