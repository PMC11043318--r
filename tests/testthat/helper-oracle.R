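# Independent fixed-step RK4 oracle for the compartment system.
#
# The right-hand side is written out here from the model equations,
# independently of the package's solver path, so that agreement between the
# two is a meaningful check.

oracle_rhs <- function(t, y, k, lam, pd = NULL) {
  sat <- 1 - y[2] / k$Bmax_sal
  f12 <- k$k12 * y[1] * sat
  d <- numeric(length(y))
  d[1] <- -(k$k10 + k$k13 + k$k14 + k$k15) * y[1] - f12 +
    k$k21 * y[2] + k$k31 * y[3] + k$k41 * y[4] + k$k51 * y[5] - lam * y[1]
  d[2] <- f12 - k$k21 * y[2] - lam * y[2]
  d[3] <- k$k13 * y[1] - k$k31 * y[3] - lam * y[3]
  d[4] <- k$k14 * y[1] - k$k41 * y[4] - lam * y[4]
  d[5] <- k$k15 * y[1] - k$k51 * y[5] - lam * y[5]
  if (!is.null(pd)) {
    Ct <- y[4] / pd$TV
    d[6] <- pd$ke0 * (Ct - y[6])
    d[7] <- (pd$kG - pd$kD_direct_h * Ct - pd$kD_delay_h * y[6]) * y[7]
  }
  d
}

# generic RK4 integrator, fixed step; returns state at t1
oracle_rk4 <- function(y, t0, t1, h, k, lam, pd = NULL) {
  n <- ceiling((t1 - t0) / h)
  h <- (t1 - t0) / n
  t <- t0
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(t, y, k, lam, pd)
    k2 <- oracle_rhs(t + h / 2, y + h / 2 * k1, k, lam, pd)
    k3 <- oracle_rhs(t + h / 2, y + h / 2 * k2, k, lam, pd)
    k4 <- oracle_rhs(t + h, y + h * k3, k, lam, pd)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# multi-dose RK4 oracle over a regimen; per-cycle k14 values supplied
oracle_solve <- function(dose_times, amts, k14_by_cycle, t_end, h, k, lam,
                         pd = NULL, psa0 = NULL) {
  y <- c(0, 0, 0, 0, 0)
  if (!is.null(pd)) y <- c(y, 0, psa0)
  for (i in seq_along(dose_times)) {
    y[1] <- y[1] + amts[i]
    seg_end <- if (i < length(dose_times)) dose_times[i + 1] else t_end
    k$k14 <- k14_by_cycle[i]
    y <- oracle_rk4(y, dose_times[i], seg_end, h, k, lam, pd)
  }
  y
}

# plain list of the population rate constants for the oracle
oracle_k <- function(p = pk_parameters()) {
  list(k10 = p$k10, k12 = p$k12, k21 = p$k21, k13 = p$k13, k31 = p$k31,
       k14 = p$k14, k41 = p$k41, k15 = p$k15, k51 = p$k51,
       Bmax_sal = p$Bmax_sal)
}

# a typical-covariate population tibble with all random effects zero
zero_eta_pop <- function(n, WT = 79, TV = 0.0443, n_occ = 4) {
  eta_names <- paste0("eta_", c("k10", "k13", "k14", "k15", "Bmax_sal",
                                "PSA0", "kG", "kD_direct", "kD_delay"))
  tb <- tibble::tibble(id = seq_len(n), WT = WT, TV = TV)
  for (nm in eta_names) tb[[nm]] <- 0
  tb$iov_k14 <- replicate(n, rep(0, n_occ), simplify = FALSE)
  class(tb) <- c("virtual_population", class(tb))
  tb
}
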