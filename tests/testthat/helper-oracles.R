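# Frozen oracle values and independent reference implementations used across
# the suite.

# Bethe mass stopping power of liquid water (I = 75 eV), frozen from an
# independent closed-form evaluation (scipy, double precision) of the same
# physics, cross-checked against published proton stopping-power tables
# before the build.
ORACLE_SP_WATER_10MEV <- 45.951426    # MeV cm^2/g, closed-form oracle
ORACLE_SP_WATER_100MEV <- 7.290925
PUBLISHED_SP_WATER_10MEV <- 45.67     # standard tabulation (with shell corr.)
PUBLISHED_SP_WATER_100MEV <- 7.289

# CSDA range of 12.5 MeV protons in water, frozen from step-halved adaptive
# quadrature of 1/(S/rho) converged to < 0.1%.
ORACLE_CSDA_WATER_12P5 <- 0.1813640   # g/cm^2

# Trapezoidal integral.
trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

# Forward step-by-step energy-loss oracle: 1 um Euler steps through the
# medium, returning depth (mm) and energy (MeV) tracks.  Independent of the
# package's range-table inversion.
euler_energy_track <- function(medium, e0, step_um = 1) {
  step_cm <- step_um * 1e-4
  e <- e0
  depth <- 0
  energies <- e0
  depths <- 0
  while (e > 0.05) {
    s <- mass_stopping_power(medium, e)      # MeV cm^2/g
    e <- e - s * medium$density * step_cm
    depth <- depth + step_cm
    energies <- c(energies, max(e, 0))
    depths <- c(depths, depth)
  }
  list(depth_mm = depths * 10, energy = energies)
}

# Linear-interpolated FWHM of a sampled profile (independent of the
# package's internal helper).
profile_fwhm <- function(x, y) {
  half <- max(y) / 2
  idx <- which(y >= half)
  lo <- min(idx); hi <- max(idx)
  left <- if (lo == 1L) x[1L] else
    x[lo - 1L] + (x[lo] - x[lo - 1L]) * (half - y[lo - 1L]) /
      (y[lo] - y[lo - 1L])
  right <- if (hi == length(y)) x[length(y)] else
    x[hi] + (x[hi + 1L] - x[hi]) * (half - y[hi]) / (y[hi + 1L] - y[hi])
  right - left
}

# Closed-form two-exponential solution of the constant-rate bleaching system
# (independent re-derivation used as the ODE-solver oracle).
closed_form_trace <- function(k_so, k_ion, eta, ratio, t) {
  a <- k_so + k_ion
  b <- ratio * a
  p <- exp(-a * t)
  q <- if (abs(b - a) < 1e-12) eta * k_so * t * exp(-a * t)
       else eta * k_so * (exp(-a * t) - exp(-b * t)) / (b - a)
  list(parent = p, photoproduct = q)
}

# Small inline MTT plate with a programmed viability for simulation studies.
make_mini_plate <- function(viability, n_wells = 3L, noise_sd = 0.05,
                            blank = 0.08, a0 = 1) {
  mk <- function(dose, ps, surv)
    data.frame(well = paste0("w", dose, ps, seq_len(n_wells)),
               absorbance = blank + a0 * surv *
                 (1 + noise_sd * stats::rnorm(n_wells)),
               dose_Gy = dose, ps_present = ps, ps_uM = 0,
               experiment_id = "E1", is_blank = FALSE)
  df <- rbind(mk(0, FALSE, 1), mk(2, FALSE, viability),
              data.frame(well = paste0("b", 1:3),
                         absorbance = blank * (1 + 0.02 * stats::rnorm(3)),
                         dose_Gy = 0, ps_present = FALSE, ps_uM = 0,
                         experiment_id = "E1", is_blank = TRUE))
  plate_readout(df)
}
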