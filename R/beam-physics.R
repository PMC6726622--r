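# Analytic proton transport: relativistic Bethe stopping power with Bragg
# additivity, CSDA ranges, residual-range depth-energy inversion and
# depth-dose (Bragg) curves with Gaussian energy spread.

# Physical constants (CODATA)
.ME_C2 <- 0.51099895       # electron rest energy, MeV
.MP_C2 <- 938.2720813      # proton rest energy, MeV
.K_BETHE <- 0.307075       # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.MEV_TO_GY_G <- 1.602176634e-10  # Gy * g / MeV

.E_MIN <- 0.05             # MeV, validity floor of the Bethe engine
.E_MAX <- 250              # MeV, table ceiling

# Bethe mass stopping power without validity checks; constant extrapolation
# below the .E_MIN floor.  Vectorised over `energy`.
.sp_raw <- function(medium, energy) {
  e <- pmax(energy, .E_MIN)
  gamma <- 1 + e / .MP_C2
  beta2 <- 1 - 1 / gamma^2
  i_mev <- medium$mean_excitation_energy * 1e-6
  .K_BETHE * medium$z_over_a / beta2 *
    (log(2 * .ME_C2 * beta2 * gamma^2 / i_mev) - beta2)
}

#' Proton mass stopping power of a medium
#'
#' Relativistic Bethe formula (no shell or Barkas corrections) with Bragg
#' additivity over the medium's elements.  Valid for proton kinetic energies
#' between 0.05 and 250 MeV.
#'
#' @param medium A [medium()] object.
#' @param energy Proton kinetic energy in MeV (vectorised).
#' @return Mass stopping power S/rho in MeV cm^2 / g.
#' @export
#' @examples
#' mass_stopping_power(builtin_medium("water"), c(10, 100))
mass_stopping_power <- function(medium, energy) {
  stopifnot(inherits(medium, "medium"), is.numeric(energy))
  if (any(energy < .E_MIN | energy > .E_MAX))
    stop(sprintf("energy outside validity window [%g, %g] MeV",
                 .E_MIN, .E_MAX))
  .sp_raw(medium, energy)
}

# Per-medium range/energy table cache.  Keyed on the fields that enter the
# stopping power, so user-defined media are cached too.
.table_cache <- new.env(parent = emptyenv())

.medium_key <- function(medium) {
  paste(medium$name, medium$density, medium$z_over_a,
        medium$mean_excitation_energy, sep = "|")
}

# Build a range-energy table for an arbitrary stopping-power function
# sfun(E) -> MeV cm^2/g on a log grid (constant extrapolation below .E_MIN).
.build_range_table <- function(sfun, n = 3000L, e_max = .E_MAX) {
  e <- exp(seq(log(.E_MIN), log(e_max), length.out = n))
  s <- sfun(e)
  inv <- 1 / s
  r0 <- .E_MIN / s[1L]
  dr <- diff(e) * (inv[-1L] + inv[-n]) / 2
  r <- r0 + c(0, cumsum(dr))
  list(energy_grid = e, s_over_rho = s, csda_range = r,
       range_of_energy = stats::splinefun(e, r, method = "hyman"),
       energy_of_range = stats::splinefun(r, e, method = "hyman"))
}

# Spread-averaged dose per fluence on a depth grid for a given range table.
.dose_from_table <- function(tab, sfun, medium, e_nodes, w_nodes, depth_mm) {
  dose <- numeric(length(depth_mm))
  r_min <- tab$csda_range[1L]
  for (j in seq_along(e_nodes)) {
    r_res <- tab$range_of_energy(e_nodes[j]) - (depth_mm / 10) * medium$density
    live <- r_res > r_min
    ez <- numeric(length(depth_mm))
    ez[live] <- pmin(tab$energy_of_range(r_res[live]), e_nodes[j])
    dj <- ifelse(ez > 0, sfun(pmax(ez, .E_MIN)) * .MEV_TO_GY_G, 0)
    dose <- dose + w_nodes[j] * dj
  }
  dose
}

#' Stopping-power and CSDA-range table for a medium
#'
#' Builds (and caches) a log-spaced table of S/rho and CSDA range over
#' 0.05-250 MeV, together with monotone spline interpolants for the
#' range-energy relation and its inverse (used by the residual-range method).
#'
#' @param medium A [medium()] object.
#' @param n Number of log-spaced energy nodes.
#' @return A list with `energy_grid` (MeV), `s_over_rho` (MeV cm^2/g),
#'   `csda_range` (g/cm^2) and interpolants `range_of_energy`,
#'   `energy_of_range`.
#' @export
stopping_power_table <- function(medium, n = 3000L) {
  key <- paste(.medium_key(medium), n, sep = "|")
  if (!is.null(tab <- .table_cache[[key]])) return(tab)
  tab <- .build_range_table(function(e) .sp_raw(medium, e), n)
  .table_cache[[key]] <- tab
  tab
}

#' CSDA range of a proton in a medium
#'
#' Continuous-slowing-down-approximation range, the integral of the inverse
#' mass stopping power from zero up to the given energy (with constant
#' extrapolation of S/rho below the 0.05 MeV validity floor).
#'
#' @inheritParams mass_stopping_power
#' @return Range in g/cm^2 (divide by the density for a depth in cm).
#' @export
#' @examples
#' csda_range(builtin_medium("dmso"), 12.5) / 1.10 * 10  # depth in mm
csda_range <- function(medium, energy) {
  stopifnot(inherits(medium, "medium"), is.numeric(energy))
  if (any(energy < .E_MIN | energy > .E_MAX))
    stop(sprintf("energy outside validity window [%g, %g] MeV",
                 .E_MIN, .E_MAX))
  stopping_power_table(medium)$range_of_energy(energy)
}

#' Define a proton beam
#'
#' @param entrance_energy Kinetic energy at the sample entrance, MeV.
#' @param energy_spread_fwhm_fraction Gaussian energy spread as a fraction of
#'   the entrance energy, full width at half maximum.  Default 0.001 (0.1\%),
#'   the value used for the beam simulations.
#' @param fluence_rate Protons per cm^2 per second entering the sample.
#' @param lateral_fwhm Lateral Gaussian FWHM of the beam spot, mm.
#' @return An object of class `proton_beam`.
#' @export
#' @examples
#' proton_beam(12.5, fluence_rate = 8e8)
proton_beam <- function(entrance_energy,
                        energy_spread_fwhm_fraction = 0.001,
                        fluence_rate = 0, lateral_fwhm = 10) {
  if (!is.numeric(entrance_energy) || entrance_energy <= 0)
    stop("`entrance_energy` must be > 0 (MeV)")
  if (energy_spread_fwhm_fraction < 0 || energy_spread_fwhm_fraction > 0.05)
    stop("`energy_spread_fwhm_fraction` must lie in [0, 0.05]")
  if (fluence_rate < 0) stop("`fluence_rate` must be >= 0")
  structure(
    list(entrance_energy = entrance_energy,
         energy_spread_fwhm_fraction = energy_spread_fwhm_fraction,
         fluence_rate = fluence_rate, lateral_fwhm = lateral_fwhm),
    class = "proton_beam")
}

#' @export
print.proton_beam <- function(x, ...) {
  cat(sprintf(
    "<proton_beam> %.4g MeV, spread %.3g%% FWHM, %.3g p cm^-2 s^-1\n",
    x$entrance_energy, 100 * x$energy_spread_fwhm_fraction, x$fluence_rate))
  invisible(x)
}

#' Proton energy at depth by the residual-range method
#'
#' The energy at depth z satisfies R(E0) - z * rho = R(E(z)); the range-energy
#' table is inverted by monotone spline.  Returns 0 at and beyond the end of
#' the range.
#'
#' @param beam A [proton_beam()] object, or a plain entrance energy in MeV.
#' @param medium A [medium()] object.
#' @param depth Depth in mm along the beam axis (z = 0 at the entrance
#'   window's inner face); vectorised.
#' @return Proton kinetic energy in MeV at each depth.
#' @export
#' @examples
#' energy_at_depth(12.5, builtin_medium("dmso"), c(0, 1, 1.7))
energy_at_depth <- function(beam, medium, depth) {
  e0 <- if (inherits(beam, "proton_beam")) beam$entrance_energy else beam
  stopifnot(is.numeric(e0), e0 > 0, inherits(medium, "medium"))
  if (any(depth < 0)) stop("`depth` must be >= 0 (mm)")
  tab <- stopping_power_table(medium)
  r_res <- tab$range_of_energy(e0) - (depth / 10) * medium$density
  e <- numeric(length(depth))
  r_min <- tab$csda_range[1L]
  live <- r_res > r_min
  e[live] <- pmin(tab$energy_of_range(r_res[live]), e0)
  # below the table floor the residual energy is linear in residual range
  tail_seg <- r_res > 0 & !live
  e[tail_seg] <- .E_MIN * r_res[tail_seg] / r_min
  e[depth == 0] <- e0
  e
}

# Deterministic Gaussian quadrature over the entrance-energy spread:
# 21 equi-spaced nodes over +-4 sigma with normalised Gaussian weights.
.spread_nodes <- function(e0, fwhm_fraction, n = 21L) {
  if (fwhm_fraction == 0)
    return(list(e = e0, w = 1))
  sigma <- fwhm_fraction * e0 / (2 * sqrt(2 * log(2)))
  x <- seq(-4, 4, length.out = n)
  w <- stats::dnorm(x)
  list(e = e0 + sigma * x, w = w / sum(w))
}

#' Depth-dose (Bragg) curve per unit fluence
#'
#' Dose per incident proton fluence at each depth, averaged over the beam's
#' Gaussian entrance-energy spread.  D(z) = (S/rho)(E(z)) * 1.602e-10 in
#' Gy per (proton/cm^2); dose is zero beyond the maximum range (the protons
#' stop - there is no exit dose).
#'
#' @param beam A [proton_beam()] object.
#' @param medium A [medium()] object.
#' @param depth_grid Strictly increasing depth grid in mm starting at 0.
#' @return An object of class `depth_dose_curve`: a list with `depth_mm`,
#'   `dose_per_fluence` (Gy per proton cm^-2), `energy_MeV` (nominal proton
#'   energy at depth), `medium` and `beam`.
#' @export
#' @examples
#' cur <- depth_dose(proton_beam(12.5), builtin_medium("dmso"),
#'                   seq(0, 2.5, by = 0.005))
#' bragg_peak_depth(cur)
depth_dose <- function(beam, medium, depth_grid) {
  stopifnot(inherits(beam, "proton_beam"), inherits(medium, "medium"))
  if (depth_grid[1L] != 0 || any(diff(depth_grid) <= 0))
    stop("`depth_grid` must start at 0 and be strictly increasing")
  nodes <- .spread_nodes(beam$entrance_energy,
                         beam$energy_spread_fwhm_fraction)
  tab <- stopping_power_table(medium)
  dose <- .dose_from_table(tab, function(e) .sp_raw(medium, e), medium,
                           nodes$e, nodes$w, depth_grid)
  structure(
    list(depth_mm = depth_grid, dose_per_fluence = dose,
         energy_MeV = energy_at_depth(beam$entrance_energy, medium,
                                      depth_grid),
         medium = medium, beam = beam),
    class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf(
    "<depth_dose_curve> %.4g MeV in %s: %d depths over [0, %.3g] mm\n",
    x$beam$entrance_energy, x$medium$name, length(x$depth_mm),
    max(x$depth_mm)))
  invisible(x)
}

#' Dose rate from fluence rate and stopping power
#'
#' D-dot = Phi-dot * (S/rho) * 1.602e-10, the fluence-to-dose conversion used
#' for the sample dosimetry.
#'
#' @param fluence_rate Protons cm^-2 s^-1 (>= 0).
#' @param s_over_rho Mass stopping power, MeV cm^2/g (>= 0).
#' @return Dose rate in Gy/s.
#' @export
#' @examples
#' sp <- mass_stopping_power(builtin_medium("dmso"), 12.5)
#' dose_rate(8e8, sp)
dose_rate <- function(fluence_rate, s_over_rho) {
  if (any(fluence_rate < 0)) stop("`fluence_rate` must be >= 0")
  if (any(s_over_rho < 0)) stop("`s_over_rho` must be >= 0")
  fluence_rate * s_over_rho * .MEV_TO_GY_G
}

# Sub-grid peak localisation: vertex of the parabola through the three points
# bracketing the grid argmax.  Shared by bragg_peak_depth() and
# locate_fluorescence_max().
.parabolic_peak <- function(x, y) {
  if (length(x) < 1L || length(x) != length(y))
    stop("profile must be non-empty with matching lengths")
  rng <- max(y) - min(y)
  if (rng <= 0 || rng < 1e-12 * max(abs(y), 1))
    stop("flat profile: peak position is degenerate")
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  x3 <- x[(i - 1L):(i + 1L)]
  y3 <- y[(i - 1L):(i + 1L)]
  # exact quadratic through three (possibly non-uniform) points
  d21 <- (y3[2L] - y3[1L]) / (x3[2L] - x3[1L])
  d32 <- (y3[3L] - y3[2L]) / (x3[3L] - x3[2L])
  a <- (d32 - d21) / (x3[3L] - x3[1L])
  if (a >= 0) return(x3[2L])  # no curvature: keep the grid point
  b <- d21 - a * (x3[1L] + x3[2L])
  -b / (2 * a)
}

#' Continuous irradiation time for a prescribed dose
#'
#' `dose / dose_rate`; at the ~0.66 Gy/s delivered within the Bragg peak, a
#' clinically relevant 60 Gy corresponds to roughly 90 s.
#'
#' @param dose_Gy Total dose, Gy.
#' @param dose_rate_Gy_s Dose rate, Gy/s (> 0).
#' @return Time in seconds.
#' @export
#' @examples
#' irradiation_time(60, 0.66)
irradiation_time <- function(dose_Gy, dose_rate_Gy_s) {
  if (any(dose_Gy < 0)) stop("`dose_Gy` must be >= 0")
  if (any(dose_rate_Gy_s <= 0)) stop("`dose_rate_Gy_s` must be > 0")
  dose_Gy / dose_rate_Gy_s
}

#' Depth of the Bragg peak
#'
#' Depth of maximum dose with sub-grid precision from a 3-point parabolic
#' interpolation around the grid maximum.
#'
#' @param curve A [depth_dose_curve][depth_dose()].
#' @return Peak depth in mm.
#' @export
bragg_peak_depth <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  .parabolic_peak(curve$depth_mm, curve$dose_per_fluence)
}
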