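water <- builtin_medium("water")
dmso <- builtin_medium("dmso")

test_that("medium constructor enforces its invariants", {
  expect_error(medium("x", 1, c(H = 0.5, O = 0.6)), "sum to 1")
  expect_error(medium("x", -1, c(H = 0.1119, O = 0.8881)), "density")
  expect_error(medium("x", 1, c(Xx = 1)), "unknown element")
  m <- medium("mix", 1.2, c(C = 0.5, O = 0.5))
  expect_gt(m$mean_excitation_energy, 0)
  expect_equal(m$z_over_a, 0.5 * 6 / 12.011 + 0.5 * 8 / 15.999)
  # explicit I override is honoured
  expect_equal(water$mean_excitation_energy, 75)
})

test_that("mass stopping power matches the closed-form oracle and published tables", {
  expect_equal(mass_stopping_power(water, 10), ORACLE_SP_WATER_10MEV,
               tolerance = 1e-6)
  expect_equal(mass_stopping_power(water, 100), ORACLE_SP_WATER_100MEV,
               tolerance = 1e-6)
  # shell/Barkas-free Bethe stays within 2% of the published values here
  expect_equal(mass_stopping_power(water, 10), PUBLISHED_SP_WATER_10MEV,
               tolerance = 0.02)
  expect_equal(mass_stopping_power(water, 100), PUBLISHED_SP_WATER_100MEV,
               tolerance = 0.02)
})

test_that("stopping power is monotone decreasing above the maximum and errors outside its window", {
  e <- c(1, 2, 5, 10, 20, 50, 100, 200)
  s <- mass_stopping_power(water, e)
  expect_true(all(diff(s) < 0))
  expect_error(mass_stopping_power(water, 0.01), "validity window")
  expect_error(mass_stopping_power(water, 300), "validity window")
})

test_that("compound stopping power equals the mass-fraction-weighted elemental sum", {
  # Bragg additivity: evaluate each element as a pure medium and combine
  fr <- dmso$composition
  for (e_test in c(5, 12.5, 60)) {
    elemental <- vapply(names(fr), function(el) {
      mass_stopping_power(medium(el, 1, stats::setNames(1, el)), e_test)
    }, 0)
    expect_equal(mass_stopping_power(dmso, e_test),
                 sum(fr * elemental), tolerance = 1e-12)
  }
})

test_that("CSDA range matches converged quadrature and the printed peak depth", {
  expect_equal(csda_range(water, 12.5), ORACLE_CSDA_WATER_12P5,
               tolerance = 2e-3)
  # simulated Bragg peak depth for the solution experiments: ~1.8 mm
  expect_equal(csda_range(dmso, 12.5) / dmso$density * 10, 1.8,
               tolerance = 0.1 / 1.8)
  e <- c(0.1, 1, 5, 12.5, 50, 200)
  expect_true(all(diff(csda_range(water, e)) > 0))
  # vanishing limit towards the validity floor
  expect_lt(csda_range(water, 0.05), 5e-4)
})

test_that("energy_at_depth inverts the range table", {
  expect_identical(energy_at_depth(12.5, dmso, 0), 12.5)
  end_mm <- csda_range(dmso, 12.5) / dmso$density * 10
  expect_equal(energy_at_depth(12.5, dmso, end_mm), 0, tolerance = 1e-6)
  expect_equal(energy_at_depth(12.5, dmso, end_mm + 0.5), 0)
  # mid-depth against the 1 um forward-Euler oracle
  trk <- euler_energy_track(dmso, 12.5)
  for (frac in c(0.25, 0.5, 0.8)) {
    z <- frac * max(trk$depth_mm)
    e_oracle <- stats::approx(trk$depth_mm, trk$energy, xout = z)$y
    expect_equal(energy_at_depth(12.5, dmso, z), e_oracle,
                 tolerance = 5e-3)
  }
})

test_that("depth_dose puts the 12.5 MeV DMSO Bragg peak at 1.8 mm and conserves energy", {
  beam <- proton_beam(12.5)
  grid <- seq(0, 2.5, by = 0.002)
  curve <- depth_dose(beam, dmso, grid)
  expect_equal(bragg_peak_depth(curve), 1.8, tolerance = 0.1 / 1.8)
  expect_true(all(curve$dose_per_fluence >= 0))
  # no dose beyond the range: the protons stop
  expect_true(all(curve$dose_per_fluence[grid > 2.0] == 0))
  e_dep <- trapz(grid / 10, curve$dose_per_fluence) * dmso$density /
    1.602176634e-10
  expect_equal(e_dep, 12.5, tolerance = 0.01)
})

test_that("energy spread preserves the dose integral and lowers/broadens the peak", {
  grid <- seq(0, 2.5, by = 0.002)
  sharp <- depth_dose(proton_beam(12.5, 0), dmso, grid)
  spread <- depth_dose(proton_beam(12.5, 0.02), dmso, grid)
  expect_equal(trapz(grid, sharp$dose_per_fluence),
               trapz(grid, spread$dose_per_fluence), tolerance = 1e-3)
  expect_lt(max(spread$dose_per_fluence), max(sharp$dose_per_fluence))
  expect_gt(profile_fwhm(grid, spread$dose_per_fluence),
            profile_fwhm(grid, sharp$dose_per_fluence))
})

test_that("200 MeV beam in soft tissue peaks at its CSDA depth", {
  tissue <- builtin_medium("soft_tissue")
  range_mm <- csda_range(tissue, 200) / tissue$density * 10
  curve <- depth_dose(proton_beam(200), tissue,
                      seq(0, ceiling(range_mm) + 5, by = 0.2))
  expect_equal(bragg_peak_depth(curve), range_mm, tolerance = 5e-3)
})

test_that("depth_dose rejects bad grids", {
  expect_error(depth_dose(proton_beam(12.5), dmso, c(0.5, 1)), "start at 0")
  expect_error(depth_dose(proton_beam(12.5), dmso, c(0, 1, 0.5)),
               "increasing")
})

test_that("dose rate is the stopping-power conversion, linear in fluence rate", {
  expect_identical(dose_rate(0, 40), 0)
  sp <- mass_stopping_power(dmso, 12.5)
  base <- dose_rate(1, sp)
  for (mag in 10^(4:8))                    # strict linearity over 5 decades
    expect_equal(dose_rate(mag, sp), mag * base)
  expect_equal(dose_rate(2 * 8e8, sp), 2 * dose_rate(8e8, sp))
  # printed entrance conversion: 8e8 p/cm^2/s ~ 5.3 Gy/s (within ~15%; the
  # pure-Bethe value is lower, see the package documentation)
  expect_equal(dose_rate(8e8, sp), 5.3, tolerance = 0.15)
  expect_error(dose_rate(-1, 40), ">= 0")
})

test_that("bragg_peak_depth finds the apex with sub-grid precision", {
  x <- seq(0, 2, by = 0.1)
  y <- 1 - abs(x - 1.1)                    # symmetric triangle, apex on-grid
  curve <- structure(list(depth_mm = x, dose_per_fluence = y,
                          medium = dmso, beam = proton_beam(12.5)),
                     class = "depth_dose_curve")
  expect_equal(bragg_peak_depth(curve), 1.1)
  # coarse-grid peak within one coarse step of a 10x finer grid argmax
  coarse <- depth_dose(proton_beam(12.5), dmso, seq(0, 2.2, by = 0.02))
  fine <- depth_dose(proton_beam(12.5), dmso, seq(0, 2.2, by = 0.002))
  fine_argmax <- fine$depth_mm[which.max(fine$dose_per_fluence)]
  expect_lt(abs(bragg_peak_depth(coarse) - fine_argmax), 0.02)
  flat <- structure(list(depth_mm = x, dose_per_fluence = rep(1, length(x)),
                         medium = dmso, beam = proton_beam(12.5)),
                    class = "depth_dose_curve")
  expect_error(bragg_peak_depth(flat), "flat")
})

test_that("proton_beam validates the energy spread window", {
  expect_error(proton_beam(-5), "entrance_energy")
  expect_error(proton_beam(12.5, 0.2), "0.05")
  expect_error(proton_beam(12.5, fluence_rate = -1), "fluence_rate")
})

test_that("irradiation time recovers the ~90 s clinical estimate", {
  expect_equal(irradiation_time(60, 0.66), 90, tolerance = 0.02)
  expect_error(irradiation_time(60, 0), "> 0")
})
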