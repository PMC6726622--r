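grid <- seq(0, 2, length.out = 31)

test_that("singlet-oxygen level follows the quenched-lifetime law", {
  acetone <- kinetic_params(so_lifetime = 1046e-6)
  water <- kinetic_params(so_lifetime = 3.45e-6)
  # solvent lifetime ratio at equal excitation: 1046 / 3.45
  expect_equal(singlet_oxygen_yield(1, acetone) /
                 singlet_oxygen_yield(1, water), 1046 / 3.45)
  # saturating DABCO kills the level
  sat <- kinetic_params(so_lifetime = 3.45e-6, dabco_conc = 1e6)
  expect_lt(singlet_oxygen_yield(1, sat), 1e-9 *
              singlet_oxygen_yield(1, water))
  # half suppression exactly at kq [DABCO] = 1 / lifetime
  half <- kinetic_params(so_lifetime = 3.45e-6, dabco_kq = 5e8,
                         dabco_conc = 1 / (3.45e-6 * 5e8))
  expect_equal(singlet_oxygen_yield(1, half),
               singlet_oxygen_yield(1, water) / 2)
  # monotone decreasing in DABCO
  lv <- vapply(c(0, 1e-3, 1e-2, 1e-1, 1), function(cc)
    singlet_oxygen_yield(1, kinetic_params(dabco_conc = cc)), 0)
  expect_true(all(diff(lv) < 0))
})

test_that("the adaptive solver matches the closed-form solution to 1e-6", {
  pars <- kinetic_params(sigma_so = 0.5, sigma_ion = 0.3, eta = 0.4,
                         degradation_ratio = 1.7)
  tr <- simulate_bleaching("proton", pars, grid)
  q <- 1  # no DABCO: unquenched
  cf <- closed_form_trace(0.5, 0.3, 0.4, 1.7, grid)
  expect_equal(tr$parent, cf$parent, tolerance = 1e-6)
  expect_equal(tr$photoproduct, cf$photoproduct, tolerance = 1e-6)
  # degenerate equal-rate branch (degradation_ratio = 1)
  pars1 <- kinetic_params(sigma_so = 0.5, sigma_ion = 0, eta = 0.4)
  tr1 <- simulate_bleaching("light", pars1, grid)
  cf1 <- closed_form_trace(0.5, 0, 0.4, 1, grid)
  expect_equal(tr1$photoproduct, cf1$photoproduct, tolerance = 1e-6)
})

test_that("zero rates give the identity trace", {
  tr <- simulate_bleaching("proton", kinetic_params(), grid)
  expect_equal(tr$parent, rep(1, length(grid)))
  expect_equal(tr$photoproduct, rep(0, length(grid)))
})

test_that("saturating DABCO separates the light and proton pathways", {
  pars <- kinetic_params(sigma_so = 0.5, sigma_ion = 0.3, eta = 0.4,
                         dabco_conc = 1e5)
  light <- simulate_bleaching("light", pars, grid)
  expect_equal(light$parent, rep(1, length(grid)), tolerance = 1e-8)
  expect_lt(max(light$photoproduct), 1e-8)
  proton <- simulate_bleaching("proton", pars, grid)
  expect_lt(min(proton$parent), 0.6)        # the ionisation channel persists
  expect_lt(max(proton$photoproduct), 1e-8)
  # without DABCO, proton mode loses more fluorescence and forms product
  pars0 <- kinetic_params(sigma_so = 0.5, sigma_ion = 0.3, eta = 0.4)
  proton0 <- simulate_bleaching("proton", pars0, grid)
  expect_lt(min(proton0$parent), min(proton$parent))
  expect_gt(max(proton0$photoproduct), 0.01)
})

test_that("mass-like bound and DABCO monotonicity hold across parameters", {
  set.seed(31)
  for (i in 1:12) {
    pars <- kinetic_params(sigma_so = runif(1, 0, 2),
                           sigma_ion = runif(1, 0, 2),
                           eta = runif(1), degradation_ratio = runif(1, 0, 3),
                           dabco_conc = sample(c(0, 1e-3, 0.2), 1))
    mode <- sample(c("light", "proton"), 1)
    tr <- simulate_bleaching(mode, pars, grid)
    if (pars$eta > 0)
      expect_true(all(tr$parent + tr$photoproduct / pars$eta <= 1 + 1e-8))
    expect_true(all(diff(tr$parent) <= 1e-12))
    expect_true(all(tr$photoproduct >= -1e-12))
  }
  # Q(t; c1) >= Q(t; c2) pointwise for c1 < c2 (within the bleaching regime
  # before parent depletion lets a slower channel catch up)
  grid_mono <- seq(0, 1.2, length.out = 25)
  qs <- lapply(c(0, 1e-3, 1e-2, 0.2), function(cc)
    simulate_bleaching("proton",
                       kinetic_params(sigma_so = 0.8, sigma_ion = 0.2,
                                      eta = 0.5, dabco_conc = cc),
                       grid_mono)$photoproduct)
  for (i in 1:3)
    expect_true(all(qs[[i]] >= qs[[i + 1L]] - 1e-10))
})

test_that("deconvolution reduces to Q at zero degradation and round-trips within 2%", {
  pars <- kinetic_params(sigma_so = 0.6, sigma_ion = 0.2, eta = 0.4,
                         degradation_ratio = 0)
  tr <- simulate_bleaching("proton", pars, grid)
  dec <- deconvolve_photoproduct(tr, pars)
  expect_equal(dec$formation, tr$photoproduct, tolerance = 1e-8)

  pars1 <- kinetic_params(sigma_so = 0.6, sigma_ion = 0.2, eta = 0.4,
                          degradation_ratio = 1)
  tr1 <- simulate_bleaching("proton", pars1, grid)
  dec1 <- deconvolve_photoproduct(tr1, pars1)
  a <- 0.8                                  # k_so + k_ion
  g_true <- 0.4 * 0.6 * (1 - exp(-a * grid)) / a
  expect_lt(max(abs(dec1$formation - g_true)) / max(g_true), 0.02)
  expect_true(all(diff(dec1$formation) >= -1e-12))

  bad <- tr1
  bad$parent <- rev(bad$parent)
  expect_error(deconvolve_photoproduct(bad, pars1), "monotone")
})

test_that("deconvolved formation is comparable across modes and higher for protons", {
  # equal sigma_so; proton mode driven at higher excitation density
  pars <- kinetic_params(sigma_so = 0.25, sigma_ion = 0.22, eta = 0.3)
  light <- simulate_bleaching("light", pars, grid, excitation_rate = 1)
  proton <- simulate_bleaching("proton", pars, grid, excitation_rate = 3.6)
  g_l <- deconvolve_photoproduct(light, pars)$formation
  g_p <- deconvolve_photoproduct(proton, pars)$formation
  expect_gt(g_p[length(g_p)], g_l[length(g_l)])
  expect_lt(g_p[length(g_p)] / g_l[length(g_l)], 10)  # same order
})

test_that("fit_kinetics recovers parameters exactly on noise-free data and flags unidentifiable designs", {
  kt <- make_kinetic_traces(generator_config(1, "kinetics", noise_sd = 0))
  fit <- fit_kinetics(kt$traces, kinetic_params(eta = 0.3), n_boot = 5)
  expect_equal(unname(fit$estimates["sigma_so"]), kt$truth$sigma_so,
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates["sigma_ion"]), kt$truth$sigma_ion,
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates["eta"]), kt$truth$eta, tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-9)

  light_only <- kt$traces[c("light", "light_dabco")]
  expect_error(fit_kinetics(light_only, kinetic_params()), "light-only")
  one_cond <- kt$traces[c("proton", "proton")]
  expect_error(fit_kinetics(one_cond, kinetic_params()), "DABCO")
})

test_that("fit_kinetics is reasonable under 3% noise with bootstrap intervals", {
  kt <- make_kinetic_traces(generator_config(42, "kinetics"))
  fit <- fit_kinetics(kt$traces, kinetic_params(eta = 0.3), n_boot = 20)
  expect_equal(unname(fit$estimates["sigma_so"]), kt$truth$sigma_so,
               tolerance = 0.15)
  expect_equal(unname(fit$estimates["sigma_ion"]), kt$truth$sigma_ion,
               tolerance = 0.15)
  expect_true(all(fit$ci[, "upper"] > fit$ci[, "lower"]))
  # bootstrap is seeded: same call, same intervals
  fit2 <- fit_kinetics(kt$traces, kinetic_params(eta = 0.3), n_boot = 20)
  expect_identical(fit$ci, fit2$ci)
})

test_that("phosphorescence ratio recovers the gel contrast", {
  # identical spectra -> ratio 1
  wl <- seq(480, 800, by = 1)
  y <- 900 * exp(-(wl - 560)^2 / (2 * 12^2)) +
    500 * exp(-(wl - 695)^2 / (2 * 18^2)) + 10
  s <- emission_spectrum(wl, y)
  pr <- phosphorescence_ratio(s, s)
  expect_equal(pr$ratio, 1, tolerance = 1e-6)
  expect_false(pr$lower_bound)

  # ErB-like vs RoseB-like gels built 40x apart
  g <- make_spectra(generator_config(1, "gels"))
  pr40 <- phosphorescence_ratio(g$roseb, g$erb)
  expect_equal(pr40$ratio, g$truth$phos_ratio, tolerance = 0.05)
  expect_false(pr40$lower_bound)

  # zero quenched band -> lower bound with flag
  y0 <- 900 * exp(-(wl - 560)^2 / (2 * 12^2)) + 10
  pr0 <- phosphorescence_ratio(emission_spectrum(wl, y0), s)
  expect_true(pr0$lower_bound)
  expect_gt(pr0$ratio, 100)
})
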