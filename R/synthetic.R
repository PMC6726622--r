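# Seeded synthetic-data generators for every input the pipeline consumes.
# Each generator is deterministic under its seed and embeds the full ground
# truth alongside the data, so every module is testable without raw data.

#' Generator configuration
#'
#' @param seed Integer seed; the same seed and configuration produce
#'   identical outputs.
#' @param scenario Named preset: `"solution-imaging"` (beam-fluorescence
#'   image pairs), `"kinetics"` (bleaching traces), `"gels"` (dry-gel
#'   spectra), `"cells"` (MTT plates) or `"nir"` (1270 nm singlet-oxygen
#'   band).
#' @param ... Named overrides of scenario parameters, stored in `$params`.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             scenario = c("solution-imaging", "kinetics",
                                          "gels", "cells", "nir"), ...) {
  scenario <- match.arg(scenario)
  structure(list(seed = as.integer(seed), scenario = scenario,
                 params = list(...)),
            class = "generator_config")
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Merge user overrides into scenario defaults.
.gen_params <- function(config, defaults) {
  ov <- config$params
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad))
    stop("unknown generator parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  defaults
}

#' Generate a synthetic beam-fluorescence image pair
#'
#' Emulates the camera acquisition of proton-induced photosensitiser
#' fluorescence in a cuvette: a lit frame containing the Bragg-shaped
#' fluorescence field (a lateral-Gaussian beam times the model
#' [fluorescence_vs_depth()] profile, red-dominant), a dark frame sharing
#' the static bench background, Poisson photon noise and 8-bit quantisation.
#' The default preset is the 12.5 MeV beam in DMSO with ErB at 110 uM and an
#' enhancement placing the true fluorescence maximum between the measured
#' 1.6 mm and the simulated 1.8 mm peak.
#'
#' @param config A [generator_config()] (scenario `"solution-imaging"`).
#'   Overridable parameters include `energy`, `enhancement`, `amplitude`,
#'   `pixel_scale`, `shift` (row/col displacement of the dark frame) and
#'   `dark_level`.
#' @return List with `lit` and `dark` ([beam_image()] pair) and `truth`
#'   (peak depth in mm, applied shift, generator parameters).
#' @export
make_beam_image <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  p <- .gen_params(config, list(
    energy = 12.5, medium = "dmso", ps_concentration = 110e-6,
    fluorescence_yield = 0.1, enhancement = 800,
    pixel_scale = 0.025, depth_extent_mm = 2.2, entrance_px = 12L,
    lateral_px = 400L, lateral_fwhm_mm = 10, amplitude = 150,
    dark_level = 8, bench_amplitude = 6, shift = c(0L, 0L)))
  med <- builtin_medium(p$medium)
  beam <- proton_beam(p$energy, fluence_rate = 32e9,
                      lateral_fwhm = p$lateral_fwhm_mm)
  fine <- seq(0, p$depth_extent_mm, by = 0.002)
  curve <- depth_dose(beam, med, fine)
  ps <- photosensitiser("ErB", p$ps_concentration,
                        fluorescence_yield = p$fluorescence_yield,
                        isc_yield = 0.6)
  prof <- fluorescence_vs_depth(curve, ps, p$enhancement)
  truth_peak <- .parabolic_peak(prof$depth_mm, prof$intensity)

  n_depth <- p$entrance_px + ceiling(p$depth_extent_mm / p$pixel_scale)
  n_lat <- p$lateral_px
  depth_mm <- (seq_len(n_depth) - p$entrance_px) * p$pixel_scale
  sig_depth <- stats::approx(prof$depth_mm,
                             prof$intensity / max(prof$intensity),
                             xout = depth_mm, yleft = 0, yright = 0)$y
  lat_sigma_px <- p$lateral_fwhm_mm / p$pixel_scale / (2 * sqrt(2 * log(2)))
  lat <- exp(-((seq_len(n_lat) - (n_lat + 1) / 2)^2) / (2 * lat_sigma_px^2))
  field <- p$amplitude * outer(lat, sig_depth)     # [lateral, depth]

  # static bench background shared by both frames
  bench <- p$bench_amplitude *
    (1 + outer(sin(seq_len(n_lat) / 37), cos(seq_len(n_depth) / 23))) / 2
  base_mean <- p$dark_level + bench
  out <- .with_seed(config$seed, {
    base <- array(stats::rpois(n_lat * n_depth * 3L, rep(base_mean, 3L)),
                  dim = c(n_lat, n_depth, 3L))
    chan <- c(0.8, 0.15, 0.05)  # red-dominant emission through the filter
    signal <- array(0, dim = dim(base))
    for (k in 1:3)
      signal[, , k] <- stats::rpois(n_lat * n_depth, chan[k] * field)
    lit_px <- pmin(pmax(base + signal, 0), 255)
    dr <- p$shift[1L]; dc <- p$shift[2L]
    dark_px <- array(stats::rpois(n_lat * n_depth * 3L,
                                  rep(p$dark_level, n_lat * n_depth * 3L)),
                     dim = dim(base))
    r1 <- max(1L, 1L + dr):min(n_lat, n_lat + dr)
    c1 <- max(1L, 1L + dc):min(n_depth, n_depth + dc)
    if (all(p$shift == 0L)) {
      dark_px <- base
    } else {
      dark_px[r1, c1, ] <- base[r1 - dr, c1 - dc, ]
    }
    dark_px <- pmin(pmax(dark_px, 0), 255)
    list(lit = lit_px, dark = dark_px)
  })
  list(
    lit = beam_image(out$lit, p$pixel_scale, "column", p$entrance_px),
    dark = beam_image(out$dark, p$pixel_scale, "column", p$entrance_px),
    truth = list(peak_depth_mm = truth_peak, shift = p$shift, params = p))
}

#' Generate synthetic emission spectra
#'
#' Gaussian emission bands on a flat dark background with sparse
#' high-amplitude single-channel spikes (the CCD artefacts of ionising
#' radiation) and Poisson counting noise.  Three presets:
#' `"solution-imaging"`/`"kinetics"` return a (proton, photon, dark,
#' solvent) visible-range set sharing band structure, the proton spectrum
#' carrying the spikes; `"gels"` returns ErB-like and RoseB-like dry-gel
#' spectra whose phosphorescence bands differ by `phos_ratio` (default 40);
#' `"nir"` returns a weak 1270 nm singlet-oxygen band atop dark + solvent at
#' a configurable signal-to-noise ratio.
#'
#' @param config A [generator_config()].
#' @return Named list of [emission_spectrum()] objects plus `truth` (band
#'   parameters, spike channels, SNR where applicable).
#' @export
make_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$scenario == "gels") return(.make_gel_spectra(config))
  if (config$scenario == "nir") return(.make_nir_spectra(config))
  p <- .gen_params(config, list(
    bands = data.frame(centre = c(635, 705), sigma = c(12, 16),
                       amplitude = c(1000, 320)),
    dark_level = 20, solvent_amplitude = 15, proton_scale = 0.8,
    spike_rate = 0.02, spike_amplitude = 40, noise = "poisson"))
  wl <- seq(450, 780, by = 1)
  clean <- function(scale) {
    y <- rep(0, length(wl))
    for (i in seq_len(nrow(p$bands)))
      y <- y + scale * p$bands$amplitude[i] *
        exp(-(wl - p$bands$centre[i])^2 / (2 * p$bands$sigma[i]^2))
    y
  }
  solvent_band <- p$solvent_amplitude * exp(-(wl - 520)^2 / (2 * 60^2))
  out <- .with_seed(config$seed, {
    noisy <- function(mean_counts) stats::rpois(length(wl),
                                                pmax(mean_counts, 0))
    n_spikes <- stats::rpois(1L, p$spike_rate * length(wl))
    spike_at <- sample(length(wl), n_spikes)
    proton_mean <- clean(p$proton_scale) + p$dark_level + solvent_band
    proton <- noisy(proton_mean)
    proton[spike_at] <- proton[spike_at] +
      p$spike_amplitude * sqrt(pmax(proton_mean[spike_at], 1)) *
      stats::runif(n_spikes, 0.8, 1.5)
    list(proton = proton, photon = noisy(clean(1) + p$dark_level +
                                         solvent_band),
         dark = noisy(rep(p$dark_level, length(wl))),
         solvent = noisy(solvent_band + p$dark_level),
         spike_at = spike_at)
  })
  list(
    proton = emission_spectrum(wl, out$proton,
                               metadata = list(excitation = "proton")),
    photon = emission_spectrum(wl, out$photon,
                               metadata = list(excitation = "photon")),
    dark = emission_spectrum(wl, out$dark),
    solvent = emission_spectrum(wl, out$solvent),
    truth = list(bands = p$bands, spike_channels = out$spike_at, params = p))
}

.make_gel_spectra <- function(config) {
  p <- .gen_params(config, list(
    phos_ratio = 40, phos_amplitude = 1200, phos_sigma = 20,
    fluor_amplitude = 2500, fluor_sigma = 12, dark_level = 10,
    noise = "poisson"))
  wl <- seq(480, 800, by = 1)
  shape <- function(fc, fa, pc, pa) {
    fa * exp(-(wl - fc)^2 / (2 * p$fluor_sigma^2)) +
      pa * exp(-(wl - pc)^2 / (2 * p$phos_sigma^2)) + p$dark_level
  }
  erb_mean <- shape(555, p$fluor_amplitude, 690, p$phos_amplitude)
  roseb_mean <- shape(575, 0.9 * p$fluor_amplitude, 700,
                      p$phos_amplitude / p$phos_ratio)
  out <- .with_seed(config$seed, list(
    erb = stats::rpois(length(wl), erb_mean),
    roseb = stats::rpois(length(wl), roseb_mean)))
  list(
    erb = emission_spectrum(wl, out$erb, metadata = list(gel = "ErB")),
    roseb = emission_spectrum(wl, out$roseb, metadata = list(gel = "RoseB")),
    truth = list(phos_ratio = p$phos_ratio,
                 phos_area_erb = p$phos_amplitude * p$phos_sigma *
                   sqrt(2 * pi),
                 params = p))
}

.make_nir_spectra <- function(config) {
  p <- .gen_params(config, list(
    band_centre = 1270, band_sigma = 15, snr = 1, dark_level = 50,
    solvent_amplitude = 12))
  wl <- seq(1150, 1400, by = 2)
  noise_sd <- sqrt(p$dark_level)
  amp <- p$snr * noise_sd
  band <- amp * exp(-(wl - p$band_centre)^2 / (2 * p$band_sigma^2))
  solvent_band <- p$solvent_amplitude * exp(-(wl - 1200)^2 / (2 * 80^2))
  out <- .with_seed(config$seed, list(
    sample = stats::rpois(length(wl),
                          band + solvent_band + p$dark_level),
    dark = stats::rpois(length(wl), rep(p$dark_level, length(wl))),
    solvent = stats::rpois(length(wl), solvent_band + p$dark_level)))
  list(
    sample = emission_spectrum(wl, out$sample, channel = "nir"),
    dark = emission_spectrum(wl, out$dark, channel = "nir"),
    solvent = emission_spectrum(wl, out$solvent, channel = "nir"),
    truth = list(band_area = amp * p$band_sigma * sqrt(2 * pi),
                 snr = p$snr, params = p))
}

# Stated-world kinetics: exposure axis normalised to [0, 1]; light-mode
# maximum fluorescence loss ~20%, proton-mode ~80%, DABCO protecting ~25
# points in proton mode.  sigma_so = -log(0.8) gives the light-mode loss;
# the proton excitation density and sigma_ion follow from the other two.
.kinetics_defaults <- local({
  a_light <- -log(0.80)                 # 20% light-mode loss
  a_proton <- -log(0.20)                # 80% proton-mode loss
  a_proton_dabco <- -log(0.20 + 0.25)   # 55% loss under saturating DABCO
  x_proton <- (a_proton - a_proton_dabco) / a_light  # excitation ratio
  list(sigma_so = a_light, sigma_ion = a_proton_dabco / x_proton,
       excitation_proton = x_proton, eta = 0.3, degradation_ratio = 1,
       so_lifetime = 3.45e-6, dabco_kq = 5e8, dabco_conc = 0.2,
       noise_sd = 0.03, n_points = 25L)
})

#' Generate synthetic bleaching/photoproduct traces
#'
#' Forward solutions of the two-pathway bleaching model across the four
#' (mode x DABCO) conditions with multiplicative Gaussian noise.  The default
#' truth reproduces the observed contrasts: maximum fluorescence loss of
#' about 20% under light, 80% under protons, with DABCO restoring about 25
#' points in proton mode and everything in light mode, and no photoproduct
#' under saturating DABCO.
#'
#' @param config A [generator_config()] (scenario `"kinetics"`).
#'   Overridable: `sigma_so`, `sigma_ion`, `excitation_proton`, `eta`,
#'   `degradation_ratio`, `so_lifetime`, `dabco_kq`, `dabco_conc`,
#'   `noise_sd`, `n_points`.
#' @return List with `traces` (list of [kinetic_trace()] across conditions)
#'   and `truth` (the generating [kinetic_params()] and settings).
#' @export
make_kinetic_traces <- function(config = generator_config(seed = 1L,
                                                          "kinetics")) {
  stopifnot(inherits(config, "generator_config"))
  p <- .gen_params(config, .kinetics_defaults)
  grid <- seq(0, 1, length.out = p$n_points)
  conds <- expand.grid(mode = c("light", "proton"),
                       dabco = c(0, p$dabco_conc),
                       stringsAsFactors = FALSE)
  traces <- .with_seed(config$seed, {
    lapply(seq_len(nrow(conds)), function(i) {
      pars <- kinetic_params(
        so_lifetime = p$so_lifetime, dabco_kq = p$dabco_kq,
        dabco_conc = conds$dabco[i], sigma_so = p$sigma_so,
        sigma_ion = p$sigma_ion, eta = p$eta,
        degradation_ratio = p$degradation_ratio)
      xr <- if (conds$mode[i] == "proton") p$excitation_proton else 1
      tr <- simulate_bleaching(conds$mode[i], pars, grid,
                               excitation_rate = xr)
      if (p$noise_sd > 0) {
        np <- length(grid)
        parent <- tr$parent *
          (1 + p$noise_sd * stats::rnorm(np))
        q <- tr$photoproduct * (1 + p$noise_sd * stats::rnorm(np))
        parent[1L] <- 1
        parent <- pmax(parent, 1e-6)
        tr <- kinetic_trace(grid, pmin(parent, 1), pmax(q, 0),
                            mode = conds$mode[i],
                            dabco_conc = conds$dabco[i],
                            excitation_rate = xr)
      }
      tr
    })
  })
  names(traces) <- paste0(conds$mode,
                          ifelse(conds$dabco > 0, "_dabco", ""))
  list(traces = traces,
       truth = list(sigma_so = p$sigma_so, sigma_ion = p$sigma_ion,
                    eta = p$eta, excitation_proton = p$excitation_proton,
                    params = p))
}

#' Generate a synthetic MTT plate suite
#'
#' Per-well absorbances from the linear-quadratic proton-dynamic survival
#' model [simulate_survival()], with a blank offset, a per-experiment beam
#' scale factor and multiplicative Gaussian well noise; at least 3 wells per
#' condition and matched dose-0 controls for both photosensitiser states.
#' The proton-dynamic coefficient is solved so that the programmed mean
#' differential gain across the irradiated doses equals `target_gain`
#' (default 0.19, i.e. 19 percentage points).
#'
#' @param config A [generator_config()] (scenario `"cells"`).  Overridable:
#'   `doses`, `n_experiments`, `n_wells`, `lq_alpha`, `lq_beta`, `rbe`,
#'   `ps_conc`, `target_gain`, `noise_sd`, `blank`, `a0`, `scale_range`.
#' @return List with `readout` (a [plate_readout()]) and `truth`
#'   (programmed viabilities, per-dose gains, solved `pd_coefficient`).
#' @export
make_plates <- function(config = generator_config(seed = 1L, "cells")) {
  stopifnot(inherits(config, "generator_config"))
  p <- .gen_params(config, list(
    doses = c(0, 2, 5, 10), n_experiments = 5L, n_wells = 3L,
    lq_alpha = 0.08, lq_beta = 0.006, rbe = 1.1, ps_conc = 6e-6,
    target_gain = 0.19, noise_sd = 0.05, blank = 0.08, a0 = 1.0,
    scale_range = c(0.9, 1.1)))
  dpos <- p$doses[p$doses > 0]
  pd <- if (p$target_gain > 0 && length(dpos)) {
    gain_at <- function(pd) {
      s0 <- simulate_survival(dpos, p$lq_alpha, p$lq_beta, 0, 0, p$rbe)
      s1 <- simulate_survival(dpos, p$lq_alpha, p$lq_beta, pd, p$ps_conc,
                              p$rbe)
      mean(s0 - s1) - p$target_gain
    }
    stats::uniroot(gain_at, c(0, 1e7 / max(1, p$ps_conc * 1e6)),
                   tol = 1e-10)$root
  } else 0
  s_no <- simulate_survival(p$doses, p$lq_alpha, p$lq_beta, 0, 0, p$rbe)
  s_ps <- simulate_survival(p$doses, p$lq_alpha, p$lq_beta, pd, p$ps_conc,
                            p$rbe)
  df <- .with_seed(config$seed, {
    rows <- list()
    wid <- 0L
    for (ex in seq_len(p$n_experiments)) {
      scale <- stats::runif(1, p$scale_range[1L], p$scale_range[2L])
      for (ps_flag in c(FALSE, TRUE)) {
        surv <- if (ps_flag) s_ps else s_no
        for (di in seq_along(p$doses)) {
          a_mean <- scale * p$a0 * surv[di]
          a <- p$blank + a_mean * (1 + p$noise_sd * stats::rnorm(p$n_wells))
          wid <- wid + p$n_wells
          rows[[length(rows) + 1L]] <- data.frame(
            well = sprintf("E%d_%s_D%g_%d", ex,
                           if (ps_flag) "PS" else "noPS", p$doses[di],
                           seq_len(p$n_wells)),
            absorbance = a, dose_Gy = p$doses[di], ps_present = ps_flag,
            ps_uM = if (ps_flag) p$ps_conc * 1e6 else 0,
            experiment_id = paste0("E", ex), is_blank = FALSE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        well = sprintf("E%d_blank_%d", ex, 1:3),
        absorbance = p$blank * (1 + 0.05 * stats::rnorm(3)),
        dose_Gy = 0, ps_present = FALSE, ps_uM = 0,
        experiment_id = paste0("E", ex), is_blank = TRUE)
    }
    do.call(rbind, rows)
  })
  list(readout = plate_readout(df),
       truth = list(pd_coefficient = pd,
                    viability_no_ps = s_no / s_no[p$doses == 0],
                    viability_ps = s_ps / s_ps[p$doses == 0],
                    gains_points = 100 * (s_no[p$doses > 0] -
                                          s_ps[p$doses > 0]),
                    mean_gain_points = 100 * p$target_gain, params = p))
}
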