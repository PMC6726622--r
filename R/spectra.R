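# Emission-spectrum container, CCD despiking, background subtraction,
# Gaussian band decomposition and proton-vs-photon spectral matching.

#' Construct an emission spectrum
#'
#' @param wavelength Strictly increasing wavelength grid, nm.
#' @param intensity Intensities (counts); may go slightly negative after
#'   background handling and is stored as-is.
#' @param channel `"visible"` or `"nir"`.
#' @param metadata Optional list (excitation source, integration settings).
#' @return Object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity, channel = "visible",
                              metadata = list()) {
  if (length(wavelength) != length(intensity))
    stop("`wavelength` and `intensity` must have equal length")
  if (any(diff(wavelength) <= 0))
    stop("`wavelength` must be strictly increasing")
  channel <- match.arg(channel, c("visible", "nir"))
  structure(list(wavelength = wavelength, intensity = intensity,
                 channel = channel, metadata = metadata),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d channels, %.4g-%.4g nm (%s)\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$channel))
  invisible(x)
}

#' Read a spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `intensity` (header optional when
#' exactly two unnamed columns are present).
#'
#' @param path CSV file path.
#' @param channel Channel label passed to [emission_spectrum()].
#' @return An [emission_spectrum()].
#' @export
read_spectrum <- function(path, channel = "visible") {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    if (ncol(df) < 2L) stop("expected two columns (wavelength_nm, intensity)")
    names(df)[1:2] <- c("wavelength_nm", "intensity")
  }
  emission_spectrum(df$wavelength_nm, df$intensity, channel = channel)
}

#' Remove radiation-induced CCD spikes from a spectrum
#'
#' Single-channel spikes from ionising radiation hitting the CCD are detected
#' as deviations from the running median exceeding `z_threshold` robust
#' standard deviations (1.4826 x MAD of the residuals, floored at a small
#' fraction of the maximum intensity so that smooth noiseless bands are left
#' untouched) and replaced with the local median.  The operation is
#' idempotent: a second pass changes nothing.
#'
#' @param spectrum An [emission_spectrum()].
#' @param window Odd running-median window length (channels), >= 3.
#' @param z_threshold Detection threshold in robust SDs.
#' @return The despiked [emission_spectrum()]; the indices of replaced
#'   channels are attached as attribute `"spikes"`.
#' @export
despike <- function(spectrum, window = 7L, z_threshold = 6) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  x <- spectrum$intensity
  if (window > length(x))
    stop("`window` is longer than the spectrum")
  med <- stats::runmed(x, k = window, endrule = "median")
  resid <- x - med
  robust_sd <- 1.4826 * stats::median(abs(resid))
  # floor guards smooth noiseless spectra, where curvature residuals at the
  # band top would otherwise dominate a near-zero MAD
  floor_sd <- 1e-2 * max(abs(x), .Machine$double.eps)
  sdev <- max(robust_sd, floor_sd)
  spikes <- which(abs(resid) > z_threshold * sdev)
  x[spikes] <- med[spikes]
  out <- emission_spectrum(spectrum$wavelength, x, spectrum$channel,
                           spectrum$metadata)
  attr(out, "spikes") <- spikes
  out
}

#' Subtract dark and solvent background from a spectrum
#'
#' Computes `sample - dark - (solvent - dark)` when a solvent spectrum is
#' given (the solvent acquisition contains the dark signal too), otherwise
#' `sample - dark`.
#'
#' @param sample,dark An [emission_spectrum()] on a shared wavelength grid.
#' @param solvent Optional solvent [emission_spectrum()] on the same grid.
#' @return The background-subtracted [emission_spectrum()].
#' @export
subtract_background <- function(sample, dark, solvent = NULL) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(dark, "emission_spectrum"))
  if (!isTRUE(all.equal(sample$wavelength, dark$wavelength)))
    stop("`sample` and `dark` wavelength grids differ")
  intensity <- sample$intensity - dark$intensity
  if (!is.null(solvent)) {
    stopifnot(inherits(solvent, "emission_spectrum"))
    if (!isTRUE(all.equal(sample$wavelength, solvent$wavelength)))
      stop("`solvent` wavelength grid differs from `sample`")
    intensity <- intensity - (solvent$intensity - dark$intensity)
  }
  emission_spectrum(sample$wavelength, intensity, sample$channel,
                    sample$metadata)
}

#' Spectral similarity between two emission spectra
#'
#' Pearson correlation of area-normalised, despiked intensities on the common
#' wavelength grid; 1 for identical shapes, negative for anti-correlated
#' ones.  Used to verify that proton-induced emission matches light-induced
#' fluorescence.
#'
#' @param a,b [emission_spectrum()] objects with >= 50 nm overlap.
#' @param despike_first Despike both spectra before comparing (default TRUE).
#' @return Similarity in `[-1, 1]`.
#' @export
spectral_match <- function(a, b, despike_first = TRUE) {
  stopifnot(inherits(a, "emission_spectrum"),
            inherits(b, "emission_spectrum"))
  lo <- max(min(a$wavelength), min(b$wavelength))
  hi <- min(max(a$wavelength), max(b$wavelength))
  if (hi - lo < 50)
    stop(sprintf("insufficient spectral overlap (%.1f nm < 50 nm)",
                 max(hi - lo, 0)))
  if (despike_first) {
    a <- despike(a)
    b <- despike(b)
  }
  grid <- sort(unique(c(a$wavelength[a$wavelength >= lo & a$wavelength <= hi],
                        b$wavelength[b$wavelength >= lo & b$wavelength <= hi])))
  ia <- stats::approx(a$wavelength, a$intensity, xout = grid)$y
  ib <- stats::approx(b$wavelength, b$intensity, xout = grid)$y
  norm_area <- function(y) {
    area <- sum(diff(grid) * (y[-1L] + y[-length(y)]) / 2)
    if (abs(area) < .Machine$double.eps) stop("zero-area spectrum")
    y / area
  }
  stats::cor(norm_area(ia), norm_area(ib))
}

#' Decompose a spectrum into Gaussian bands
#'
#' Least-squares fit of a sum of `n_bands` Gaussian bands
#' A exp(-(lambda - c)^2 / (2 s^2)), optionally atop a constant baseline
#' (fitted; default on, since CCD spectra carry a dark offset).  Starting
#' values come from the `n_bands` most prominent local maxima of the lightly
#' smoothed spectrum; the fit runs on log-amplitude and log-width for
#' positivity.
#'
#' @param spectrum An [emission_spectrum()].
#' @param n_bands Number of bands, >= 1.
#' @param baseline Fit a constant baseline term (default TRUE).
#' @return List with `bands` (data frame: `centre`, `width` (Gaussian sigma),
#'   `amplitude`, `area`, sorted by centre), `baseline`, `residual_rms`,
#'   `aic` and `fitted`.
#' @export
band_decompose <- function(spectrum, n_bands = 1L, baseline = TRUE) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("`n_bands` must be >= 1")
  wl <- spectrum$wavelength
  y <- spectrum$intensity
  n <- length(wl)
  if (n < 3L * n_bands + 1L)
    stop("spectrum too short for the requested number of bands")

  # initial guesses by sequential residual peaks: place a band at the
  # maximum of the smoothed residual, estimate its width from the local
  # half-maximum extent, subtract, repeat
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  base0 <- if (baseline) stats::quantile(ys, 0.1, names = FALSE) else 0
  span <- diff(range(wl))
  amp_floor <- 1e-6 * max(abs(y), 1)
  smooth7 <- function(v) {
    out <- stats::filter(v, rep(1 / 7, 7), sides = 2)
    out[is.na(out)] <- v[is.na(out)]
    as.numeric(out)
  }
  # seed where the smoothed residual is largest in Poisson-noise units, so a
  # weak band in a quiet region beats noise blips on a strong band
  seed_band <- function(resid) {
    rs <- smooth7(resid)
    snr <- rs / sqrt(pmax(ys, 0) + 1)
    i <- which.max(snr)
    am <- max(rs[i], amp_floor)
    half <- am / 2
    jr <- i; while (jr < n && rs[jr] > half) jr <- jr + 1L
    jl <- i; while (jl > 1L && rs[jl] > half) jl <- jl - 1L
    sig <- max((wl[jr] - wl[jl]) / 2.3548, span / (12 * n_bands))
    c(wl[i], log(sig), log(am))
  }

  # Separable (variable-projection) least squares: band amplitudes and the
  # baseline are linear, so for given centres/widths they are solved exactly
  # by linear least squares and only (centre, log width) pairs are optimised.
  dx <- min(diff(wl))
  design <- function(p, nb) {
    m <- matrix(0, n, nb + as.integer(baseline))
    for (k in seq_len(nb)) {
      s <- exp(p[2L * k])
      m[, k] <- exp(-(wl - p[2L * k - 1L])^2 / (2 * s^2))
    }
    if (baseline) m[, nb + 1L] <- 1
    m
  }
  lin_solve <- function(p, nb) {
    m <- design(p, nb)
    cf <- stats::lm.fit(m, y)$coefficients
    cf[is.na(cf)] <- 0
    cf[seq_len(nb)] <- pmax(cf[seq_len(nb)], 0)  # bands emit, not absorb
    list(coef = cf, sse = sum((y - drop(m %*% cf))^2))
  }
  run_fit <- function(p0, nb) {
    lo <- rep(c(min(wl), log(2 * dx)), nb)
    hi <- rep(c(max(wl), log(span / 2)), nb)
    p0 <- pmin(pmax(p0, lo), hi)
    obj <- function(p) lin_solve(p, nb)$sse
    f <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 1000, factr = 1e2))
    if (nb > 1L || f$convergence != 0) {  # polish in a flat valley
      f2 <- stats::optim(f$par, obj, control = list(maxit = 3000,
                                                    reltol = 1e-14))
      f2$par <- pmin(pmax(f2$par, lo), hi)
      if (f2$value <= f$value) f <- f2
    }
    f
  }
  # two initialisations, best SSE wins:
  # (a) one-shot sequential residual seeding (subtract the seeded band)
  resid <- ys - base0
  p_a <- numeric(0)
  for (k in seq_len(n_bands)) {
    sb <- seed_band(resid)
    p_a <- c(p_a, sb[1:2])
    resid <- resid - exp(sb[3L]) * exp(-(wl - sb[1L])^2 / (2 * exp(sb[2L])^2))
  }
  fit <- run_fit(p_a, n_bands)
  # (b) greedy build-up, refitting the smaller model before each new seed
  if (n_bands > 1L) {
    fit_k <- NULL
    for (k in seq_len(n_bands)) {
      resid <- if (k == 1L) ys - base0 else {
        ls <- lin_solve(fit_k$par, k - 1L)
        y - drop(design(fit_k$par, k - 1L) %*% ls$coef)
      }
      pk <- c(if (k > 1L) fit_k$par, seed_band(resid)[1:2])
      fit_k <- run_fit(pk, k)
    }
    if (fit_k$value < fit$value) fit <- fit_k
  }
  final <- lin_solve(fit$par, n_bands)
  model <- function(p) drop(design(p, n_bands) %*% final$coef)
  sse0 <- sum((y - mean(y))^2)
  if (final$sse > 0.9 * sse0 && sse0 > 0)
    stop("band decomposition did not converge: residual SSE ",
         format(final$sse), " vs total ", format(sse0),
         "; try a different n_bands or inspect the spectrum")
  p <- fit$par
  bands <- data.frame(
    centre = p[seq(1L, by = 2L, length.out = n_bands)],
    width = exp(p[seq(2L, by = 2L, length.out = n_bands)]),
    amplitude = unname(final$coef[seq_len(n_bands)]))
  bands$area <- bands$amplitude * bands$width * sqrt(2 * pi)
  bands <- bands[order(bands$centre), , drop = FALSE]
  rownames(bands) <- NULL
  rss <- final$sse
  n_par <- 3L * n_bands + as.integer(baseline) + 1L
  aic <- n * log(max(rss, .Machine$double.eps) / n) + 2 * n_par
  list(bands = bands,
       baseline = if (baseline) unname(final$coef[n_bands + 1L]) else 0,
       residual_rms = sqrt(rss / n), aic = aic, fitted = model(fit$par))
}
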