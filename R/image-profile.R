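# Beam-fluorescence image processing: grayscale conversion, registration and
# dark-frame subtraction, depth-intensity profiling and peak localisation.

#' Construct a beam image
#'
#' @param pixels Numeric array `[rows, cols, 3]` of RGB values (0-255 for
#'   8-bit data).
#' @param pixel_scale mm per pixel (> 0).
#' @param beam_axis `"column"` when depth runs along columns (the beam
#'   travels left to right), `"row"` when along rows.
#' @param entrance_line Pixel index (along the beam axis) of the cuvette's
#'   inner entrance face.
#' @return Object of class `beam_image`.
#' @export
beam_image <- function(pixels, pixel_scale, beam_axis = c("column", "row"),
                       entrance_line = 1L) {
  beam_axis <- match.arg(beam_axis)
  if (!(is.array(pixels) && length(dim(pixels)) == 3L &&
        dim(pixels)[3L] == 3L))
    stop("`pixels` must be an RGB array [rows, cols, 3]")
  if (pixel_scale <= 0) stop("`pixel_scale` must be > 0 (mm/pixel)")
  extent <- if (beam_axis == "column") dim(pixels)[2L] else dim(pixels)[1L]
  if (entrance_line < 1L || entrance_line > extent)
    stop("`entrance_line` must lie inside the raster")
  structure(list(pixels = pixels, pixel_scale = pixel_scale,
                 beam_axis = beam_axis,
                 entrance_line = as.integer(entrance_line)),
            class = "beam_image")
}

#' @export
print.beam_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<beam_image> %d x %d px, %.4g mm/px, depth along %ss, entrance at %d\n",
    d[1L], d[2L], x$pixel_scale, x$beam_axis, x$entrance_line))
  invisible(x)
}

#' Convert an RGB beam image to grayscale
#'
#' Standard luminance combination 0.299 R + 0.587 G + 0.114 B, discarding hue
#' and saturation while retaining per-pixel intensity.
#'
#' @param image A [beam_image()] (or a bare RGB array).
#' @return Intensity matrix `[rows, cols]`.
#' @export
to_grayscale <- function(image) {
  px <- if (inherits(image, "beam_image")) image$pixels else image
  if (!(is.array(px) && length(dim(px)) == 3L && dim(px)[3L] == 3L))
    stop("input must be an RGB array [rows, cols, 3]")
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}

# Normalised cross-correlation of two equal-size matrices.
.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Register a dark frame to the irradiated frame and subtract it
#'
#' Integer-pixel translation-only registration by exhaustive normalised
#' cross-correlation over shifts up to `max_shift` pixels, followed by
#' subtraction of the aligned dark frame, clipped at zero.
#'
#' @param lit [beam_image()] acquired during irradiation.
#' @param dark [beam_image()] acquired without irradiation (same size).
#' @param max_shift Maximum |shift| searched in each direction, px.
#' @param min_correlation Registration is declared failed (analysis error)
#'   when the best correlation falls below this.
#' @return Intensity matrix (lit minus aligned dark, clipped at 0) with
#'   attributes `shift` (the detected `c(row, col)` displacement of the dark
#'   frame relative to the lit frame) and `correlation`.
#' @export
register_and_subtract <- function(lit, dark, max_shift = 10L,
                                  min_correlation = 0.2) {
  stopifnot(inherits(lit, "beam_image"), inherits(dark, "beam_image"))
  gl <- to_grayscale(lit)
  gd <- to_grayscale(dark)
  if (!all(dim(gl) == dim(gd))) stop("images must have the same dimensions")
  nr <- nrow(gl); nc <- ncol(gl)
  best <- c(cor = -Inf, dr = 0L, dc = 0L)
  for (dr in -max_shift:max_shift) {
    r1 <- max(1L, 1L + dr):min(nr, nr + dr)   # rows in lit
    r2 <- r1 - dr                              # rows in dark
    for (dc in -max_shift:max_shift) {
      c1 <- max(1L, 1L + dc):min(nc, nc + dc)
      c2 <- c1 - dc
      cc <- .ncc(gl[r1, c1], gd[r2, c2])
      if (cc > best["cor"]) best <- c(cor = cc, dr = dr, dc = dc)
    }
  }
  if (best["cor"] < min_correlation)
    stop(sprintf("registration failed: best correlation %.3f < %.3f",
                 best["cor"], min_correlation))
  dr <- best["dr"]; dc <- best["dc"]
  aligned <- matrix(stats::median(gd), nr, nc)
  r1 <- max(1L, 1L + dr):min(nr, nr + dr)
  c1 <- max(1L, 1L + dc):min(nc, nc + dc)
  aligned[r1, c1] <- gd[r1 - dr, c1 - dc]
  out <- pmax(gl - aligned, 0)
  dim(out) <- c(nr, nc)
  attr(out, "shift") <- unname(c(-dr, -dc))
  attr(out, "correlation") <- unname(best["cor"])
  out
}

#' Depth-intensity profile of a subtracted beam image
#'
#' Averages the intensity across the lateral extent of the beam (the pixels
#' within the lateral FWHM band around the lateral maximum) at each depth
#' pixel beyond the entrance line, converting pixel index to depth in mm.
#'
#' @param raster Intensity matrix (e.g. from [register_and_subtract()]).
#' @param pixel_scale mm per pixel.
#' @param beam_axis `"column"` or `"row"` (see [beam_image()]).
#' @param entrance_line Pixel index of the entrance face along the beam axis.
#' @param lateral_band Optional integer vector of lateral pixel indices to
#'   average over; default: the FWHM band of the summed lateral profile.
#' @return A [fluorescence_profile()] (depth measured from the entrance
#'   line).
#' @export
depth_profile <- function(raster, pixel_scale, beam_axis = c("column", "row"),
                          entrance_line = 1L, lateral_band = NULL) {
  beam_axis <- match.arg(beam_axis)
  if (beam_axis == "row") raster <- t(raster)
  nc <- ncol(raster)
  if (entrance_line < 1L || entrance_line >= nc)
    stop("`entrance_line` must lie inside the raster")
  if (is.null(lateral_band)) {
    lat <- rowSums(raster[, entrance_line:nc, drop = FALSE])
    if (max(lat) <= 0) stop("empty lateral band: no signal to average")
    half <- max(lat) / 2
    lateral_band <- which(lat >= half)
  }
  if (!length(lateral_band)) stop("empty lateral band")
  depth_cols <- entrance_line:nc
  intensity <- colMeans(raster[lateral_band, depth_cols, drop = FALSE])
  depth_mm <- (depth_cols - entrance_line) * pixel_scale
  fluorescence_profile(depth_mm, intensity)
}

#' Locate the fluorescence maximum of a depth profile
#'
#' Depth of maximum intensity with sub-pixel precision from the 3-point
#' parabolic interpolation shared with [bragg_peak_depth()].
#'
#' @param profile A [fluorescence_profile()].
#' @return Depth of the fluorescence maximum, mm.
#' @export
locate_fluorescence_max <- function(profile) {
  stopifnot(inherits(profile, "fluorescence_profile"))
  .parabolic_peak(profile$depth_mm, profile$intensity)
}

#' Write / read an RGB image as plain-text PPM (P3)
#'
#' Offline-friendly plain-text image format used by the synthetic-image
#' round trips (no binary PNG/TIFF codecs are required).
#'
#' @param pixels RGB array `[rows, cols, 3]` with 8-bit values.
#' @param path File path.
#' @return `read_ppm` returns the RGB array.
#' @export
write_ppm <- function(pixels, path) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)
  vals <- as.integer(round(aperm(pixels, c(3L, 2L, 1L))))  # RGB per pixel,
  con <- file(path, "w")                                   # row-major
  on.exit(close(con))
  writeLines(c("P3", paste(d[2L], d[1L]), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = "", quiet = TRUE, comment.char = "#")
  if (toks[1L] != "P3") stop("only ASCII PPM (P3) is supported")
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3L * w * h) stop("corrupt PPM payload")
  aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
}
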