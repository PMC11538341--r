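#' sCMOS camera model
#'
#' Per-pixel calibration of a scientific CMOS sensor: gain (gray level per
#' electron), read noise (electrons rms), offset (gray-level baseline) and
#' thermal (dark-current) rate (electrons per second).  Because per-pixel
#' gain estimates are noisy, the scalar median gain is used for all
#' gray-level/photon conversions, matching common sCMOS practice.
#'
#' @param gain per-pixel gain map (gray level / e-), or a scalar
#' @param read_noise per-pixel read noise (e- rms), or a scalar
#' @param offset per-pixel baseline (gray level), or a scalar
#' @param thermal per-pixel dark-current rate (e-/s), or a scalar
#' @param shape image dimensions c(rows, cols); required when all
#'   parameters are scalars
#' @param bit_depth maximum gray value (12-bit sensor: 4095)
#' @return a `camera_model` object
#' @export
camera_model <- function(gain = 2.58, read_noise = 1.6, offset = 100,
                         thermal = 0.2, shape = NULL, bit_depth = 4095) {
  if (is.null(shape)) {
    for (x in list(gain, read_noise, offset, thermal))
      if (is.matrix(x)) { shape <- dim(x); break }
    if (is.null(shape)) stop("shape required when parameters are scalars")
  }
  as_map <- function(x) {
    if (is.matrix(x)) return(x)
    matrix(x, shape[1], shape[2])
  }
  gain <- as_map(gain); read_noise <- as_map(read_noise)
  offset <- as_map(offset); thermal <- as_map(thermal)
  if (any(gain <= 0)) stop("gain must be positive everywhere")
  if (any(read_noise < 0) || any(offset < 0)) stop("negative noise/offset")
  structure(list(gain = gain, read_noise = read_noise, offset = offset,
                 thermal = thermal, median_gain = median(gain),
                 bit_depth = bit_depth),
            class = "camera_model")
}

#' Calibrate an sCMOS camera from dark (and optionally flat) frames
#'
#' Offset and thermal rate come from a per-pixel linear fit of the dark
#' mean versus exposure time; read noise from the dark variance at the
#' shortest exposure; gain from the photon-transfer (variance vs mean)
#' slope of graded flat-field series when provided, otherwise from
#' `gain_fallback`.
#'
#' @param dark_series named list: one element per exposure time, each a 3D
#'   array (rows x cols x frames) of gray levels; names are exposure times
#'   in seconds
#' @param flat_series optional list of 3D arrays at graded illumination
#'   (same exposure), used for photon-transfer gain estimation
#' @param gain_fallback scalar gain used when `flat_series` is absent
#' @param bit_depth sensor maximum gray value
#' @return a [camera_model()]
#' @export
calibrate_camera <- function(dark_series, flat_series = NULL,
                             gain_fallback = 2.58, bit_depth = 4095) {
  exposures <- as.numeric(names(dark_series))
  if (length(exposures) < 2)
    stop("thermal rate unidentifiable: need >= 2 exposure times")
  if (any(is.na(exposures))) stop("dark_series must be named by exposure (s)")
  nf <- vapply(dark_series, function(a) dim(a)[3], numeric(1))
  if (any(nf < 20)) stop("need >= 20 frames per exposure")
  means <- lapply(dark_series, function(a) apply(a, c(1, 2), mean))
  shp <- dim(means[[1]])
  # gain first: needed to convert thermal slope (gray/s) to e-/s
  if (!is.null(flat_series)) {
    mu <- vapply(flat_series, function(a) mean(a), numeric(1))
    vv <- vapply(flat_series, function(a) mean(apply(a, c(1, 2), var)),
                 numeric(1))
    sat <- mu > 0.9 * bit_depth
    if (any(sat)) warning(sprintf("%d saturated flat levels masked", sum(sat)))
    fit <- lm(vv[!sat] ~ mu[!sat])
    gain_scalar <- unname(coef(fit)[2])
  } else gain_scalar <- gain_fallback
  # per-pixel linear fit mean ~ exposure (closed form)
  ex <- exposures - mean(exposures)
  sxx <- sum(ex^2)
  slope <- Reduce(`+`, Map(function(m, e) m * e, means, ex)) / sxx
  mbar <- Reduce(`+`, means) / length(means)
  offset <- mbar - slope * mean(exposures)
  offset[offset < 0] <- 0
  thermal <- slope / gain_scalar  # e-/s
  thermal[thermal < 0] <- 0
  i0 <- which.min(exposures)
  v0 <- apply(dark_series[[i0]], c(1, 2), var)
  # dark variance at the shortest exposure ~ read noise (e-) plus the small
  # shot noise of the thermal electrons accumulated in that exposure
  rn2 <- v0 / gain_scalar^2 - thermal * exposures[i0]
  read_noise <- sqrt(pmax(rn2, 0))
  camera_model(gain = matrix(gain_scalar, shp[1], shp[2]),
               read_noise = read_noise, offset = offset, thermal = thermal,
               bit_depth = bit_depth)
}

#' Apply the sCMOS forward model to a photon image
#'
#' Per pixel: Poisson(photons + thermal * exposure) electrons, plus
#' Gaussian read noise (e-), times gain, plus offset, rounded to the
#' nearest integer and clipped to the sensor range.
#'
#' @param photons image of expected photons (electrons) per pixel
#' @param model a [camera_model()]; maps must match the image shape
#' @param exposure exposure time (s) for dark-current accumulation
#' @param seed optional RNG seed for reproducibility
#' @return gray-level image (integer-valued numeric matrix)
#' @export
apply_camera <- function(photons, model, exposure = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(photons >= 0), exposure > 0)
  lam <- photons + model$thermal * exposure
  e <- matrix(rpois(length(lam), lam), nrow(lam)) +
    matrix(rnorm(length(lam), 0, model$read_noise), nrow(lam))
  g <- round(e * model$gain + model$offset)
  pmin(pmax(g, 0), model$bit_depth)
}

#' Convert gray levels to photons
#'
#' Uses the scalar median gain (not the per-pixel map): subtracts the
#' per-pixel offset, divides by the median gain, and clips at zero.
#'
#' @param gray gray-level image
#' @param model a [camera_model()]
#' @return photon image
#' @export
to_photons <- function(gray, model) {
  pmax((gray - model$offset) / model$median_gain, 0)
}
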