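#' Camera model
#'
#' Describes the detector geometry and noise used throughout the pipeline.
#' Quantum efficiency and gain are treated as unity, so all pixel values are
#' photon counts.
#'
#' @param pixel_size_nm Physical pixel size in nm (160 nm for the reference
#'   optical configuration: NA 1.4, 20x magnification).
#' @param read_noise_e RMS Gaussian read noise, electrons (= photons at unit
#'   gain).
#' @param background_photons_per_px Mean background photons per pixel per
#'   frame.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 160, read_noise_e = 1,
                         background_photons_per_px = 10) {
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number")
  }
  if (read_noise_e < 0 || background_photons_per_px < 0) {
    stop("noise parameters must be >= 0")
  }
  structure(list(pixel_size_nm = pixel_size_nm,
                 read_noise_e = read_noise_e,
                 background_photons_per_px = background_photons_per_px),
            class = "camera_model")
}

#' Gaussian point-spread-function model
#'
#' A 2D Gaussian PSF, I(x, y) = I0 exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2)),
#' optionally anisotropic with separate x/y widths. The default width
#' sigma = 102 nm gives FWHM ~ 240 nm, the Abbe diffraction limit for AF647
#' emission at NA 1.4 (see [abbe_limit_nm()]).
#'
#' @param sigma_nm Isotropic standard deviation in nm.
#' @param sigma_x_nm,sigma_y_nm Optional anisotropic widths; default
#'   `sigma_nm`.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(sigma_nm = 102, sigma_x_nm = sigma_nm,
                      sigma_y_nm = sigma_nm) {
  if (any(c(sigma_nm, sigma_x_nm, sigma_y_nm) <= 0)) {
    stop("PSF widths must be > 0")
  }
  structure(list(sigma_nm = sigma_nm, sigma_x_nm = sigma_x_nm,
                 sigma_y_nm = sigma_y_nm),
            class = "psf_model")
}

#' Photon-count distribution of single-emitter events
#'
#' The per-event photon yield of a blinking fluorophore. The default is a
#' broad truncated lognormal (median 5000 photons, geometric SD 1.8,
#' truncated to [500, 50000]) emulating the wide experimental photon spread
#' of AF647 under STORM buffers.
#'
#' @param family Distribution family; `"lognormal"` or `"constant"`.
#' @param median Median photon count.
#' @param geom_sd Geometric standard deviation (> 1) for the lognormal family.
#' @param lower,upper Truncation bounds (photons).
#' @return An object of class `photon_distribution`.
#' @export
photon_distribution <- function(family = c("lognormal", "constant"),
                                median = 5000, geom_sd = 1.8,
                                lower = 500, upper = 50000) {
  family <- match.arg(family)
  if (median <= 0 || lower < 0 || upper <= lower) {
    stop("invalid photon distribution parameters")
  }
  if (family == "lognormal" && geom_sd <= 1) {
    stop("`geom_sd` must be > 1")
  }
  structure(list(family = family, median = median, geom_sd = geom_sd,
                 lower = lower, upper = upper),
            class = "photon_distribution")
}

#' Draw photon counts
#'
#' Samples per-event photon counts from a [photon_distribution()] using the
#' current R random number generator state (seed with [set.seed()]).
#'
#' @param n Number of draws.
#' @param dist A [photon_distribution()].
#' @return Numeric vector of strictly positive photon counts.
#' @export
sample_photons <- function(n, dist) {
  stopifnot(inherits(dist, "photon_distribution"), n >= 0)
  if (n == 0) return(numeric(0))
  if (dist$family == "constant") {
    return(rep(dist$median, n))
  }
  meanlog <- log(dist$median)
  sdlog <- log(dist$geom_sd)
  out <- numeric(0)
  # rejection against the truncation bounds; acceptance is ~1 for defaults
  while (length(out) < n) {
    draw <- rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    draw <- draw[draw >= dist$lower & draw <= dist$upper]
    out <- c(out, draw)
  }
  out[seq_len(n)]
}

#' Abbe diffraction limit
#'
#' d = lambda / (2 NA), the minimal resolvable separation of a conventional
#' microscope. For AF647 emission (~670 nm) at NA 1.4 this is ~240 nm, the
#' disk diameter used when deriving multi-emitter spots.
#'
#' @param wavelength_nm Emission wavelength in nm.
#' @param na Numerical aperture.
#' @return Diffraction limit in nm.
#' @export
abbe_limit_nm <- function(wavelength_nm = 670, na = 1.4) {
  stopifnot(wavelength_nm > 0, na > 0)
  wavelength_nm / (2 * na)
}
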