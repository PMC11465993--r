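#' Spot image container
#'
#' A small photon-count raster crop together with the global-frame position of
#' its top-left corner. The global frame has its origin at the top-left corner
#' of pixel (0, 0), x increasing rightward (columns), y downward (rows); pixel
#' (row i, col j) covers the half-open square
#' \[j px, (j+1) px) x \[i px, (i+1) px) nm.
#'
#' @param data Numeric matrix of photon counts (rows = y, cols = x).
#' @param offset_nm Length-2 numeric `c(x, y)`: global nm position of the
#'   crop's top-left corner.
#' @param pixel_size_nm Pixel pitch in nm.
#' @return An object of class `spot_image`.
#' @export
spot_image <- function(data, offset_nm = c(0, 0), pixel_size_nm = 160) {
  stopifnot(is.matrix(data), length(offset_nm) == 2, pixel_size_nm > 0)
  structure(list(data = data, offset_nm = as.numeric(offset_nm),
                 pixel_size_nm = pixel_size_nm),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  cat(sprintf("<spot_image %dx%d px (%.0f nm/px), offset (%.1f, %.1f) nm, sum %.1f>\n",
              nrow(x$data), ncol(x$data), x$pixel_size_nm,
              x$offset_nm[1], x$offset_nm[2], sum(x$data)))
  invisible(x)
}

as_spot_image <- function(x, pixel_size_nm = 160) {
  if (inherits(x, "spot_image")) x else spot_image(x, pixel_size_nm = pixel_size_nm)
}

#' Render a pixel-integrated Gaussian PSF
#'
#' Computes the expected photon count in each pixel of a crop for a point
#' emitter imaged through a 2D Gaussian PSF. The Gaussian is integrated
#' analytically over each pixel's area (error-function differences), not
#' sampled at pixel centers, so photon flux is conserved exactly up to crop
#' truncation. The output is noiseless; apply [add_camera_noise()] separately.
#'
#' @param emitter_xy_nm Length-2 `c(x, y)` emitter position in global nm.
#' @param photons Expected total photon count of the event (>= 0).
#' @param psf A [psf_model()].
#' @param camera A [camera_model()].
#' @param shape_px Length-2 `c(rows, cols)` crop size in pixels.
#' @param offset_nm Global nm position of the crop's top-left corner.
#' @return A [spot_image()] of expected photon counts.
#' @export
render_psf <- function(emitter_xy_nm, photons, psf = psf_model(),
                       camera = camera_model(), shape_px = c(7, 7),
                       offset_nm = c(0, 0)) {
  stopifnot(inherits(psf, "psf_model"), inherits(camera, "camera_model"))
  if (photons < 0) stop("`photons` must be >= 0")
  px <- camera$pixel_size_nm
  x0 <- emitter_xy_nm[1] - offset_nm[1]
  y0 <- emitter_xy_nm[2] - offset_nm[2]
  nr <- shape_px[1]; nc <- shape_px[2]
  # per-axis Gaussian mass within each pixel's interval
  xe <- px * (0:nc); ye <- px * (0:nr)
  mx <- diff(pnorm(xe, mean = x0, sd = psf$sigma_x_nm))
  my <- diff(pnorm(ye, mean = y0, sd = psf$sigma_y_nm))
  img <- photons * outer(my, mx)
  spot_image(img, offset_nm = offset_nm, pixel_size_nm = px)
}

#' Add camera noise to an expected-photon image
#'
#' Per-pixel Poisson shot noise on signal plus background, followed by
#' additive Gaussian read noise. Deterministic given the R random seed.
#'
#' @param image A [spot_image()] (or matrix) of expected photon counts.
#' @param camera A [camera_model()].
#' @return A [spot_image()] with the same shape and offset.
#' @export
add_camera_noise <- function(image, camera = camera_model()) {
  img <- as_spot_image(image, camera$pixel_size_nm)
  if (any(img$data < 0)) stop("expected image must be non-negative")
  if (camera$background_photons_per_px < 0) stop("negative background")
  lam <- img$data + camera$background_photons_per_px
  noisy <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
  if (camera$read_noise_e > 0) {
    noisy <- noisy + matrix(rnorm(length(lam), sd = camera$read_noise_e),
                            nrow(lam), ncol(lam))
  }
  spot_image(noisy, offset_nm = img$offset_nm, pixel_size_nm = img$pixel_size_nm)
}

#' Blinking kinetics of a photoswitchable fluorophore
#'
#' Two-state (on/off) Markov kinetics per camera frame: an off molecule turns
#' on with probability `p_on` per frame; an on molecule stays on for a
#' geometric dwell with mean `mean_on_frames` frames.
#'
#' @param p_on Per-frame off-to-on switching probability.
#' @param mean_on_frames Mean on-state dwell time, frames (>= 1).
#' @return An object of class `blink_kinetics`.
#' @export
blink_kinetics <- function(p_on = 1e-3, mean_on_frames = 2) {
  if (p_on < 0 || p_on > 1) stop("`p_on` must be in [0, 1]")
  if (mean_on_frames < 1) stop("`mean_on_frames` must be >= 1")
  structure(list(p_on = p_on, p_off = 1 / mean_on_frames,
                 mean_on_frames = mean_on_frames),
            class = "blink_kinetics")
}

#' Stationary on-fraction of a blink trace
#'
#' Closed-form stationary probability p_on / (p_on + p_off) of the two-state
#' chain, i.e. the long-run fraction of frames a molecule spends emitting.
#'
#' @param kinetics A [blink_kinetics()].
#' @return Stationary on-state probability.
#' @export
blink_on_fraction <- function(kinetics) {
  kinetics$p_on / (kinetics$p_on + kinetics$p_off)
}

#' Simulate a blinking trace
#'
#' Draws an on/off two-state Markov trajectory over `n_frames` frames and, for
#' each on frame, a photon count from `photon_dist`. Off frames yield zero.
#' The chain starts from its stationary distribution.
#'
#' @param n_frames Number of camera frames (>= 1).
#' @param kinetics A [blink_kinetics()].
#' @param photon_dist A [photon_distribution()].
#' @return Numeric vector of per-frame photon counts (class `blink_trace`).
#' @export
sample_blink_trace <- function(n_frames, kinetics = blink_kinetics(),
                               photon_dist = photon_distribution()) {
  stopifnot(n_frames >= 1)
  on <- logical(n_frames)
  state <- runif(1) < blink_on_fraction(kinetics)
  for (t in seq_len(n_frames)) {
    on[t] <- state
    state <- if (state) runif(1) >= kinetics$p_off else runif(1) < kinetics$p_on
  }
  trace <- numeric(n_frames)
  n_on <- sum(on)
  if (n_on > 0) trace[on] <- sample_photons(n_on, photon_dist)
  structure(trace, class = "blink_trace", on = on)
}

#' Build a synthetic single-emitter spot library
#'
#' Generates `n_molecules` noisy 7x7 single-emitter spots with known
#' ground-truth sub-pixel positions and photon counts, then Gaussian-fits each
#' spot (see [fit_gaussian_2d()]) so the fitted coordinates can serve as
#' anchor points when deriving multi-emitter spots. Emitters are placed
#' uniformly within the central pixel of the crop, mimicking detection-centered
#' experimental crops.
#'
#' @param n_molecules Number of library molecules (>= 1).
#' @param psf A [psf_model()].
#' @param camera A [camera_model()].
#' @param photon_dist A [photon_distribution()].
#' @param shape_px Crop size (default 7x7).
#' @param fit Run the 2D Gaussian fit on each record (default TRUE).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `spot_library`: a list with `records` (each a
#'   list with `molecule_id`, `image`, `true_xy_nm`, `photons_true`,
#'   `photons`, `fit`), plus the generator models and seed.
#' @export
build_synthetic_library <- function(n_molecules, psf = psf_model(),
                                    camera = camera_model(),
                                    photon_dist = photon_distribution(),
                                    shape_px = c(7, 7), fit = TRUE,
                                    seed = NULL) {
  stopifnot(n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  px <- camera$pixel_size_nm
  ctr <- floor(shape_px / 2) # central pixel index (0-based): 3 for 7x7
  photons <- sample_photons(n_molecules, photon_dist)
  xs <- (ctr[2] + runif(n_molecules)) * px
  ys <- (ctr[1] + runif(n_molecules)) * px
  records <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    clean <- render_psf(c(xs[i], ys[i]), photons[i], psf, camera, shape_px)
    noisy <- add_camera_noise(clean, camera)
    rec <- list(molecule_id = i, image = noisy,
                true_xy_nm = c(xs[i], ys[i]),
                photons_true = photons[i],
                photons = spot_photons(noisy), fit = NULL)
    if (fit) rec$fit <- fit_gaussian_2d(noisy)
    records[[i]] <- rec
  }
  structure(list(records = records, camera = camera, psf = psf,
                 photon_dist = photon_dist, seed = seed),
            class = "spot_library")
}

#' @export
print.spot_library <- function(x, ...) {
  cat(sprintf("<spot_library of %d single-emitter spots (%.0f nm/px)>\n",
              length(x$records), x$camera$pixel_size_nm))
  invisible(x)
}

#' Write / read a spot library
#'
#' Serializes a library as a directory holding `library.csv` (molecule id,
#' ground-truth and fitted coordinates in nm, photon counts, fitted widths)
#' plus a multi-page TIFF of the crops and a YAML config snapshot.
#'
#' @param library A [build_synthetic_library()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spot_library <- function(library, dir) {
  stopifnot(inherits(library, "spot_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- library$records
  tab <- data.frame(
    molecule_id = vapply(recs, function(r) r$molecule_id, numeric(1)),
    x_nm = vapply(recs, function(r) r$true_xy_nm[1], numeric(1)),
    y_nm = vapply(recs, function(r) r$true_xy_nm[2], numeric(1)),
    photons = vapply(recs, function(r) r$photons, numeric(1)),
    fit_x_nm = vapply(recs, function(r) r$fit$x0_nm %||% NA_real_, numeric(1)),
    fit_y_nm = vapply(recs, function(r) r$fit$y0_nm %||% NA_real_, numeric(1)),
    sigma_x_nm = vapply(recs, function(r) r$fit$sigma_x_nm %||% NA_real_, numeric(1)),
    sigma_y_nm = vapply(recs, function(r) r$fit$sigma_y_nm %||% NA_real_, numeric(1)),
    fit_photons = vapply(recs, function(r) r$fit$photons %||% NA_real_, numeric(1)),
    fit_background = vapply(recs, function(r) r$fit$background %||% NA_real_, numeric(1))
  )
  write.csv(tab, file.path(dir, "library.csv"), row.names = FALSE)
  write_stack(lapply(recs, function(r) r$image$data), file.path(dir, "spots.tiff"))
  yaml::write_yaml(list(pixel_size_nm = library$camera$pixel_size_nm,
                        sigma_nm = library$psf$sigma_nm,
                        photon_median = library$photon_dist$median,
                        seed = library$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_spot_library
#' @param dir Library directory written by [write_spot_library()].
#' @export
read_spot_library <- function(dir) {
  tab <- read.csv(file.path(dir, "library.csv"))
  crops <- read_stack(file.path(dir, "spots.tiff"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  camera <- camera_model(pixel_size_nm = cfg$pixel_size_nm)
  records <- lapply(seq_len(nrow(tab)), function(i) {
    fit <- if (!is.na(tab$fit_x_nm[i])) {
      structure(list(photons = tab$fit_photons[i],
                     x0_nm = tab$fit_x_nm[i], y0_nm = tab$fit_y_nm[i],
                     sigma_x_nm = tab$sigma_x_nm[i],
                     sigma_y_nm = tab$sigma_y_nm[i],
                     peak = tab$fit_photons[i] /
                       (2 * pi * tab$sigma_x_nm[i] * tab$sigma_y_nm[i]),
                     background = tab$fit_background[i],
                     rss = NA_real_, converged = TRUE, niter = NA_integer_),
                class = "gaussian_fit")
    } else NULL
    list(molecule_id = tab$molecule_id[i],
         image = spot_image(crops[[i]], pixel_size_nm = cfg$pixel_size_nm),
         true_xy_nm = c(tab$x_nm[i], tab$y_nm[i]),
         photons_true = NA_real_, photons = tab$photons[i], fit = fit)
  })
  structure(list(records = records, camera = camera,
                 psf = psf_model(sigma_nm = cfg$sigma_nm %||% 102),
                 photon_dist = photon_distribution(
                   median = cfg$photon_median %||% 5000),
                 seed = cfg$seed),
            class = "spot_library")
}
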