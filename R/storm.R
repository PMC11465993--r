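# STORM-imaging simulation of dense sub-diffraction ultrastructures:
# non-uniform molecule layouts, blinking image sequences with exact
# ground-truth bookkeeping, and super-resolution reconstruction comparison.

#' Ultrastructure specification
#'
#' A sub-diffraction-sized structure: a disk of the given diameter holding
#' `n_molecules` fluorophores with a radially decreasing density (denser
#' center than periphery), modeled as a radial Gaussian with
#' `density_sigma_nm` (default diameter/4) truncated to the disk.
#'
#' @param n_molecules Number of molecules (>= 1); the reference densities are
#'   50, 150, 250, 350, 450, 550.
#' @param diameter_nm Structure diameter in nm (240 = diffraction limit).
#' @param density_sigma_nm Radial Gaussian width of the density profile.
#' @return An object of class `ultrastructure_spec`.
#' @export
ultrastructure_spec <- function(n_molecules, diameter_nm = 240,
                                density_sigma_nm = diameter_nm / 4) {
  stopifnot(n_molecules >= 1, diameter_nm > 0, density_sigma_nm > 0)
  structure(list(n_molecules = n_molecules, diameter_nm = diameter_nm,
                 density_sigma_nm = density_sigma_nm),
            class = "ultrastructure_spec")
}

#' Lay out molecules within an ultrastructure
#'
#' Rejection-samples molecule positions from the radial Gaussian density
#' truncated to the structure disk, giving a monotone non-increasing radial
#' density (center denser than periphery).
#'
#' @param spec An [ultrastructure_spec()].
#' @return n x 2 matrix of `c(x, y)` nm coordinates relative to the
#'   structure center.
#' @export
layout_ultrastructure <- function(spec) {
  stopifnot(inherits(spec, "ultrastructure_spec"))
  r <- spec$diameter_nm / 2
  out <- matrix(NA_real_, spec$n_molecules, 2)
  got <- 0
  while (got < spec$n_molecules) {
    m <- 2 * (spec$n_molecules - got)
    x <- rnorm(m, 0, spec$density_sigma_nm)
    y <- rnorm(m, 0, spec$density_sigma_nm)
    ok <- which(x^2 + y^2 <= r^2)
    take <- head(ok, spec$n_molecules - got)
    if (length(take)) {
      out[(got + 1):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Simulate a STORM image sequence of an ultrastructure
#'
#' Each molecule gets an independent two-state blinking trace; in every frame
#' the active molecules are rendered at their layout positions through the
#' pixel-integrated Gaussian PSF, camera noise is added, and the ground truth
#' records every emission event. Per frame, co-active molecules are grouped
#' into apparent spots by single-linkage clustering at the diffraction limit
#' (240 nm), so every spot decomposes exactly into its contributing
#' molecules.
#'
#' @param layout n x 2 molecule coordinates (nm, structure frame) from
#'   [layout_ultrastructure()].
#' @param n_frames Number of frames (>= 1).
#' @param camera A [camera_model()].
#' @param psf A [psf_model()].
#' @param photon_dist A [photon_distribution()].
#' @param kinetics A [blink_kinetics()].
#' @param frame_px Frame size in pixels (structure placed at the center).
#' @param cluster_nm Single-linkage cut distance for spot grouping.
#' @param seed Optional integer seed.
#' @return An object of class `simulated_sequence`: `frames` (list of
#'   matrices), `truth` (data.frame: frame, molecule, x/y nm in the frame's
#'   global coordinates, photons, spot id within frame, spot multiplicity),
#'   `layout_nm` (global frame), and the models used.
#' @export
simulate_sequence <- function(layout, n_frames, camera = camera_model(),
                              psf = psf_model(),
                              photon_dist = photon_distribution(),
                              kinetics = blink_kinetics(),
                              frame_px = c(28, 28), cluster_nm = 240,
                              seed = NULL) {
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  layout <- rbind(layout)
  n_mol <- nrow(layout)
  center <- c(frame_px[2], frame_px[1]) / 2 * camera$pixel_size_nm
  pos <- sweep(layout, 2, center, "+")
  traces <- matrix(0, n_mol, n_frames)
  for (m in seq_len(n_mol)) {
    traces[m, ] <- as.numeric(sample_blink_trace(n_frames, kinetics,
                                                 photon_dist))
  }
  frames <- vector("list", n_frames)
  truth_rows <- list()
  for (f in seq_len(n_frames)) {
    active <- which(traces[, f] > 0)
    expected <- matrix(0, frame_px[1], frame_px[2])
    for (m in active) {
      expected <- expected + render_psf(pos[m, ], traces[m, f], psf, camera,
                                        frame_px)$data
    }
    frames[[f]] <- add_camera_noise(
      spot_image(expected, pixel_size_nm = camera$pixel_size_nm),
      camera)$data
    if (length(active)) {
      spot_id <- if (length(active) == 1) 1L else {
        stats::cutree(stats::hclust(stats::dist(pos[active, , drop = FALSE]),
                                    method = "single"), h = cluster_nm)
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        frame = f, molecule = active,
        x_nm = pos[active, 1], y_nm = pos[active, 2],
        photons = traces[active, f], spot = as.integer(spot_id),
        multiplicity = as.integer(table(spot_id)[as.character(spot_id)]))
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(frame = integer(0), molecule = integer(0), x_nm = numeric(0),
               y_nm = numeric(0), photons = numeric(0), spot = integer(0),
               multiplicity = integer(0))
  rownames(truth) <- NULL
  structure(list(frames = frames, truth = truth, layout_nm = pos,
                 camera = camera, psf = psf, kinetics = kinetics,
                 seed = seed),
            class = "simulated_sequence")
}

#' Reconstruct a super-resolution image from localizations
#'
#' Renders unit spikes at every localization on an upsampled canvas and
#' convolves them with a Gaussian kernel, producing the density-colored
#' super-resolution image used for method comparison.
#'
#' @param table Data.frame with `x [nm]`/`y [nm]` (or `x_nm`/`y_nm`) columns.
#' @param canvas_px Low-resolution canvas size, pixels.
#' @param upsampling High-resolution factor.
#' @param kernel_sigma_px Gaussian kernel sigma in high-resolution pixels.
#' @param pixel_size_nm Low-resolution pixel pitch.
#' @return Numeric matrix (the reconstruction).
#' @export
reconstruct_superres <- function(table, canvas_px = c(28, 28),
                                 upsampling = 8, kernel_sigma_px = 1,
                                 pixel_size_nm = 160) {
  xy <- localization_xy(table)
  if (nrow(xy) == 0) {
    return(matrix(0, canvas_px[1] * upsampling, canvas_px[2] * upsampling))
  }
  spikes <- render_spikes(xy, canvas_px, upsampling, pixel_size_nm)
  heatmap_from_spikes(spikes, kernel_sigma_px)
}

localization_xy <- function(table) {
  xc <- intersect(c("x [nm]", "x_nm", "x"), names(table))[1]
  yc <- intersect(c("y [nm]", "y_nm", "y"), names(table))[1]
  if (is.na(xc) || is.na(yc)) stop("no x/y nm columns found")
  cbind(x = table[[xc]], y = table[[yc]])
}

# Single-Gaussian-fit baseline: every detected spot is treated as one
# molecule, however many emitters produced it.
gaussian_fit_localizations <- function(frames, camera = camera_model(),
                                       detect_args = list()) {
  rows <- list()
  for (f in seq_along(frames)) {
    centers <- do.call(detect_spot_centers, c(list(frames[[f]]), detect_args))
    for (i in seq_len(nrow(centers))) {
      fit <- tryCatch(
        suppressWarnings(
          fit_gaussian_2d(crop_spot(frames[[f]],
                                    c(centers$row[i], centers$col[i]),
                                    3, camera$pixel_size_nm))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rows[[length(rows) + 1]] <- data.frame(frame = f, x_nm = fit$x0_nm,
                                               y_nm = fit$y0_nm,
                                               photons = fit$photons)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               photons = numeric(0))
}

#' SSIM of reconstructions versus ground truth across densities
#'
#' For each molecule density, simulates STORM imaging of one ultrastructure,
#' reconstructs super-resolution images from (i) ground-truth emission
#' events, (ii) the two-stage model's predictions, and (iii) the
#' single-molecule Gaussian-fit baseline (which treats every spot as one
#' molecule), and reports SSIM of (ii) and (iii) against (i).
#'
#' @param n_molecules Vector of densities (molecules per structure).
#' @param bundle A trained [model_bundle()].
#' @param n_frames Frames per simulated sequence.
#' @param camera,psf,photon_dist,kinetics Imaging models.
#' @param frame_px Frame size.
#' @param upsampling,kernel_sigma_px Reconstruction parameters.
#' @param seed Optional integer seed.
#' @param detect_args Extra detection arguments.
#' @return Data.frame with `n_molecules`, `ssim_prediction`, `ssim_gaussfit`
#'   and event counts.
#' @export
ssim_vs_density <- function(n_molecules = c(50, 150, 250, 350, 450, 550),
                            bundle, n_frames = 2000,
                            camera = camera_model(), psf = psf_model(),
                            photon_dist = photon_distribution(),
                            kinetics = blink_kinetics(),
                            frame_px = c(28, 28), upsampling = 8,
                            kernel_sigma_px = 1, seed = NULL,
                            detect_args = list()) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(n_molecules, function(nm) {
    layout <- layout_ultrastructure(ultrastructure_spec(nm))
    sim <- simulate_sequence(layout, n_frames, camera, psf, photon_dist,
                             kinetics, frame_px)
    gt_img <- reconstruct_superres(sim$truth, frame_px, upsampling,
                                   kernel_sigma_px, camera$pixel_size_nm)
    pred <- process_stack(sim$frames, bundle, camera, detect_args)
    pred_img <- reconstruct_superres(pred, frame_px, upsampling,
                                     kernel_sigma_px, camera$pixel_size_nm)
    fitloc <- gaussian_fit_localizations(sim$frames, camera, detect_args)
    fit_img <- reconstruct_superres(fitloc, frame_px, upsampling,
                                    kernel_sigma_px, camera$pixel_size_nm)
    data.frame(n_molecules = nm,
               ssim_prediction = ssim(gt_img, pred_img),
               ssim_gaussfit = ssim(gt_img, fit_img),
               n_events = nrow(sim$truth),
               n_predicted = nrow(pred), n_gaussfit = nrow(fitloc))
  })
  do.call(rbind, out)
}
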