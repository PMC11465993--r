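# Derivation of labeled multi-emitter spots: coordinate sampling inside the
# diffraction-limited disk, sub-pixel superposition of library spots anchored
# at their fitted emitter positions, and assembly of training/testing sets.

#' Sample emitter coordinates inside the diffraction-limited disk
#'
#' Draws `n_emitters` points uniformly at random on a 1 nm grid inside a disk
#' of the given diameter (default 240 nm, the Abbe limit for AF647). Because
#' the disk diameter equals the limit, all pairwise distances are guaranteed
#' to be sub-diffraction. Coordinates are returned relative to the disk
#' center.
#'
#' @param n_emitters Number of emitters (>= 2; single positions are drawn by
#'   the dataset builder directly).
#' @param diameter_nm Disk diameter in nm.
#' @param grid_nm Grid pitch in nm (coordinates are integer multiples).
#' @return `n_emitters` x 2 matrix of `c(x, y)` nm offsets from the disk
#'   center.
#' @export
sample_emitter_coordinates <- function(n_emitters, diameter_nm = 240,
                                       grid_nm = 1) {
  if (n_emitters < 2) stop("`n_emitters` must be >= 2")
  r <- diameter_nm / 2
  out <- matrix(NA_real_, n_emitters, 2)
  got <- 0
  while (got < n_emitters) {
    m <- 2 * (n_emitters - got)
    x <- round(runif(m, -r, r) / grid_nm) * grid_nm
    y <- round(runif(m, -r, r) / grid_nm) * grid_nm
    ok <- which(x^2 + y^2 <= r^2)
    take <- head(ok, n_emitters - got)
    if (length(take)) {
      out[(got + 1):(got + length(take)), ] <- cbind(x[take], y[take])
      got <- got + length(take)
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Sample an emitter pair at a constrained separation
#'
#' Draws two points whose separation is uniform within `distance_nm` (an
#' interval, e.g. `c(28, 32)` for the 30 +/- 2 nm evaluation subset) with a
#' uniformly random orientation, centered on the origin and snapped to a 1 nm
#' grid (so the realized distance deviates by at most sqrt(2) nm).
#'
#' @param distance_nm Length-2 interval of separations in nm, within
#'   (0, 240].
#' @param grid_nm Grid pitch in nm.
#' @return 2 x 2 matrix of `c(x, y)` nm coordinates.
#' @export
sample_constrained_pair <- function(distance_nm = c(28, 32), grid_nm = 1) {
  if (length(distance_nm) == 1) distance_nm <- rep(distance_nm, 2)
  if (distance_nm[1] > distance_nm[2] || distance_nm[2] <= 0 ||
      distance_nm[2] > 240) {
    stop("`distance_nm` must be a non-empty interval within (0, 240]")
  }
  d <- runif(1, distance_nm[1], distance_nm[2])
  th <- runif(1, 0, 2 * pi)
  half <- (d / 2) * c(cos(th), sin(th))
  pts <- rbind(-half, half)
  pts <- round(pts / grid_nm) * grid_nm
  colnames(pts) <- c("x", "y")
  pts
}

# Bilinear sub-pixel shift with zero fill outside the crop.
bilinear_shift <- function(mat, dx_px, dy_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  padded <- matrix(0, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mat
  for (i in seq_len(nr)) {
    si <- i - dy_px
    i0 <- floor(si); wi <- si - i0
    if (i0 < 0 || i0 > nr) next
    for (j in seq_len(nc)) {
      sj <- j - dx_px
      j0 <- floor(sj); wj <- sj - j0
      if (j0 < 0 || j0 > nc) next
      out[i, j] <- (1 - wi) * (1 - wj) * padded[i0 + 1, j0 + 1] +
        (1 - wi) * wj * padded[i0 + 1, j0 + 2] +
        wi * (1 - wj) * padded[i0 + 2, j0 + 1] +
        wi * wj * padded[i0 + 2, j0 + 2]
    }
  }
  out
}

# Circular Fourier shift of a matrix by (dx, dy) pixels, computed after
# zero-padding to 3x the size so the wrap-around crosses only zeros.
fourier_shift <- function(mat, dx_px, dy_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  P_r <- 3 * nr; P_c <- 3 * nc
  pad <- matrix(0, P_r, P_c)
  pad[(nr + 1):(2 * nr), (nc + 1):(2 * nc)] <- mat
  kx <- c(0:floor(P_c / 2), -(ceiling(P_c / 2) - 1):-1)[1:P_c]
  ky <- c(0:floor(P_r / 2), -(ceiling(P_r / 2) - 1):-1)[1:P_r]
  phase <- outer(exp(-2i * pi * ky * dy_px / P_r),
                 exp(-2i * pi * kx * dx_px / P_c))
  shifted <- Re(fft(fft(pad) * phase, inverse = TRUE)) / (P_r * P_c)
  shifted[(nr + 1):(2 * nr), (nc + 1):(2 * nc)]
}

#' Superimpose library spots at target coordinates
#'
#' Builds one multi-emitter sub-diffraction-limited spot by translating each
#' single-emitter record so that its Gaussian-fitted emitter position lands
#' exactly on its target coordinate, then summing the translated images
#' pixel-wise. Translation decomposes into an integer-pixel placement and a
#' sub-pixel shift. The target coordinates become the ground-truth label.
#'
#' The default sub-pixel method, `"gaussian_residual"`, re-renders the
#' record's fitted pixel-integrated Gaussian at the shifted position and adds
#' the Fourier-shifted fit residual: a spot sampled at 160 nm/px is not
#' band-limited, so interpolating the raw pixels (pure `"fourier"` or
#' `"bilinear"`) errs by several percent of peak at half-pixel shifts,
#' whereas the model carries the bulk of the flux analytically and only the
#' small residual (noise plus non-Gaussian structure) is interpolated.
#'
#' @param records List of library records (from [build_synthetic_library()]),
#'   one per target coordinate, each carrying a `fit`.
#' @param target_coords k x 2 matrix of `c(x, y)` positions in the output
#'   canvas frame, nm.
#' @param out_shape_px Canvas size in pixels (default 15 x 15).
#' @param shift_method `"gaussian_residual"` (default), `"fourier"`, or
#'   `"bilinear"`.
#' @return An object of class `labeled_spot`: `image` ([spot_image()]),
#'   `count`, `coords` (k x 2 nm, canvas frame), `pair_dist_nm` (max pairwise
#'   distance; NA for a single emitter) and `source_ids`.
#' @export
merge_spots <- function(records, target_coords, out_shape_px = c(15, 15),
                        shift_method = c("gaussian_residual", "fourier",
                                         "bilinear")) {
  shift_method <- match.arg(shift_method)
  target_coords <- rbind(target_coords)
  k <- nrow(target_coords)
  if (length(records) != k) stop("need one record per target coordinate")
  px <- records[[1]]$image$pixel_size_nm
  lim <- c(out_shape_px[2], out_shape_px[1]) * px
  if (any(target_coords < 0) || any(target_coords[, 1] > lim[1]) ||
      any(target_coords[, 2] > lim[2])) {
    stop("target coordinate outside the output canvas")
  }
  canvas <- matrix(0, out_shape_px[1], out_shape_px[2])
  for (i in seq_len(k)) {
    rec <- records[[i]]
    if (is.null(rec$fit)) stop("library record lacks a Gaussian fit")
    crop <- rec$image$data
    anchor <- c(rec$fit$x0_nm, rec$fit$y0_nm) - rec$image$offset_nm
    s <- target_coords[i, ] - anchor
    s_int <- round(s / px)
    frac <- s - s_int * px
    shifted <- if (max(abs(frac)) < 1e-9) {
      crop # pure integer-pixel shift: exact
    } else if (shift_method == "fourier") {
      fourier_shift(crop, frac[1] / px, frac[2] / px)
    } else if (shift_method == "bilinear") {
      bilinear_shift(crop, frac[1] / px, frac[2] / px)
    } else {
      fit <- rec$fit
      model_at <- function(xy) {
        render_psf(xy, fit$photons,
                   psf_model(sigma_x_nm = fit$sigma_x_nm,
                             sigma_y_nm = fit$sigma_y_nm),
                   camera_model(pixel_size_nm = px),
                   dim(crop), offset_nm = rec$image$offset_nm)$data
      }
      old_pos <- c(fit$x0_nm, fit$y0_nm)
      residual <- crop - model_at(old_pos)
      model_at(old_pos + frac) +
        fourier_shift(residual, frac[1] / px, frac[2] / px)
    }
    rows <- seq_len(nrow(crop)) + s_int[2]
    cols <- seq_len(ncol(crop)) + s_int[1]
    ok_r <- rows >= 1 & rows <= out_shape_px[1]
    ok_c <- cols >= 1 & cols <= out_shape_px[2]
    canvas[rows[ok_r], cols[ok_c]] <-
      canvas[rows[ok_r], cols[ok_c]] + shifted[which(ok_r), which(ok_c)]
  }
  pair_dist <- if (k >= 2) max(stats::dist(target_coords)) else NA_real_
  structure(list(image = spot_image(canvas, pixel_size_nm = px),
                 count = k, coords = target_coords,
                 pair_dist_nm = pair_dist,
                 source_ids = vapply(records, function(r) r$molecule_id,
                                     numeric(1))),
            class = "labeled_spot")
}

#' Zero-pad an image to the network input size
#'
#' Centers the input in a zero canvas of the target shape (e.g. 11x11
#' inference crops padded to the 15x15 network format) and updates the global
#' offset so nm coordinates survive the round trip.
#'
#' @param image A [spot_image()] or matrix.
#' @param target_px Length-2 target shape `c(rows, cols)`.
#' @return A [spot_image()] of the target shape.
#' @export
pad_to_input <- function(image, target_px = c(15, 15)) {
  sp <- as_spot_image(image)
  nr <- nrow(sp$data); nc <- ncol(sp$data)
  if (nr > target_px[1] || nc > target_px[2]) {
    stop("input larger than target shape")
  }
  top <- floor((target_px[1] - nr) / 2)
  left <- floor((target_px[2] - nc) / 2)
  out <- matrix(0, target_px[1], target_px[2])
  out[top + seq_len(nr), left + seq_len(nc)] <- sp$data
  spot_image(out,
             offset_nm = sp$offset_nm - c(left, top) * sp$pixel_size_nm,
             pixel_size_nm = sp$pixel_size_nm)
}

#' Build a labeled multi-emitter spot dataset
#'
#' Assembles a balanced, reproducible dataset of labeled sub-diffraction-
#' limited spots by drawing emitter configurations inside the 240 nm disk and
#' superimposing library spots at them ([merge_spots()]). The merged spot is
#' rendered on a 15x15 canvas whose center receives the centroid of the
#' emitter configuration plus a +/- 0.5 px uniform jitter (so the centroid is
#' not a trivial cue, mirroring the noisy crop centers of real inference).
#' Train and test splits use disjoint library molecules to prevent leakage
#' through reused source spots.
#'
#' @param library A [build_synthetic_library()] result (records must be
#'   fitted).
#' @param n_per_class Spots per emitter-count class.
#' @param classes Emitter counts to generate (subset of 1:4).
#' @param diameter_nm Diffraction-limited disk diameter.
#' @param pair_interval_nm Optional separation interval passed to
#'   [sample_constrained_pair()]; applies to two-emitter spots only.
#' @param jitter_px Centroid placement jitter, pixels.
#' @param test_fraction Fraction of spots (and library molecules) held out.
#' @param canvas_px Canvas shape.
#' @param shift_method Sub-pixel translation method, see [merge_spots()].
#' @param seed Optional integer seed.
#' @return An object of class `labeled_dataset`: `images` (n x 225 matrix,
#'   one flattened 15x15 canvas per row, photon counts), `labels` (data.frame
#'   with `count`, coordinates `x1,y1,...` in canvas nm, `pair_dist_nm`,
#'   `split`), plus generation metadata.
#' @export
build_dataset <- function(library, n_per_class, classes = c(1, 2),
                          diameter_nm = 240, pair_interval_nm = NULL,
                          jitter_px = 0.5, test_fraction = 0.1,
                          canvas_px = c(15, 15),
                          shift_method = "gaussian_residual", seed = NULL) {
  stopifnot(inherits(library, "spot_library"), n_per_class >= 1)
  if (!all(classes %in% 1:4)) stop("emitter counts are capped at 1..4")
  if (!is.null(seed)) set.seed(seed)
  recs <- library$records
  n_mol <- length(recs)
  if (n_mol < 2) stop("library too small")
  px <- library$camera$pixel_size_nm
  center <- c(canvas_px[2], canvas_px[1]) / 2 * px
  test_ids <- if (test_fraction > 0) {
    sample(n_mol, max(1, round(test_fraction * n_mol)))
  } else integer(0)
  pools <- list(train = setdiff(seq_len(n_mol), test_ids), test = test_ids)

  n_total <- n_per_class * length(classes)
  images <- matrix(0, n_total, prod(canvas_px))
  labs <- data.frame(count = integer(n_total),
                     x1 = NA_real_, y1 = NA_real_, x2 = NA_real_,
                     y2 = NA_real_, x3 = NA_real_, y3 = NA_real_,
                     x4 = NA_real_, y4 = NA_real_,
                     pair_dist_nm = NA_real_,
                     split = character(n_total))
  row <- 0
  for (cls in classes) {
    n_test <- round(test_fraction * n_per_class)
    split_of <- rep(c("train", "test"), c(n_per_class - n_test, n_test))
    for (i in seq_len(n_per_class)) {
      split <- split_of[i]
      pool <- pools[[split]]
      if (length(pool) == 0) pool <- pools$train
      coords <- if (cls == 1) {
        sample_emitter_coordinates(2, diameter_nm)[1, , drop = FALSE]
      } else if (cls == 2 && !is.null(pair_interval_nm)) {
        sample_constrained_pair(pair_interval_nm)
      } else {
        sample_emitter_coordinates(cls, diameter_nm)
      }
      centroid <- colMeans(coords)
      jit <- runif(2, -jitter_px, jitter_px) * px
      targets <- sweep(coords, 2, centroid) +
        matrix(center + jit, nrow(coords), 2, byrow = TRUE)
      ids <- pool[sample.int(length(pool), cls, replace = cls > length(pool))]
      spot <- merge_spots(recs[ids], targets, canvas_px,
                          shift_method = shift_method)
      row <- row + 1
      images[row, ] <- as.vector(spot$image$data)
      labs$count[row] <- cls
      for (j in seq_len(cls)) {
        labs[[paste0("x", j)]][row] <- targets[j, 1]
        labs[[paste0("y", j)]][row] <- targets[j, 2]
      }
      labs$pair_dist_nm[row] <- spot$pair_dist_nm
      labs$split[row] <- split
    }
  }
  structure(list(images = images, labels = labs, canvas_px = canvas_px,
                 pixel_size_nm = px, seed = seed,
                 config = list(classes = classes, n_per_class = n_per_class,
                               diameter_nm = diameter_nm,
                               pair_interval_nm = pair_interval_nm,
                               jitter_px = jitter_px,
                               test_fraction = test_fraction)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d spots (%s), classes {%s}>\n",
              nrow(x$images),
              paste(names(table(x$labels$split)), table(x$labels$split),
                    sep = ":", collapse = ", "),
              paste(sort(unique(x$labels$count)), collapse = ",")))
  invisible(x)
}

#' Write / read a labeled dataset
#'
#' Serializes a dataset as a directory: `images.tiff` (one page per spot),
#' `labels.csv` (counts, coordinates, distances, split) and `meta.yaml`.
#'
#' @param dataset A [build_dataset()] result.
#' @param dir Output directory.
#' @return `dir` invisibly (write); a `labeled_dataset` (read).
#' @export
write_labeled_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(seq_len(nrow(dataset$images)), function(i) {
    matrix(dataset$images[i, ], dataset$canvas_px[1], dataset$canvas_px[2])
  })
  write_stack(pages, file.path(dir, "images.tiff"))
  write.csv(dataset$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  yaml::write_yaml(list(canvas_px = dataset$canvas_px,
                        pixel_size_nm = dataset$pixel_size_nm,
                        seed = dataset$seed, config = dataset$config),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(dir) {
  pages <- read_stack(file.path(dir, "images.tiff"))
  labels <- read.csv(file.path(dir, "labels.csv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  images <- do.call(rbind, lapply(pages, as.vector))
  structure(list(images = images, labels = labels,
                 canvas_px = unlist(meta$canvas_px),
                 pixel_size_nm = meta$pixel_size_nm, seed = meta$seed,
                 config = meta$config),
            class = "labeled_dataset")
}

#' Extract ground-truth coordinate matrix for one spot
#'
#' @param labels The `labels` data.frame of a [build_dataset()] result.
#' @param i Row index.
#' @return k x 2 matrix of nm coordinates in the canvas frame.
#' @export
label_coords <- function(labels, i) {
  k <- labels$count[i]
  m <- matrix(NA_real_, k, 2)
  for (j in seq_len(k)) {
    m[j, ] <- c(labels[[paste0("x", j)]][i], labels[[paste0("y", j)]][i])
  }
  colnames(m) <- c("x", "y")
  m
}
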