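# Frame-level two-stage inference: detect spots, crop and pad, classify the
# emitter count, route to the count-matched localizer, emit global-frame
# localizations.

#' Cut and pad an inference crop
#'
#' Extracts an 11x11 crop (5 pixels around the determined center) and
#' zero-pads it to the 15x15 network input format, preserving the global
#' offset metadata.
#'
#' @param frame Numeric matrix or [spot_image()].
#' @param center_px `c(row, col)` 1-based pixel center (from detection /
#'   Gaussian fit).
#' @param pixel_size_nm Pixel pitch for bare-matrix frames.
#' @return A 15x15 [spot_image()].
#' @export
preprocess_crop <- function(frame, center_px, pixel_size_nm = 160) {
  crop <- crop_spot(frame, center_px, radius_px = 5,
                    pixel_size_nm = pixel_size_nm)
  pad_to_input(crop, c(15, 15))
}

#' Predict emitter count and positions for one crop
#'
#' Runs the classifier on the 15x15 crop, picks the count by maximum class
#' probability (ties broken toward the lower count), then routes the crop to
#' the localizer trained for that count and maps its canvas-relative
#' coordinates to the global frame via the crop offset.
#'
#' @param bundle A [model_bundle()].
#' @param crop A 15x15 [spot_image()] (raw photon counts).
#' @return A list of class `prediction_record`: `count`, `confidence`
#'   (named class-probability vector), `coords_nm` (count x 2 global nm),
#'   `offset_nm`.
#' @export
predict_spot <- function(bundle, crop) {
  stopifnot(inherits(bundle, "model_bundle"))
  sp <- as_spot_image(crop)
  img_row <- matrix(as.vector(sp$data), nrow = 1)
  cls <- bundle$classifier
  probs <- as.vector(model_forward(cls, img_row))
  names(probs) <- as.character(cls$classes)
  best <- which(probs >= max(probs) - 1e-12)
  count <- cls$classes[min(best)] # tie-break: lower emitter count
  loc <- bundle$localizers[[as.character(count)]]
  if (is.null(loc)) {
    stop(sprintf("no localizer available for predicted count %d", count))
  }
  rel <- as.vector(model_forward(loc, img_row))
  coords <- matrix(rel, ncol = 2, byrow = TRUE)
  coords <- sweep(coords, 2, loc$center_nm + sp$offset_nm, "+")
  colnames(coords) <- c("x", "y")
  structure(list(count = count, confidence = probs, coords_nm = coords,
                 offset_nm = sp$offset_nm),
            class = "prediction_record")
}

#' Process one camera frame
#'
#' Detects candidate spots, refines each center with a single Gaussian fit of
#' the 7x7 crop (which for multi-emitter spots lands near the photometric
#' center), merges detections closer than 2 px, and predicts emitter counts
#' and coordinates for every surviving crop.
#'
#' @param frame Numeric matrix (photon counts).
#' @param bundle A [model_bundle()].
#' @param camera A [camera_model()].
#' @param frame_index Frame number recorded in the output.
#' @param detect_args List of extra arguments for [detect_spot_centers()].
#' @return List of `prediction_record`s (empty when nothing is detected).
#' @export
process_frame <- function(frame, bundle, camera = camera_model(),
                          frame_index = 1, detect_args = list()) {
  centers <- do.call(detect_spot_centers, c(list(frame), detect_args))
  if (nrow(centers) == 0) return(list())
  px <- camera$pixel_size_nm
  refined <- centers
  for (i in seq_len(nrow(centers))) {
    ctr <- c(centers$row[i], centers$col[i])
    fit <- tryCatch(
      suppressWarnings(fit_gaussian_2d(crop_spot(frame, ctr, 3, px))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      refined$row[i] <- min(max(1, floor(fit$y0_nm / px) + 1), nrow(frame))
      refined$col[i] <- min(max(1, floor(fit$x0_nm / px) + 1), ncol(frame))
    }
  }
  # merge refined centers within 2 px (keep the brighter)
  keep <- rep(TRUE, nrow(refined))
  for (i in seq_len(nrow(refined))) {
    if (!keep[i]) next
    if (i < nrow(refined)) {
      later <- (i + 1):nrow(refined)
      d2 <- (refined$row[later] - refined$row[i])^2 +
        (refined$col[later] - refined$col[i])^2
      keep[later][d2 <= 4] <- FALSE
    }
  }
  refined <- refined[keep, , drop = FALSE]
  out <- vector("list", nrow(refined))
  for (i in seq_len(nrow(refined))) {
    crop <- preprocess_crop(frame, c(refined$row[i], refined$col[i]), px)
    rec <- predict_spot(bundle, crop)
    rec$frame_index <- frame_index
    out[[i]] <- rec
  }
  out
}

#' Process a frame stack into a localization table
#'
#' Batch driver over [process_frame()]: concatenates per-frame prediction
#' records into a ThunderSTORM-style localization table. Frames that fail are
#' skipped with a warning and counted.
#'
#' @param stack List of frames (numeric matrices) or a 3D array with frames
#'   along the third dimension.
#' @param bundle A [model_bundle()].
#' @param camera A [camera_model()].
#' @param detect_args Extra arguments for [detect_spot_centers()].
#' @return A `localization_table` data.frame with columns `frame`, `spot`,
#'   `x [nm]`, `y [nm]`, `count`, `confidence`. Attribute `n_failed` counts
#'   skipped frames.
#' @export
process_stack <- function(stack, bundle, camera = camera_model(),
                          detect_args = list()) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  rows <- list()
  n_failed <- 0
  for (f in seq_along(stack)) {
    recs <- tryCatch(
      process_frame(stack[[f]], bundle, camera, frame_index = f,
                    detect_args = detect_args),
      error = function(e) {
        warning(sprintf("frame %d skipped: %s", f, conditionMessage(e)))
        n_failed <<- n_failed + 1
        list()
      })
    for (s in seq_along(recs)) {
      rec <- recs[[s]]
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, spot = s,
        x = rec$coords_nm[, 1], y = rec$coords_nm[, 2],
        count = rec$count, confidence = max(rec$confidence),
        check.names = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), spot = integer(0), x = numeric(0),
               y = numeric(0), count = integer(0), confidence = numeric(0))
  names(tab)[names(tab) == "x"] <- "x [nm]"
  names(tab)[names(tab) == "y"] <- "y [nm]"
  attr(tab, "n_failed") <- n_failed
  class(tab) <- c("localization_table", class(tab))
  tab
}
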