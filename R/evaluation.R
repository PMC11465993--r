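# Quantitative evaluation: confusion-matrix metrics, minimum-cost emitter
# matching, RMS localization error with distance binning, displacement maps,
# and the spike-rendering / Gaussian-convolution / SSIM comparison harness.

#' Confusion matrix from predicted and true emitter counts
#'
#' With the two-emitter class as "positive": TP = true 2 predicted 2,
#' FN = true 2 predicted 1, FP = true 1 predicted 2, TN = true 1 predicted 1.
#' For more than two classes use `table(truth, prediction)` directly.
#'
#' @param predicted,truth Integer vectors of emitter counts.
#' @param positive The count treated as the positive class (default 2).
#' @return An object of class `confusion_matrix` with fields TP, FP, FN, TN.
#' @export
confusion_matrix <- function(predicted, truth, positive = 2) {
  stopifnot(length(predicted) == length(truth))
  pp <- predicted == positive
  tp <- truth == positive
  structure(list(TP = sum(pp & tp), FP = sum(pp & !tp),
                 FN = sum(!pp & tp), TN = sum(!pp & !tp),
                 positive = positive),
            class = "confusion_matrix")
}

#' Classification metrics
#'
#' Recall = TP/(TP+FN), Precision = TP/(TP+FP),
#' Accuracy = (TP+TN)/(TP+FN+FP+TN). A zero denominator yields `NaN` (an
#' explicit undefined flag), never silently 0.
#'
#' @param cm A [confusion_matrix()] or list with TP, FP, FN, TN.
#' @return Named numeric vector `c(precision, recall, accuracy)`.
#' @export
classification_metrics <- function(cm) {
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total == 0) stop("empty confusion matrix")
  prec <- if (cm$TP + cm$FP == 0) NaN else cm$TP / (cm$TP + cm$FP)
  rec <- if (cm$TP + cm$FN == 0) NaN else cm$TP / (cm$TP + cm$FN)
  c(precision = prec, recall = rec, accuracy = (cm$TP + cm$TN) / total)
}

#' Minimum-cost emitter matching
#'
#' Finds the bijection between predicted and true emitters that minimizes the
#' total squared distance, via an exact bitmask dynamic program (any n; the
#' pipeline caps emitter counts at 4).
#'
#' @param pred,truth k x 2 coordinate matrices (nm).
#' @return Integer vector `a` with `a[i]` = index of the true emitter matched
#'   to prediction i; attribute `"cost"` holds the total squared distance.
#' @export
match_emitters <- function(pred, truth) {
  pred <- rbind(pred); truth <- rbind(truth)
  k <- nrow(pred)
  if (k != nrow(truth)) stop("coordinate lists must have equal length")
  if (k == 0) stop("empty coordinate lists")
  cost <- outer(seq_len(k), seq_len(k), function(i, j) {
    (pred[i, 1] - truth[j, 1])^2 + (pred[i, 2] - truth[j, 2])^2
  })
  # dp over subsets of truth indices assigned to predictions 1..popcount(mask)
  n_mask <- bitwShiftL(1L, k)
  dp <- rep(Inf, n_mask)
  choice <- rep(NA_integer_, n_mask)
  parent <- rep(NA_integer_, n_mask)
  dp[1] <- 0
  popcount <- vapply(0:(n_mask - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0), numeric(1))
  for (mask in 0:(n_mask - 2)) {
    m1 <- mask + 1L
    if (!is.finite(dp[m1])) next
    i <- popcount[m1] + 1 # next prediction to assign
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0) next
      nm <- bitwOr(mask, bit) + 1L
      cand <- dp[m1] + cost[i, j]
      if (cand < dp[nm]) { dp[nm] <- cand; choice[nm] <- j; parent[nm] <- m1 }
    }
  }
  assign <- integer(k)
  m <- n_mask
  while (!is.na(choice[m])) {
    i <- popcount[m]
    assign[i] <- choice[m]
    m <- parent[m]
  }
  structure(assign, cost = dp[n_mask])
}

#' RMS localization error
#'
#' RMS = sqrt( sum_i [(x_i - xbar_i)^2 + (y_i - ybar_i)^2] / (2I) ) over the
#' I emitters of one spot. When `match = TRUE` (default) predictions are
#' first paired to truths by [match_emitters()], so the error is invariant
#' under emitter relabeling.
#'
#' @param pred,truth I x 2 coordinate matrices (nm).
#' @param match Apply minimum-cost matching before computing the error.
#' @return RMS error in nm.
#' @export
rms_error <- function(pred, truth, match = TRUE) {
  pred <- rbind(pred); truth <- rbind(truth)
  if (nrow(pred) == 0) stop("empty coordinate lists")
  if (nrow(pred) != nrow(truth)) stop("coordinate lists must have equal length")
  if (match && nrow(pred) > 1) {
    truth <- truth[match_emitters(pred, truth), , drop = FALSE]
  }
  sqrt(sum((pred - truth)^2) / (2 * nrow(pred)))
}

#' Midpoint-baseline RMS for an emitter pair
#'
#' Predicting both emitters of a pair separated by d at their midpoint gives
#' RMS = d / (2 sqrt(2)) exactly: the trivial lower bar any two-emitter
#' localizer must beat at resolvable separations.
#'
#' @param distance_nm Pair separation(s) in nm.
#' @return Baseline RMS in nm.
#' @export
midpoint_baseline_rms <- function(distance_nm) {
  distance_nm / (2 * sqrt(2))
}

#' Bin per-spot RMS values by true pair distance
#'
#' Groups two-emitter evaluation records into separation bins (default the
#' four 60 nm bins spanning the 240 nm diffraction limit) and summarizes the
#' RMS per bin.
#'
#' @param records Data.frame with columns `rms` and `pair_dist_nm`.
#' @param edges Bin edges in nm.
#' @return Data.frame with bin labels, counts, mean/median and quartiles.
#' @export
bin_rms_by_distance <- function(records, edges = c(0, 60, 120, 180, 240)) {
  stopifnot(all(c("rms", "pair_dist_nm") %in% names(records)))
  bin <- cut(records$pair_dist_nm, edges, include.lowest = TRUE)
  excluded <- sum(is.na(bin))
  if (excluded > 0) {
    message(sprintf("%d records outside all bins excluded", excluded))
  }
  keep <- !is.na(bin)
  out <- do.call(rbind, lapply(levels(bin), function(lv) {
    v <- records$rms[keep & bin == lv]
    data.frame(bin = lv, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) quantile(v, 0.25, names = FALSE) else NA_real_,
               q75 = if (length(v)) quantile(v, 0.75, names = FALSE) else NA_real_)
  }))
  attr(out, "excluded") <- excluded
  out
}

#' Displacement heatmap of prediction errors
#'
#' 2D histogram of (prediction - truth) displacement vectors, centered at the
#' origin: with perfect predictions all mass falls in the central cell.
#'
#' @param displacements n x 2 matrix of `c(dx, dy)` nm displacement vectors
#'   (matched predictions minus truths).
#' @param half_range_nm Half-width of the map (nm).
#' @param cell_nm Histogram cell size (nm).
#' @param kernel_sigma_cells Optional Gaussian smoothing, in cells (0 = off).
#' @return Square numeric matrix; total mass equals the number of
#'   displacements inside the range.
#' @export
displacement_heatmap <- function(displacements, half_range_nm = 60,
                                 cell_nm = 2, kernel_sigma_cells = 0) {
  displacements <- rbind(displacements)
  n_cells <- 2 * ceiling(half_range_nm / cell_nm) + 1
  ctr <- (n_cells + 1) / 2
  H <- matrix(0, n_cells, n_cells)
  ix <- round(displacements[, 1] / cell_nm) + ctr
  iy <- round(displacements[, 2] / cell_nm) + ctr
  ok <- ix >= 1 & ix <= n_cells & iy >= 1 & iy <= n_cells
  for (k in which(ok)) H[iy[k], ix[k]] <- H[iy[k], ix[k]] + 1
  if (kernel_sigma_cells > 0) H <- gaussian_blur(H, kernel_sigma_cells)
  H
}

#' Render localization spikes on a high-resolution canvas
#'
#' Places a unit impulse at the high-resolution pixel containing each
#' coordinate (coincident coordinates accumulate), the first step of the
#' spike-image reconstruction used for SSIM comparison of methods.
#'
#' @param coords_nm n x 2 matrix of `c(x, y)` nm coordinates.
#' @param canvas_px Size of the low-resolution canvas, pixels.
#' @param upsampling Integer high-resolution factor (default 8).
#' @param pixel_size_nm Low-resolution pixel pitch.
#' @return Numeric matrix of size `canvas_px * upsampling`.
#' @export
render_spikes <- function(coords_nm, canvas_px = c(15, 15), upsampling = 8,
                          pixel_size_nm = 160) {
  hi_px <- pixel_size_nm / upsampling
  nr <- canvas_px[1] * upsampling; nc <- canvas_px[2] * upsampling
  img <- matrix(0, nr, nc)
  coords_nm <- rbind(coords_nm)
  if (nrow(coords_nm) == 0) return(img)
  i <- floor(coords_nm[, 2] / hi_px) + 1
  j <- floor(coords_nm[, 1] / hi_px) + 1
  if (any(i < 1 | i > nr | j < 1 | j > nc)) {
    stop("coordinate outside the canvas")
  }
  for (k in seq_len(nrow(coords_nm))) img[i[k], j[k]] <- img[i[k], j[k]] + 1
  img
}

#' Convolve a spike image with a Gaussian kernel
#'
#' Produces the smooth super-resolution heatmap from a spike image, with
#' zero padding outside the canvas.
#'
#' @param spikes Numeric matrix from [render_spikes()] (or any image).
#' @param kernel_sigma_px Gaussian sigma in high-resolution pixels (> 0).
#' @return Numeric matrix, same shape.
#' @export
heatmap_from_spikes <- function(spikes, kernel_sigma_px = 1) {
  if (kernel_sigma_px <= 0) stop("`kernel_sigma_px` must be > 0")
  gaussian_blur(spikes, kernel_sigma_px)
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM between two equally shaped images, computed with a square
#' uniform window (default 7x7), unbiased covariance normalization and the
#' standard stabilization constants C1 = (0.01 L)^2, C2 = (0.03 L)^2, where L
#' is the data range. Identical images give exactly 1.
#'
#' @param image_a,image_b Numeric matrices of equal shape.
#' @param window Odd window side length.
#' @param data_range Dynamic range L; default the observed range over both
#'   images.
#' @param K1,K2 Stabilization constants.
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(image_a, image_b, window = 7, data_range = NULL,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(image_a) == dim(image_b))) stop("images differ in shape")
  if (window %% 2 != 1 || window < 3) stop("`window` must be odd and >= 3")
  if (any(dim(image_a) < window)) stop("images smaller than the window")
  L <- data_range %||% (max(image_a, image_b) - min(image_a, image_b))
  if (L <= 0) return(1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  N <- window^2
  win_mean <- function(m) {
    # mean over all fully interior (valid) windows
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    v <- cs[(window + 1):nrow(cs), , drop = FALSE] -
      cs[1:(nrow(cs) - window), , drop = FALSE]
    cs2 <- t(apply(v, 1, cumsum))
    cs2 <- cbind(0, cs2)
    (cs2[, (window + 1):ncol(cs2), drop = FALSE] -
       cs2[, 1:(ncol(cs2) - window), drop = FALSE]) / N
  }
  ux <- win_mean(image_a); uy <- win_mean(image_b)
  uxx <- win_mean(image_a^2); uyy <- win_mean(image_b^2)
  uxy <- win_mean(image_a * image_b)
  cov_norm <- N / (N - 1)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}
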