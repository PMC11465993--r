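# Spot detection: band-pass filtering and local-maximum search on raw frames.

# Separable Gaussian blur with zero padding outside the frame.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  blur1 <- function(m) { # along rows (dimension 1), zero padded
    n <- nrow(m)
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + n - 1), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(mat))))
}

# Difference-of-Gaussians band-pass used for detection only; raw pixels are
# always what gets cropped and fitted.
bandpass_filter <- function(mat, sigma_small = 1, sigma_large = 3) {
  gaussian_blur(mat, sigma_small) - gaussian_blur(mat, sigma_large)
}

#' Detect candidate spot centers in a frame
#'
#' Applies a difference-of-Gaussians band-pass filter (suppressing pixel noise
#' and slowly varying background), then finds local maxima above a robust
#' threshold. Maxima closer than `min_separation_px` are merged greedily by
#' brightness, so one spot footprint yields at most one center.
#'
#' @param frame Numeric matrix (a raw camera frame, photon counts).
#' @param threshold_sd Detection threshold in units of the robust (MAD-based)
#'   standard deviation of the filtered frame (default 5).
#' @param sigma_small_px,sigma_large_px Band-pass widths in pixels.
#' @param min_separation_px Minimum center-to-center distance kept, pixels.
#' @return A data.frame with 1-based pixel indices `row`, `col` and the
#'   filtered intensity `value`, ordered by decreasing brightness. Zero rows
#'   when nothing is detected.
#' @export
detect_spot_centers <- function(frame, threshold_sd = 5,
                                sigma_small_px = 1, sigma_large_px = 3,
                                min_separation_px = 3) {
  stopifnot(is.matrix(frame))
  empty <- data.frame(row = integer(0), col = integer(0), value = numeric(0))
  if (all(frame == 0)) return(empty)
  f <- bandpass_filter(frame, sigma_small_px, sigma_large_px)
  thr <- threshold_sd * max(mad(f), 1e-12)
  nr <- nrow(f); nc <- ncol(f)
  # strict 8-neighbour local maxima (ties broken by > on shifted copies)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- f
  is_max <- f > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    is_max <- is_max & (f >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  vals <- f[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- rep(TRUE, nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!keep[i]) next
    if (i < nrow(idx)) {
      later <- (i + 1):nrow(idx)
      d2 <- (idx[later, 1] - idx[i, 1])^2 + (idx[later, 2] - idx[i, 2])^2
      keep[later][d2 < min_separation_px^2] <- FALSE
    }
  }
  data.frame(row = as.integer(idx[keep, 1]), col = as.integer(idx[keep, 2]),
             value = vals[keep])
}

#' Crop a square spot image out of a frame
#'
#' Extracts a (2r+1) x (2r+1) crop centered on a pixel, zero-filling pixels
#' that fall outside the frame, and records the crop's global offset so
#' coordinates survive the round trip. Radius 3 yields the 7x7 library crops;
#' radius 5 the 11x11 inference crops.
#'
#' @param frame Numeric matrix or [spot_image()].
#' @param center_px Length-2 `c(row, col)`, 1-based pixel indices.
#' @param radius_px Crop radius in pixels.
#' @param pixel_size_nm Pixel pitch (used when `frame` is a bare matrix).
#' @return A [spot_image()].
#' @export
crop_spot <- function(frame, center_px, radius_px = 3, pixel_size_nm = 160) {
  fr <- as_spot_image(frame, pixel_size_nm)
  nr <- nrow(fr$data); nc <- ncol(fr$data)
  ci <- center_px[1]; cj <- center_px[2]
  if (ci < 1 || ci > nr || cj < 1 || cj > nc) {
    stop("crop center outside frame bounds")
  }
  n <- 2 * radius_px + 1
  out <- matrix(0, n, n)
  rows <- (ci - radius_px):(ci + radius_px)
  cols <- (cj - radius_px):(cj + radius_px)
  ok_r <- rows >= 1 & rows <= nr
  ok_c <- cols >= 1 & cols <= nc
  out[which(ok_r), which(ok_c)] <- fr$data[rows[ok_r], cols[ok_c], drop = FALSE]
  off <- fr$offset_nm + c(cols[1] - 1, rows[1] - 1) * fr$pixel_size_nm
  spot_image(out, offset_nm = off, pixel_size_nm = fr$pixel_size_nm)
}
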