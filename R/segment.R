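#' Excess-green gray conversion of an RGB image
#'
#' Scales each channel to `[0, 1]` by bit depth and computes `2G - R - B`
#' per pixel. Vegetation scores high, soil and neutral surfaces near zero,
#' so the resulting gray image is suited to entropy-based thresholding.
#'
#' @param rgb HxWx3 array of DN values (channel order R, G, B).
#' @param bits bit depth of the DN values.
#' @return an object of class `gray_image`: list with `gray` (HxW matrix)
#'   and `valid` (HxW logical; ExG is defined everywhere).
#' @export
gray_exg <- function(rgb, bits = 8L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("gray_exg: expected an HxWx3 array", call. = FALSE)
  }
  if (any(rgb < 0)) stop("gray_exg: DN values must be >= 0", call. = FALSE)
  s <- rgb / (2^bits - 1)
  g <- 2 * s[, , 2] - s[, , 1] - s[, , 3]
  structure(list(gray = g, valid = matrix(TRUE, nrow(g), ncol(g))),
            class = "gray_image")
}

#' NDVI gray conversion of a multispectral image
#'
#' Computes `(NIR - Red) / (NIR + Red)` per pixel. Pixels with
#' `NIR + Red == 0` are flagged invalid and excluded from downstream
#' histograms.
#'
#' @param ms HxWx5 array of DN values.
#' @param bands band order of the third dimension.
#' @return a `gray_image`.
#' @export
gray_ndvi <- function(ms, bands = c("blue", "green", "red", "nir", "red_edge")) {
  if (length(dim(ms)) != 3L) stop("gray_ndvi: expected an HxWxB array", call. = FALSE)
  ir <- match("nir", bands); rd <- match("red", bands)
  if (is.na(ir) || is.na(rd) || dim(ms)[3] < max(ir, rd)) {
    stop("gray_ndvi: NIR and Red bands are required", call. = FALSE)
  }
  nir <- ms[, , ir]; red <- ms[, , rd]
  den <- nir + red
  valid <- den != 0
  g <- matrix(0, nrow(nir), ncol(nir))
  g[valid] <- (nir[valid] - red[valid]) / den[valid]
  structure(list(gray = g, valid = valid), class = "gray_image")
}

#' Kapur maximum-entropy threshold
#'
#' Histograms the valid pixels into `n_bins` equal-width bins over
#' `[min, max]` and returns the bin boundary that maximizes the sum of the
#' Shannon entropies of the two classes it induces:
#' `H(t) = H0 + H1`, with `H0 = -sum_{i<=t} (p_i/P0) ln(p_i/P0)` and `H1`
#' analogous for the upper class. Empty bins contribute zero (the limit
#' `x ln x -> 0`); only cuts with both classes non-empty are candidates;
#' ties break to the smallest cut. Natural logarithm throughout (the base
#' rescales the entropy but not its argmax).
#'
#' @param gray a `gray_image` (or plain numeric matrix, taken as all-valid).
#' @param n_bins number of histogram bins (>= 2).
#' @return the threshold, in gray-value units (a bin boundary).
#' @export
kapur_threshold <- function(gray, n_bins = 256L) {
  if (is.matrix(gray)) gray <- structure(list(gray = gray,
                                              valid = matrix(TRUE, nrow(gray), ncol(gray))),
                                         class = "gray_image")
  stopifnot(inherits(gray, "gray_image"), n_bins >= 2L)
  v <- gray$gray[gray$valid]
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(unique(v)) < 2L) {
    stop("kapur_threshold: image is constant, no threshold exists", call. = FALSE)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)[1:(n_bins - 1L)]
  A <- cumsum(plogp)[1:(n_bins - 1L)]
  Atot <- sum(plogp)
  ok <- P0 > 0 & P0 < 1
  H <- rep(-Inf, n_bins - 1L)
  H[ok] <- (log(P0[ok]) - A[ok] / P0[ok]) +
    (log(1 - P0[ok]) - (Atot - A[ok]) / (1 - P0[ok]))
  t_star <- which.max(H)  # ties -> smallest index
  edges[t_star + 1L]
}

#' Threshold a gray image into a plant/background mask
#'
#' @param gray a `gray_image`.
#' @param threshold cut value in gray units.
#' @param plant_is_high if `TRUE` (default), pixels above the threshold are
#'   plant; both ExG and NDVI are higher on vegetation.
#' @return a `binary_mask`: HxW 0/1 matrix, 1 = plant. Invalid gray pixels
#'   are always background.
#' @export
segment_mask <- function(gray, threshold, plant_is_high = TRUE) {
  stopifnot(inherits(gray, "gray_image"))
  stopifnot_scalar(threshold, "threshold")
  m <- if (plant_is_high) gray$gray > threshold else gray$gray < threshold
  m[!gray$valid] <- FALSE
  n1 <- sum(m); n <- length(m)
  if (n1 == 0L) stop("segmentation failed: empty plant mask", call. = FALSE)
  if (n1 == n) stop("segmentation failed: mask covers the whole image", call. = FALSE)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Apply a binary mask to an image
#'
#' Background pixels are set to `NA` (a sentinel excluded from all
#' statistics); plant pixels are unchanged.
#'
#' @param image HxW matrix or HxWxC array.
#' @param mask HxW 0/1 matrix.
#' @return masked image of the same shape.
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (!identical(d[1:2], dim(mask))) stop("apply_mask: shape mismatch", call. = FALSE)
  if (sum(mask) == 0L) stop("apply_mask: empty plant region", call. = FALSE)
  bg <- mask == 0L
  if (length(d) == 2L) {
    image[bg] <- NA_real_
  } else {
    for (ch in seq_len(d[3])) {
      plane <- image[, , ch]
      plane[bg] <- NA_real_
      image[, , ch] <- plane
    }
  }
  image
}

#' Segment one scene (both sources)
#'
#' Runs the full flow for a scene pair: ExG gray conversion and Kapur
#' thresholding for the RGB image, NDVI conversion and Kapur thresholding
#' for the multispectral image. The white reference panel is a calibration
#' object at a known location, neither plant nor natural background, so its
#' pixels are excluded from the threshold histogram and labeled background.
#'
#' @param scene a `scene_pair`.
#' @param n_bins histogram bins for the threshold search.
#' @return list with `rgb_mask` and `ms_mask` (binary masks), and the two
#'   thresholds.
#' @export
segment_scene <- function(scene, n_bins = 256L) {
  g_rgb <- gray_exg(scene$rgb)
  g_ms <- gray_ndvi(scene$ms)
  p <- scene$white_panel
  if (!is.null(p)) {
    g_rgb$valid[p[1]:p[2], p[3]:p[4]] <- FALSE
    g_ms$valid[p[1]:p[2], p[3]:p[4]] <- FALSE
  }
  t_rgb <- kapur_threshold(g_rgb, n_bins)
  t_ms <- kapur_threshold(g_ms, n_bins)
  list(rgb_mask = segment_mask(g_rgb, t_rgb),
       ms_mask = segment_mask(g_ms, t_ms),
       rgb_threshold = t_rgb, ms_threshold = t_ms)
}

#' Jaccard similarity of two binary masks
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return intersection over union.
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a == 1L & b == 1L)
  uni <- sum(a == 1L | b == 1L)
  if (uni == 0L) return(1)
  inter / uni
}
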