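#' Per-channel mean DN over the plant mask
#'
#' @param image HxWxC array (RGB: channels R, G, B; MS: the five bands) or
#'   HxW matrix.
#' @param mask HxW 0/1 matrix, 1 = plant.
#' @param channel_names optional channel names for the result.
#' @return named numeric vector of channel means, with attribute
#'   `n_pixels` (number of plant pixels used).
#' @export
mask_mean <- function(image, mask, channel_names = NULL) {
  d <- dim(image)
  if (!identical(d[1:2], dim(mask))) stop("mask_mean: shape mismatch", call. = FALSE)
  sel <- mask == 1L
  n <- sum(sel)
  if (n == 0L) stop("mask_mean: empty plant region", call. = FALSE)
  if (length(d) == 2L) {
    out <- mean(image[sel])
  } else {
    out <- vapply(seq_len(d[3]), function(ch) mean(image[, , ch][sel]), 0)
  }
  if (!is.null(channel_names)) names(out) <- channel_names
  else if (length(d) == 3L && !is.null(dimnames(image)[[3]])) {
    names(out) <- dimnames(image)[[3]]
  }
  attr(out, "n_pixels") <- n
  out
}

#' Mean DN over the white reference panel
#'
#' @param image HxW matrix or HxWxC array.
#' @param panel 1-based inclusive rectangle `c(row0, row1, col0, col1)`.
#' @inheritParams mask_mean
#' @return named vector of panel channel means.
#' @export
panel_mean <- function(image, panel, channel_names = NULL) {
  d <- dim(image)
  if (panel[1] < 1 || panel[2] > d[1] || panel[3] < 1 || panel[4] > d[2]) {
    stop("panel_mean: panel rectangle outside image bounds", call. = FALSE)
  }
  m <- matrix(0L, d[1], d[2])
  m[panel[1]:panel[2], panel[3]:panel[4]] <- 1L
  mask_mean(image, m, channel_names)
}

#' White-plate correction of channel means
#'
#' Divides plant channel means by the white-panel channel means, treating
#' the panel as reflectance 1.0. Because both numerator and denominator
#' scale linearly with scene illumination, the ratio cancels global
#' brightness differences between shade levels.
#'
#' @param plant named vector of plant channel means.
#' @param panel named vector of panel channel means (same channels).
#' @return corrected channel means (dimensionless reflectance-like values).
#' @export
white_correct <- function(plant, panel) {
  if (length(plant) != length(panel)) {
    stop("white_correct: channel count mismatch", call. = FALSE)
  }
  if (any(!is.finite(panel)) || any(panel <= 0)) {
    stop("white_correct: panel means must be positive", call. = FALSE)
  }
  out <- as.numeric(plant) / as.numeric(panel)
  names(out) <- names(plant)
  attr(out, "n_pixels") <- attr(plant, "n_pixels")
  out
}

# Evaluate one index formula, flagging invalid (non-finite) results instead
# of raising.
.idx <- function(expr) {
  v <- tryCatch(expr, error = function(e) NA_real_, warning = function(w) NA_real_)
  if (!is.finite(v)) NA_real_ else v
}

#' The ten RGB vegetation indices
#'
#' Evaluates the ten visible-light indices from white-corrected channel
#' means `R`, `G`, `B` (means first, formulas second):
#' ExG `2G-R-B`; ExGR `ExG-(1.4R-G)`; NGRDI `(G-R)/(G+R)`;
#' NGBDI `(G-B)/(G+B)`; RGRI `R/G`; GBRI `B/G`;
#' CIVE `0.441R-0.811G+0.385B+18.78745`; VEG `G/(R^0.667 * B^0.333)`;
#' RGBVI `(G^2-B*R^2)/(G^2+B*R^2)`; MGRVI `(G^2-R^2)/(G^2+R^2)`.
#' A zero denominator flags that index invalid (`NA`) rather than raising.
#' With `literature_formulas = TRUE`, RGBVI uses the common literature form
#' `(G^2 - B*R)/(G^2 + B*R)` instead of the form above.
#'
#' @param x named vector with elements `R`, `G`, `B` (corrected means).
#' @param literature_formulas use the common literature variant of RGBVI.
#' @return named numeric vector of the 10 indices, `NA` where invalid, with
#'   attribute `valid` (named logical).
#' @export
rgb_indices <- function(x, literature_formulas = FALSE) {
  R <- unname(x["R"]); G <- unname(x["G"]); B <- unname(x["B"])
  if (any(!is.finite(c(R, G, B)))) stop("rgb_indices: R, G, B means required", call. = FALSE)
  exg <- 2 * G - R - B
  out <- c(
    ExG = exg,
    ExGR = exg - (1.4 * R - G),
    NGRDI = .idx((G - R) / (G + R)),
    NGBDI = .idx((G - B) / (G + B)),
    RGRI = .idx(R / G),
    GBRI = .idx(B / G),
    CIVE = 0.441 * R - 0.811 * G + 0.385 * B + 18.78745,
    VEG = .idx(if (R <= 0 || B <= 0) NA_real_ else G / (R^0.667 * B^0.333)),
    RGBVI = if (literature_formulas) .idx((G^2 - B * R) / (G^2 + B * R))
            else .idx((G^2 - B * R^2) / (G^2 + B * R^2)),
    MGRVI = .idx((G^2 - R^2) / (G^2 + R^2))
  )
  attr(out, "valid") <- stats::setNames(is.finite(out), names(out))
  out
}

#' The ten multispectral vegetation indices
#'
#' Evaluates the ten narrowband indices from white-corrected band means:
#' NDVI `(NIR-Red)/(NIR+Red)`; RVI `NIR/Red`; DVI `NIR-Red`;
#' EVI `2.5(NIR-Red)/(NIR+6Red-7.5Blue+1)`; RDVI `(NDVI/DVI)^0.5`;
#' REVI `NIR/RE-1`; NDRE `(NIR-RE)/(NIR+RE)`; RERVI `NIR/RE`;
#' REDVI `NIR-RE`; sCCCI `NDRE/NDVI`. Zero denominators or a negative
#' radicand flag the index invalid (`NA`). With
#' `literature_formulas = TRUE`, RDVI uses the common literature form
#' `(NIR-Red)/sqrt(NIR+Red)` instead.
#'
#' Note the exact affine identity `RERVI = REVI + 1`: any feature set
#' containing both is perfectly collinear, which the screening stage must
#' detect and resolve.
#'
#' @param x named vector with elements `blue`, `green`, `red`, `nir`,
#'   `red_edge` (corrected means).
#' @param literature_formulas use the common literature variant of RDVI.
#' @return named numeric vector of the 10 indices with attribute `valid`.
#' @export
ms_indices <- function(x, literature_formulas = FALSE) {
  NIR <- unname(x["nir"]); Red <- unname(x["red"])
  Blue <- unname(x["blue"]); RE <- unname(x["red_edge"])
  if (any(!is.finite(c(NIR, Red, Blue, RE)))) {
    stop("ms_indices: blue, red, nir, red_edge means required", call. = FALSE)
  }
  ndvi <- .idx((NIR - Red) / (NIR + Red))
  dvi <- NIR - Red
  ndre <- .idx((NIR - RE) / (NIR + RE))
  out <- c(
    NDVI = ndvi,
    RVI = .idx(NIR / Red),
    DVI = dvi,
    EVI = .idx(2.5 * (NIR - Red) / (NIR + 6 * Red - 7.5 * Blue + 1)),
    RDVI = if (literature_formulas) .idx((NIR - Red) / sqrt(NIR + Red))
           else .idx(if (!is.finite(ndvi) || dvi == 0 || ndvi / dvi < 0) NA_real_
                     else sqrt(ndvi / dvi)),
    REVI = .idx(NIR / RE - 1),
    NDRE = ndre,
    RERVI = .idx(NIR / RE),
    REDVI = NIR - RE,
    sCCCI = .idx(if (!is.finite(ndvi) || ndvi == 0) NA_real_ else ndre / ndvi)
  )
  attr(out, "valid") <- stats::setNames(is.finite(out), names(out))
  out
}

#' Extract the per-seedling feature table from a dataset
#'
#' Full extraction flow per scene: segment (ExG/Kapur for RGB, NDVI/Kapur
#' for MS), average DN over the plant mask, white-plate-correct against the
#' panel, and evaluate the ten RGB and ten MS indices.
#'
#' @param ds a `canopy_dataset`.
#' @param n_bins histogram bins for thresholding.
#' @param literature_formulas passed to [rgb_indices()] / [ms_indices()].
#' @return data frame: `id`, `shade`, `spad_measured`, the 10 RGB and 10 MS
#'   index columns, plus `n_valid` (count of valid indices in the row).
#' @export
extract_features <- function(ds, n_bins = 256L, literature_formulas = FALSE) {
  stopifnot(inherits(ds, "canopy_dataset"))
  rows <- lapply(ds$records$id, function(id) {
    sc <- ds$scenes[[id]]
    seg <- segment_scene(sc, n_bins)
    rgb_plant <- mask_mean(sc$rgb, seg$rgb_mask, c("R", "G", "B"))
    rgb_panel <- panel_mean(sc$rgb, sc$white_panel, c("R", "G", "B"))
    ms_plant <- mask_mean(sc$ms, seg$ms_mask)
    ms_panel <- panel_mean(sc$ms, sc$white_panel)
    vi_rgb <- rgb_indices(white_correct(rgb_plant, rgb_panel), literature_formulas)
    vi_ms <- ms_indices(white_correct(ms_plant, ms_panel), literature_formulas)
    c(vi_rgb, vi_ms)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  out <- cbind(ds$records[c("id", "shade", "spad_measured")], feat)
  out$n_valid <- rowSums(is.finite(as.matrix(feat)))
  rownames(out) <- NULL
  out
}

#' Feature table from simulated band means (no rendering)
#'
#' Companion to [simulate_band_means()]: evaluates both index sets directly
#' on simulated corrected band means. The RGB channel means are taken from
#' the red/green/blue bands of the optical model.
#'
#' @param bm output of [simulate_band_means()].
#' @param literature_formulas passed to the index functions.
#' @return same layout as [extract_features()].
#' @export
features_from_band_means <- function(bm, literature_formulas = FALSE) {
  rows <- lapply(seq_len(nrow(bm)), function(i) {
    rgb <- c(R = bm$red[i], G = bm$green[i], B = bm$blue[i])
    ms <- c(blue = bm$blue[i], green = bm$green[i], red = bm$red[i],
            nir = bm$nir[i], red_edge = bm$red_edge[i])
    c(rgb_indices(rgb, literature_formulas), ms_indices(ms, literature_formulas))
  })
  feat <- as.data.frame(do.call(rbind, rows))
  out <- cbind(bm[c("id", "shade", "spad_measured")], feat)
  out$n_valid <- rowSums(is.finite(as.matrix(feat)))
  rownames(out) <- NULL
  out
}

#' Names of the two index sets
#'
#' @return list with elements `rgb` and `ms`.
#' @export
index_names <- function() {
  list(rgb = c("ExG", "ExGR", "NGRDI", "NGBDI", "RGRI", "GBRI", "CIVE",
               "VEG", "RGBVI", "MGRVI"),
       ms = c("NDVI", "RVI", "DVI", "EVI", "RDVI", "REVI", "NDRE",
              "RERVI", "REDVI", "sCCCI"))
}
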