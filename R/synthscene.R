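#' Shade experiment configuration
#'
#' Describes a shaded seedling trial: the shade levels (fraction of incident
#' light blocked by netting), the SPAD distribution of seedlings grown under
#' each level, the number of seedlings per level, and the relative scene
#' illumination under each net. Defaults emulate a four-level trial
#' (0/25/50/75 % shade, 50 seedlings per level) in which chlorophyll peaks at
#' intermediate shade: per-level mean SPAD 18.39, 25.76, 31.81 and 29.26.
#' The within-level standard deviation (3.6 SPAD) is chosen so that the
#' one-way ANOVA F statistic across levels lands in the low hundreds, the
#' magnitude typical of such trials.
#'
#' @param levels strictly increasing shade fractions in `[0, 1)`.
#' @param mean_spad per-level mean SPAD (unitless meter reading).
#' @param sd_spad per-level SPAD standard deviation; recycled if scalar.
#' @param n_per_level seedlings per shade level.
#' @param illumination per-level scene illumination scale in `(0, 1]`,
#'   non-increasing with shade fraction. Denser netting means darker scenes,
#'   which is what white-plate correction must cancel.
#' @return an object of class `shade_config`.
#' @export
#' @examples
#' cfg <- shade_config(n_per_level = 5)
#' cfg$mean_spad
shade_config <- function(levels = c(0, 0.25, 0.50, 0.75),
                         mean_spad = c(18.39, 25.76, 31.81, 29.26),
                         sd_spad = 3.6,
                         n_per_level = 50,
                         illumination = c(1.0, 0.75, 0.5, 0.25)) {
  k <- length(levels)
  sd_spad <- rep_len(sd_spad, k)
  if (!all(is.finite(c(levels, mean_spad, sd_spad, n_per_level, illumination)))) {
    stop("shade_config: all values must be finite", call. = FALSE)
  }
  if (k < 1L || length(mean_spad) != k || length(illumination) != k) {
    stop("shade_config: levels, mean_spad and illumination must have equal length",
         call. = FALSE)
  }
  if (any(diff(levels) <= 0) || any(levels < 0) || any(levels >= 1)) {
    stop("shade_config: levels must be strictly increasing within [0, 1)", call. = FALSE)
  }
  if (any(sd_spad < 0)) stop("shade_config: sd_spad must be >= 0", call. = FALSE)
  if (n_per_level < 1) stop("shade_config: n_per_level must be >= 1", call. = FALSE)
  if (any(illumination <= 0) || any(illumination > 1) || any(diff(illumination) > 0)) {
    stop("shade_config: illumination must lie in (0, 1] and be non-increasing with shade",
         call. = FALSE)
  }
  structure(list(levels = levels, mean_spad = mean_spad, sd_spad = sd_spad,
                 n_per_level = as.integer(n_per_level), illumination = illumination),
            class = "shade_config")
}

#' Sample a seedling population under a shade configuration
#'
#' Draws per-seedling true SPAD from a normal distribution per shade level,
#' truncated below at 5 (SPAD meters do not read healthy leaves lower), and
#' simulates the field protocol of averaging the meter reading over three
#' randomly chosen leaves: each leaf reading is the true value plus
#' independent meter noise.
#'
#' @param cfg a [shade_config()].
#' @param noise_sd per-leaf SPAD meter noise standard deviation (SPAD units).
#' @param seed integer seed; the same seed reproduces the population exactly.
#' @param n_leaves leaves averaged per seedling (field protocol uses 3).
#' @return data frame with columns `id`, `shade`, `spad_true`, `spad_measured`.
#' @export
sample_population <- function(cfg, noise_sd = 1.0, seed = 1L, n_leaves = 3L) {
  stopifnot(inherits(cfg, "shade_config"))
  stopifnot_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    out <- lapply(seq_along(cfg$levels), function(l) {
      n <- cfg$n_per_level
      spad <- stats::rnorm(n, cfg$mean_spad[l], cfg$sd_spad[l])
      while (any(spad < 5)) {
        bad <- spad < 5
        spad[bad] <- stats::rnorm(sum(bad), cfg$mean_spad[l], cfg$sd_spad[l])
      }
      leaf <- matrix(spad, n, n_leaves) +
        matrix(stats::rnorm(n * n_leaves, 0, noise_sd), n, n_leaves)
      data.frame(
        id = sprintf("L%02.0f_%03d", 100 * cfg$levels[l], seq_len(n)),
        shade = cfg$levels[l],
        spad_true = spad,
        spad_measured = rowMeans(leaf),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}

#' Leaf and soil spectral model
#'
#' A five-band (blue, green, red, NIR, red edge) reflectance model linking
#' chlorophyll to leaf optics through Beer–Lambert-like exponential decay:
#' `reflectance = baseline * exp(-k * SPAD) + floor`. Chlorophyll absorbs
#' strongly in red, moderately in green/blue, weakly on the red edge and not
#' at all in the NIR plateau, so the sensitivity coefficients must satisfy
#' `k_red > k_green > k_red_edge > k_nir >= 0`. Soil reflectance is flat-ish
#' and chlorophyll-independent. Band centers follow a typical narrowband
#' five-sensor camera (blue 475, green 560, red 668, NIR 840, red edge
#' 717 nm).
#'
#' @param baseline per-band decaying component amplitude.
#' @param k per-band chlorophyll sensitivity (1/SPAD).
#' @param floor_refl per-band chlorophyll-independent reflectance floor.
#' @param soil per-band soil background reflectance.
#' @return an object of class `spectral_model`.
#' @export
spectral_model <- function(
    baseline   = c(blue = 0.20, green = 0.35, red = 0.30, nir = 0.05, red_edge = 0.35),
    k          = c(blue = 0.030, green = 0.020, red = 0.035, nir = 0.000, red_edge = 0.012),
    floor_refl = c(blue = 0.03, green = 0.06, red = 0.03, nir = 0.80, red_edge = 0.18),
    soil       = c(blue = 0.10, green = 0.15, red = 0.22, nir = 0.26, red_edge = 0.24)) {
  bands <- c("blue", "green", "red", "nir", "red_edge")
  for (v in list(baseline, k, floor_refl, soil)) {
    if (!all(bands %in% names(v))) stop("spectral_model: all five bands required", call. = FALSE)
  }
  baseline <- baseline[bands]; k <- k[bands]
  floor_refl <- floor_refl[bands]; soil <- soil[bands]
  if (any(k < 0)) stop("spectral_model: k must be >= 0", call. = FALSE)
  if (!(k["red"] > k["green"] && k["green"] > k["red_edge"] && k["red_edge"] > k["nir"])) {
    stop("spectral_model: require k_red > k_green > k_red_edge > k_nir", call. = FALSE)
  }
  refl_range <- c(baseline * exp(-outer(k, c(5, 60))) + floor_refl)
  if (any(refl_range <= 0) || any(refl_range >= 1)) {
    stop("spectral_model: leaf reflectance must stay inside (0, 1) for SPAD in [5, 60]",
         call. = FALSE)
  }
  if (any(soil <= 0) || any(soil >= 1)) {
    stop("spectral_model: soil reflectance must lie in (0, 1)", call. = FALSE)
  }
  structure(list(baseline = baseline, k = k, floor_refl = floor_refl,
                 soil = soil, bands = bands),
            class = "spectral_model")
}

#' Leaf reflectance at a given SPAD value
#'
#' @param spad SPAD value(s), > 0.
#' @param model a [spectral_model()].
#' @param band one of `"blue"`, `"green"`, `"red"`, `"nir"`, `"red_edge"`.
#' @return reflectance in (0, 1), vectorized over `spad`.
#' @export
leaf_reflectance <- function(spad, model = spectral_model(), band) {
  stopifnot(inherits(model, "spectral_model"))
  if (length(band) != 1L || !band %in% model$bands) {
    stop(sprintf("unknown band '%s'", paste(band, collapse = ",")), call. = FALSE)
  }
  if (any(!is.finite(spad)) || any(spad <= 0)) stop("spad must be > 0", call. = FALSE)
  r <- model$baseline[[band]] * exp(-model$k[[band]] * spad) + model$floor_refl[[band]]
  pmin(pmax(r, 1e-4), 1 - 1e-4)
}

# Quantize radiance in [0,1] to an integer DN at the given bit depth.
# Rounds to the nearest level (as a camera ADC does); truncation would leave
# a half-step bias that does not cancel in the white-plate ratio at low
# illumination.
quantize_dn <- function(radiance, bits) {
  depth <- 2^bits - 1
  pmin(pmax(floor(radiance * depth + 0.5), 0), depth)
}

#' Render a synthetic canopy scene for one seedling
#'
#' Builds a co-registered RGB (8-bit) and five-band multispectral (16-bit)
#' image pair of a single seedling photographed from above: elliptical leaf
#' blobs on a soil background, plus a white reference panel in the top-left
#' corner. Plant pixels carry the leaf reflectance implied by the seedling's
#' true SPAD, modulated by a per-seedling band factor (individual optical
#' variation, lognormal sd `seedling_sd`) and per-pixel texture noise.
#' Texture has two parts: a brightness field shared across bands (surface
#' roughness and micro-shading modulate all bands together) and a smaller
#' independent per-band component. All radiance is scaled by the shade
#' level's illumination before DN quantization; the RGB bands carry
#' additional broader-bandwidth noise before 8-bit quantization.
#'
#' @param record one row of a [sample_population()] data frame.
#' @param model a [spectral_model()].
#' @param cfg the [shade_config()] the record was drawn under.
#' @param geometry_seed integer seed controlling layout and noise.
#' @param width,height scene size in pixels.
#' @param panel_size side length of the square white panel (pixels).
#' @param panel_reflectance reflectance of the reference panel (real panels
#'   sit a little below 1; keeping headroom avoids sensor clipping).
#' @param seedling_sd lognormal sd of the per-seedling band factor.
#' @param texture_sd lognormal sd of the shared per-pixel brightness texture.
#' @param band_texture_sd lognormal sd of the independent per-band texture.
#' @param canopy_texture_sd lognormal sd of extra NIR/red-edge texture on
#'   plant pixels; leaf internal structure (the main driver of NIR
#'   scattering) varies strongly across a canopy, spreading the vegetation
#'   mode of the NDVI histogram the way real canopy images do.
#' @param rgb_noise_sd extra lognormal sd on the RGB bands (broader
#'   effective bandwidth of a consumer camera).
#' @return an object of class `scene_pair`: list with `rgb` (HxWx3, DN),
#'   `ms` (HxWx5, DN, bands blue/green/red/nir/red_edge), `white_panel`
#'   (1-based inclusive `c(row0, row1, col0, col1)`), `truth_mask` (HxW 0/1),
#'   `record`, `illumination`.
#' @export
render_scene <- function(record, model = spectral_model(), cfg = shade_config(),
                         geometry_seed = 1L, width = 96L, height = 96L,
                         panel_size = 14L, panel_reflectance = 0.95,
                         seedling_sd = 0.10, texture_sd = 0.05,
                         band_texture_sd = 0.03, canopy_texture_sd = 0.20,
                         rgb_noise_sd = 0.08) {
  stopifnot(inherits(model, "spectral_model"), inherits(cfg, "shade_config"))
  li <- match(record$shade, cfg$levels)
  if (is.na(li)) stop("record shade level not present in config", call. = FALSE)
  illum <- cfg$illumination[li]
  h <- as.integer(height); w <- as.integer(width); ps <- as.integer(panel_size)
  if (h < 3L * ps || w < 3L * ps) {
    stop("scene too small to hold the white panel and a plant", call. = FALSE)
  }
  panel <- c(2L, 1L + ps, 2L, 1L + ps)  # row0,row1,col0,col1 (1-based inclusive)

  with_seed(geometry_seed, {
    # --- plant geometry: union of elliptical leaf blobs around the center
    # the scene emulates a region-of-interest crop centered on one seedling,
    # so the canopy dominates the frame
    n_leaves <- sample(6:8, 1L)
    rr <- matrix(rep(seq_len(h), w), h, w)
    cc <- matrix(rep(seq_len(w), each = h), h, w)
    mask <- matrix(FALSE, h, w)
    cy0 <- h * 0.60; cx0 <- w * 0.52  # keep clear of the panel corner
    span <- min(h, w)
    for (i in seq_len(n_leaves)) {
      cy <- cy0 + stats::runif(1, -0.13, 0.13) * span
      cx <- cx0 + stats::runif(1, -0.15, 0.15) * span
      a <- stats::runif(1, 0.20, 0.33) * span
      b <- stats::runif(1, 0.55, 0.95) * a
      th <- stats::runif(1, 0, pi)
      dx <- (cc - cx) * cos(th) + (rr - cy) * sin(th)
      dy <- -(cc - cx) * sin(th) + (rr - cy) * cos(th)
      mask <- mask | ((dx / a)^2 + (dy / b)^2 <= 1)
    }
    mask[panel[1]:panel[2], panel[3]:panel[4]] <- FALSE

    # --- reflectance fields (independent of illumination, so the same seed
    #     at two illumination scales differs only by scaling + quantization)
    band_factor <- exp(stats::rnorm(5, 0, seedling_sd))
    names(band_factor) <- model$bands
    brightness <- exp(matrix(stats::rnorm(h * w, 0, texture_sd), h, w))
    refl <- array(0, dim = c(h, w, 5), dimnames = list(NULL, NULL, model$bands))
    for (b in model$bands) {
      f <- matrix(model$soil[[b]], h, w)
      f[mask] <- leaf_reflectance(record$spad_true, model, b) * band_factor[[b]]
      f[panel[1]:panel[2], panel[3]:panel[4]] <- panel_reflectance
      f <- f * brightness * exp(matrix(stats::rnorm(h * w, 0, band_texture_sd), h, w))
      if (b %in% c("nir", "red_edge")) {
        f[mask] <- f[mask] * exp(stats::rnorm(sum(mask), 0, canopy_texture_sd))
      }
      refl[, , b] <- pmin(pmax(f, 1e-4), 1)
    }
    rgb_refl <- refl[, , c("red", "green", "blue")]
    rgb_refl <- rgb_refl * exp(array(stats::rnorm(h * w * 3, 0, rgb_noise_sd),
                                     dim = c(h, w, 3)))
    rgb_refl <- pmin(pmax(rgb_refl, 1e-4), 1)

    ms <- quantize_dn(refl * illum, 16L)
    rgb <- quantize_dn(rgb_refl * illum, 8L)

    structure(list(rgb = rgb, ms = ms, white_panel = panel,
                   truth_mask = matrix(as.integer(mask), h, w),
                   record = record, illumination = illum),
              class = "scene_pair")
  })
}

#' Generate a full synthetic dataset in memory
#'
#' Samples a population under `cfg` and renders one scene per seedling,
#' deriving an independent sub-seed per scene from the master seed.
#'
#' @inheritParams sample_population
#' @inheritParams render_scene
#' @param ... further arguments passed to [render_scene()].
#' @return an object of class `canopy_dataset`: list with `records`,
#'   `scenes` (list of `scene_pair`), `cfg`, `model`, `seed`.
#' @export
synth_dataset <- function(cfg = shade_config(), model = spectral_model(),
                          noise_sd = 1.0, seed = 1L, ...) {
  records <- sample_population(cfg, noise_sd = noise_sd, seed = seed)
  scene_seeds <- derive_seeds(seed + 1L, nrow(records))
  scenes <- lapply(seq_len(nrow(records)), function(i) {
    render_scene(records[i, ], model, cfg, geometry_seed = scene_seeds[i], ...)
  })
  names(scenes) <- records$id
  structure(list(records = records, scenes = scenes, cfg = cfg,
                 model = model, seed = as.integer(seed)),
            class = "canopy_dataset")
}

#' Simulate corrected band means without rendering images
#'
#' Analytic fast path through the optical model: per seedling, the
#' white-plate-corrected band mean equals the leaf reflectance at its true
#' SPAD times a per-seedling lognormal band factor (individual optical
#' variation). Used for model-level simulation studies where rendering and
#' re-segmenting full scenes would only add the segmentation stage's (already
#' separately tested) noise.
#'
#' @inheritParams sample_population
#' @param model a [spectral_model()].
#' @param seedling_sd lognormal sd of the per-seedling band factor.
#' @return data frame: `id`, `shade`, `spad_measured`, corrected means
#'   `blue`, `green`, `red`, `nir`, `red_edge`.
#' @export
simulate_band_means <- function(cfg = shade_config(), model = spectral_model(),
                                noise_sd = 1.0, seedling_sd = 0.10, seed = 1L) {
  records <- sample_population(cfg, noise_sd = noise_sd, seed = seed)
  n <- nrow(records)
  with_seed(seed + 1L, {
    fac <- matrix(exp(stats::rnorm(n * 5, 0, seedling_sd)), n, 5)
    bands <- vapply(seq_along(model$bands), function(j) {
      leaf_reflectance(records$spad_true, model, model$bands[j]) * fac[, j]
    }, numeric(n))
    colnames(bands) <- model$bands
    cbind(records[c("id", "shade", "spad_measured")], as.data.frame(bands))
  })
}

#' Write a synthetic dataset to disk
#'
#' RGB scenes as 8-bit PNG, multispectral scenes as 5-page 16-bit TIFF (one
#' band per page, order blue/green/red/nir/red_edge), truth masks as 0/255
#' PNG, records as CSV and a manifest JSON mapping ids to files and panel
#' coordinates (0-based, row-major, half-open rectangles).
#'
#' @param ds a [synth_dataset()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, force = FALSE) {
  stopifnot(inherits(ds, "canopy_dataset"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rgb"), showWarnings = FALSE)
  dir.create(file.path(dir, "ms"), showWarnings = FALSE)
  dir.create(file.path(dir, "mask"), showWarnings = FALSE)
  entries <- lapply(ds$records$id, function(id) {
    sc <- ds$scenes[[id]]
    rgb_path <- file.path("rgb", paste0(id, ".png"))
    ms_path <- file.path("ms", paste0(id, ".tif"))
    mask_path <- file.path("mask", paste0(id, ".png"))
    png::writePNG(sc$rgb / 255, file.path(dir, rgb_path))
    tiff::writeTIFF(lapply(1:5, function(b) sc$ms[, , b] / 65535),
                    file.path(dir, ms_path), bits.per.sample = 16L)
    png::writePNG(sc$truth_mask + 0, file.path(dir, mask_path))
    p <- sc$white_panel
    list(id = id, rgb = rgb_path, ms = ms_path, mask = mask_path,
         # 0-based half-open [row0, row1) x [col0, col1)
         panel = c(p[1] - 1L, p[2], p[3] - 1L, p[4]),
         illumination = sc$illumination)
  })
  utils::write.csv(ds$records, file.path(dir, "records.csv"), row.names = FALSE)
  manifest <- list(
    band_order = ds$model$bands,
    rgb_bits = 8L, ms_bits = 16L,
    shade_levels = ds$cfg$levels,
    seed = ds$seed,
    scenes = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return a `canopy_dataset` (without `cfg`/`model`, which are not stored).
#' @export
read_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  records <- utils::read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  scenes <- lapply(seq_len(nrow(mf$scenes)), function(i) {
    e <- mf$scenes[i, ]
    rgb <- round(png::readPNG(file.path(dir, e$rgb)) * 255)
    pages <- tiff::readTIFF(file.path(dir, e$ms), all = TRUE)
    ms <- array(0, dim = c(dim(pages[[1]]), 5),
                dimnames = list(NULL, NULL, mf$band_order))
    for (b in 1:5) ms[, , b] <- round(pages[[b]] * 65535)
    mask <- round(png::readPNG(file.path(dir, e$mask)))
    p <- unlist(e$panel)
    structure(list(rgb = rgb, ms = ms,
                   white_panel = c(p[1] + 1L, p[2], p[3] + 1L, p[4]),
                   truth_mask = mask,
                   record = records[records$id == e$id, ],
                   illumination = e$illumination),
              class = "scene_pair")
  })
  names(scenes) <- mf$scenes$id
  structure(list(records = records, scenes = scenes, cfg = NULL, model = NULL,
                 seed = mf$seed),
            class = "canopy_dataset")
}
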