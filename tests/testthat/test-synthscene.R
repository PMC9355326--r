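test_that("population sampling honors configured moments, truncation and determinism", {
  cfg <- shade_config()  # 4 x 50 defaults
  pop <- sample_population(cfg, noise_sd = 1, seed = 7)
  expect_equal(nrow(pop), 200L)
  expect_equal(as.numeric(table(pop$shade)), rep(50, 4))
  means <- tapply(pop$spad_true, pop$shade, mean)
  # CLT band: 3 * sd / sqrt(n) around each configured mean
  expect_true(all(abs(means - cfg$mean_spad) < 3 * cfg$sd_spad / sqrt(50)))

  # degenerate noise: everything collapses onto the configured means
  cfg0 <- shade_config(sd_spad = 0, n_per_level = 5)
  pop0 <- sample_population(cfg0, noise_sd = 0, seed = 1)
  expect_equal(pop0$spad_true, rep(cfg0$mean_spad, each = 5))
  expect_equal(pop0$spad_measured, pop0$spad_true)

  # truncation keeps SPAD physical
  cfg_low <- shade_config(levels = 0, mean_spad = 6, sd_spad = 3,
                          n_per_level = 200, illumination = 1)
  expect_true(all(sample_population(cfg_low, seed = 3)$spad_true >= 5))

  expect_identical(sample_population(cfg, seed = 42),
                   sample_population(cfg, seed = 42))
})

test_that("configuration invariants are enforced", {
  expect_error(shade_config(levels = c(0.5, 0.25), mean_spad = c(20, 25),
                            illumination = c(1, 0.8)), "increasing")
  expect_error(shade_config(sd_spad = -1), "sd_spad")
  expect_error(shade_config(illumination = c(0.25, 0.5, 0.75, 1.0)),
               "non-increasing")
  expect_error(shade_config(mean_spad = c(1, NA, 3, 4)), "finite")
  expect_error(spectral_model(k = c(blue = 0.03, green = 0.04, red = 0.035,
                                    nir = 0, red_edge = 0.012)),
               "k_red > k_green")
})

test_that("leaf reflectance follows the chlorophyll-absorption model", {
  m <- spectral_model()
  # zero sensitivity: NIR plateau is flat in SPAD
  expect_equal(leaf_reflectance(10, m, "nir"), leaf_reflectance(50, m, "nir"))
  # red absorption: strictly decreasing in SPAD
  spads <- seq(5, 60, by = 5)
  expect_true(all(diff(leaf_reflectance(spads, m, "red")) < 0))
  # every band stays a valid reflectance over the working range
  for (b in m$bands) {
    r <- leaf_reflectance(spads, m, b)
    expect_true(all(r > 0 & r < 1))
  }
  # a healthy leaf is NDVI-positive under the default model
  ndvi <- (leaf_reflectance(30, m, "nir") - leaf_reflectance(30, m, "red")) /
    (leaf_reflectance(30, m, "nir") + leaf_reflectance(30, m, "red"))
  expect_gt(ndvi, 0)
  expect_error(leaf_reflectance(30, m, "uv"), "unknown band")
  expect_error(leaf_reflectance(-2, m, "red"), "spad")
})

test_that("rendered scenes obey the linear light model", {
  rec <- sample_population(shade_config(levels = 0, mean_spad = 26, sd_spad = 0,
                                        n_per_level = 1, illumination = 1),
                           noise_sd = 0, seed = 1)
  cfg_full <- shade_config(levels = 0, mean_spad = 26, sd_spad = 0,
                           n_per_level = 1, illumination = 1.0)
  cfg_half <- shade_config(levels = 0, mean_spad = 26, sd_spad = 0,
                           n_per_level = 1, illumination = 0.5)
  sc1 <- render_scene(rec, cfg = cfg_full, geometry_seed = 5)
  sc2 <- render_scene(rec, cfg = cfg_half, geometry_seed = 5)
  # same seed, same reflectance field: halving the light halves every DN up
  # to one quantization step, including the white panel
  expect_identical(sc1$truth_mask, sc2$truth_mask)
  expect_lt(max(abs(sc2$ms - sc1$ms / 2)), 1)
  expect_lt(max(abs(sc2$rgb - sc1$rgb / 2)), 1)
  p <- sc1$white_panel
  expect_equal(mean(sc2$ms[p[1]:p[2], p[3]:p[4], "nir"]) /
                 mean(sc1$ms[p[1]:p[2], p[3]:p[4], "nir"]), 0.5,
               tolerance = 1e-3)
})

test_that("scene rendering is deterministic and geometrically sane", {
  cfg <- small_cfg()
  pop <- sample_population(cfg, seed = 9)
  sc_a <- render_scene(pop[1, ], cfg = cfg, geometry_seed = 3)
  sc_b <- render_scene(pop[1, ], cfg = cfg, geometry_seed = 3)
  expect_identical(sc_a, sc_b)

  fracs <- vapply(1:6, function(s) {
    mean(render_scene(pop[s, ], cfg = cfg, geometry_seed = 50 + s)$truth_mask)
  }, 0)
  expect_true(all(fracs > 0.05 & fracs < 0.8))

  expect_true(all(sc_a$rgb >= 0 & sc_a$rgb <= 255))
  expect_true(all(sc_a$ms >= 0 & sc_a$ms <= 65535))
  # panel disjoint from plant
  p <- sc_a$white_panel
  expect_equal(sum(sc_a$truth_mask[p[1]:p[2], p[3]:p[4]]), 0L)
  expect_error(render_scene(pop[1, ], cfg = cfg, geometry_seed = 1,
                            width = 20, height = 20), "too small")
})

test_that("datasets round-trip through PNG/TIFF/CSV/manifest on disk", {
  ds <- small_dataset()
  dir1 <- file.path(tempdir(), "ds1")
  unlink(dir1, recursive = TRUE)
  write_dataset(ds, dir1)
  expect_error(write_dataset(ds, dir1), "force")

  back <- read_dataset(dir1)
  id <- ds$records$id[5]
  expect_equal(back$scenes[[id]]$ms, ds$scenes[[id]]$ms,
               ignore_attr = TRUE)
  expect_equal(back$scenes[[id]]$rgb, ds$scenes[[id]]$rgb,
               ignore_attr = TRUE)
  expect_equal(back$scenes[[id]]$truth_mask, ds$scenes[[id]]$truth_mask,
               ignore_attr = TRUE)
  expect_equal(back$scenes[[id]]$white_panel, ds$scenes[[id]]$white_panel,
               ignore_attr = TRUE)
  expect_equal(back$records$spad_measured, ds$records$spad_measured,
               tolerance = 1e-10)

  # regenerating and rewriting with the same seed gives identical manifests
  dir2 <- file.path(tempdir(), "ds2")
  unlink(dir2, recursive = TRUE)
  ds2 <- synth_dataset(small_cfg(), seed = 101L, width = 64L, height = 64L)
  write_dataset(ds2, dir2)
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("simulated band means track the chlorophyll-reflectance link", {
  bm <- simulate_band_means(shade_config(), seed = 21)
  expect_equal(nrow(bm), 200L)
  # ordering against measured SPAD mirrors the optical model's signs
  expect_lt(cor(bm$red, bm$spad_measured), 0)
  expect_lt(cor(bm$green, bm$spad_measured), 0)
  expect_identical(simulate_band_means(shade_config(), seed = 5),
                   simulate_band_means(shade_config(), seed = 5))
})
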