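test_that("default grid arithmetic covers 4000-400 inclusive", {
  g2 <- default_grid(2)
  expect_length(g2, 1801)
  expect_equal(g2[1], 4000)
  expect_equal(g2[length(g2)], 400)
  expect_equal(default_grid(1800), c(4000, 2200, 400))
  expect_error(default_grid(0), "positive")
  expect_error(default_grid(-4), "positive")
})

test_that("noise-free single-band spectrum is a pure Gaussian with unit peak", {
  bands <- data.frame(center = 2928, width = 20, base_intensity = 1,
                      d_B_edulis = 1, d_L_rugosiceps = 1,
                      d_B_tomentipes = 1, d_B_umbriniporus = 1,
                      d_cap = 1, d_stipe = 1)
  cfg <- synthetic_config(bands = bands, noise_sd = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, baseline_amp = 0,
                          phenol_link_slope = 1e9)  # phenol band negligible
  y <- generate_spectrum(cfg, "B_edulis", "cap", content = 1, substream = 5)
  grid <- cfg$grid
  nearest <- which.min(abs(grid - 2928))
  expect_equal(y[nearest], max(y))
  expect_equal(y[nearest], 1, tolerance = 1e-9)
  expect_equal(y, exp(-(grid - 2928)^2 / (2 * 20^2)) +
                 1e-9 * exp(-(grid - cfg$phenol_band_center)^2 /
                              (2 * cfg$phenol_band_width^2)),
               tolerance = 1e-12)
})

test_that("spectra are deterministic given the substream and config seed", {
  cfg <- small_config(seed = 4)
  s1 <- generate_spectrum(cfg, "B_tomentipes", "stipe", 12, substream = 7)
  s2 <- generate_spectrum(cfg, "B_tomentipes", "stipe", 12, substream = 7)
  expect_identical(s1, s2)
  s3 <- generate_spectrum(cfg, "B_tomentipes", "stipe", 12, substream = 8)
  expect_false(identical(s1, s3))
})

test_that("with all noise scales zero, spectra depend only on (species, part, content)", {
  cfg <- small_config(noise_sd = 0, scatter_slope_sd = 0,
                      scatter_offset_sd = 0, baseline_amp = 0)
  a <- generate_spectrum(cfg, "L_rugosiceps", "cap", 14, substream = 1)
  b <- generate_spectrum(cfg, "L_rugosiceps", "cap", 14, substream = 99)
  expect_identical(a, b)
})

test_that("additive noise has the configured scale in a flat region", {
  bands <- data.frame(center = 2928, width = 20, base_intensity = 1,
                      d_B_edulis = 1, d_L_rugosiceps = 1,
                      d_B_tomentipes = 1, d_B_umbriniporus = 1,
                      d_cap = 1, d_stipe = 1)
  cfg <- synthetic_config(bands = bands, grid_step = 16, noise_sd = 0.01,
                          scatter_slope_sd = 0, scatter_offset_sd = 0,
                          baseline_amp = 0, phenol_link_slope = 1e9)
  flat <- which.min(abs(cfg$grid - 2200))   # far from every band
  vals <- vapply(1:1000, function(i) {
    generate_spectrum(cfg, "B_edulis", "cap", 1, substream = i)[flat]
  }, numeric(1))
  expect_gt(sd(vals), 0.008)
  expect_lt(sd(vals), 0.012)
})

test_that("phenol band height is an exact affine function of content when noise is off", {
  ## step 5 puts the phenol band centre (1515) exactly on a grid point
  cfg <- synthetic_config(grid_step = 5, noise_sd = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, baseline_amp = 0)
  idx <- which.min(abs(cfg$grid - cfg$phenol_band_center))
  y1 <- generate_spectrum(cfg, "B_edulis", "cap", 10, substream = 1)
  y2 <- generate_spectrum(cfg, "B_edulis", "cap", 20, substream = 1)
  y3 <- generate_spectrum(cfg, "B_edulis", "cap", 15, substream = 1)
  ## linearity: midpoint content gives midpoint spectrum
  expect_equal(y3, (y1 + y2) / 2, tolerance = 1e-12)
  ## slope at the band centre matches the configured link
  expect_equal(y2[idx] - y1[idx], 10 / cfg$phenol_link_slope,
               tolerance = 1e-12)
})

test_that("generated datasets are reproducible and balanced", {
  cfg <- small_config(seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$caps$absorbance, d2$caps$absorbance)
  expect_identical(d1$contents, d2$contents)
  expect_equal(unname(table(d1$caps$meta$species)), rep(6L, 4),
               ignore_attr = TRUE)
  expect_equal(nrow(d1$caps$absorbance), 24)
  expect_equal(nrow(d1$stipes$absorbance), 24)
  expect_true(all(d1$contents$content > 0))
})

test_that("default dataset has 100 cap and 100 stipe rows, 25 per species", {
  cfg <- synthetic_config(grid_step = 64, seed = 2)  # coarse grid: counting only
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$caps$absorbance), 100)
  expect_equal(nrow(ds$stipes$absorbance), 100)
  expect_equal(unname(table(ds$caps$meta$species)), rep(25L, 4),
               ignore_attr = TRUE)
})

test_that("content draws recover the configured per-cell means at large n", {
  cfg <- synthetic_config(seed = 10)
  cp <- cfg$species_content_params
  n <- 10000
  ## B. edulis caps: mean 15.10, SD 1.37 (3 SE at n = 10,000)
  row <- cp[cp$species == "B_edulis" & cp$part == "cap", ]
  draws <- vapply(seq_len(n), function(i) {
    mirfuse:::.draw_content(row$mean, row$sd, cfg$seed, i)
  }, numeric(1))
  se <- row$sd / sqrt(n)
  expect_lt(abs(mean(draws) - row$mean), 3 * se)
  expect_lt(abs(sd(draws) - row$sd), 3 * row$sd / sqrt(2 * n))
})

test_that("unknown vocabulary values and invalid contents are rejected", {
  cfg <- small_config()
  expect_error(generate_spectrum(cfg, "B_fakeus", "cap", 10), "species")
  expect_error(generate_spectrum(cfg, "B_edulis", "gills", 10), "part")
  expect_error(generate_spectrum(cfg, "B_edulis", "cap", -1), "positive")
})
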