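test_that("calibration recovers exact lines and rejects degenerate designs", {
  cal <- fit_calibration(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r2_fit, 1, tolerance = 1e-12)

  cal2 <- fit_calibration(c(0, 0.25, 0.5, 1), 0.8 * c(0, 0.25, 0.5, 1) + 0.05)
  expect_equal(cal2$intercept, 0.05, tolerance = 1e-10)
  expect_equal(cal2$slope, 0.8, tolerance = 1e-10)

  expect_error(fit_calibration(c(0, 1), c(0, 1)), "3 standards")
  expect_error(fit_calibration(rep(0.5, 4), c(1, 2, 3, 4)), "degenerate")
  expect_error(fit_calibration(c(0, 0.5, 1), c(1, 0.5, 0)), "not positive")
})

test_that("noisy calibrations recover the true slope within Monte-Carlo error", {
  conc <- seq(0, 1, length.out = 6)
  slopes <- vapply(1:1000, function(i) {
    set.seed(i)
    fit_calibration(conc, 0.9 * conc + 0.02 + rnorm(6, 0, 0.01))$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(1000)
  expect_lt(abs(mean(slopes) - 0.9), 3 * se)
})

test_that("dilution fold arithmetic", {
  expect_equal(dilution_fold(assay_protocol()), 80)
  expect_equal(dilution_fold(assay_protocol(aliquot = 1, diluent = 0)), 1)
  expect_equal(dilution_fold(assay_protocol(aliquot = 0.5, diluent = 4.5)), 10)
})

test_that("absorbance converts to content through the assay chain", {
  curve <- structure(list(slope = 1, intercept = 0, r2_fit = 1,
                          n_standards = 3), class = "calibration_curve")
  ## 0.0018875 absorbance with defaults: x80, x25 ml, /0.25 g = 15.10 mg/g
  expect_equal(absorbance_to_content(0.0018875, curve), 15.10,
               tolerance = 1e-10)
  expect_equal(absorbance_to_content(curve$intercept, curve), 0)
  ## doubling the sample mass halves the content
  half <- absorbance_to_content(0.0018875, curve,
                                assay_protocol(sample_mass = 0.5))
  expect_equal(half, 15.10 / 2, tolerance = 1e-10)
  ## below-intercept absorbances clamp to zero with a warning
  curve2 <- structure(list(slope = 1, intercept = 0.05, r2_fit = 1,
                           n_standards = 3), class = "calibration_curve")
  expect_warning(out <- absorbance_to_content(0.01, curve2), "clamped")
  expect_equal(out, 0)
})

test_that("forward assay simulation inverts exactly", {
  curve <- fit_calibration(c(0, 0.5, 1), 0.75 * c(0, 0.5, 1) + 0.03)
  proto <- assay_protocol()
  contents <- c(0.5, 10.22, 15.10, 17.33)
  back <- absorbance_to_content(content_to_absorbance(contents, curve, proto),
                                curve, proto)
  expect_lt(max(abs(back - contents)), 1e-9)
})

test_that("species summaries compute the Table-style statistics", {
  rec <- data.frame(species = rep("B_edulis", 6),
                    part = rep(c("cap", "stipe"), each = 3),
                    content = c(12, 15, 18, 10, 11, 30))
  s <- summarize_species(rec)
  cap <- s$cells[s$cells$part == "cap", ]
  expect_equal(cap$mean, 15)
  expect_equal(cap$median, 15)
  expect_equal(c(cap$min, cap$max), c(12, 18))
  expect_equal(cap$extraction_pct, 1.5)
  st <- s$cells[s$cells$part == "stipe", ]
  expect_equal(st$median, 11)
  expect_equal(s$bcf$bcf, 15 / 11, tolerance = 1e-12)

  ## single record: SD flagged as degenerate zero
  one <- summarize_species(data.frame(species = "B_edulis",
                                      part = c("cap", "stipe"),
                                      content = c(5, 4)))
  expect_true(all(one$cells$sd == 0))
  expect_true(all(one$cells$sd_degenerate))

  ## even-n median is the mean of the central pair
  ev <- summarize_species(data.frame(species = "B_edulis",
                                     part = rep(c("cap", "stipe"), each = 4),
                                     content = c(1, 2, 3, 10, 1, 1, 1, 1)))
  expect_equal(ev$cells$median[ev$cells$part == "cap"], 2.5)
})

test_that("BCF uses medians, is scale invariant, and validates inputs", {
  cells <- data.frame(species = rep("B_edulis", 2), part = c("cap", "stipe"),
                      median = c(14.76, 17.33))
  expect_equal(bcf_cap_stipe(cells)$bcf_display, 0.85)
  cells2 <- cells; cells2$median <- cells2$median * 7
  expect_equal(bcf_cap_stipe(cells2)$bcf, bcf_cap_stipe(cells)$bcf,
               tolerance = 1e-12)
  expect_equal(bcf_cap_stipe(data.frame(species = "x",
                                        part = c("cap", "stipe"),
                                        median = c(3, 3)))$bcf_display, 1)
  expect_error(bcf_cap_stipe(cells[1, , drop = FALSE]), "lacks")
})

test_that("generator contents round-trip through the summary at scale", {
  ## n = 10,000 draws per cell would be slow through full spectra; contents
  ## alone carry the statistics being recovered
  cfg <- synthetic_config(seed = 77)
  cp <- cfg$species_content_params
  row <- cp[cp$species == "B_tomentipes" & cp$part == "stipe", ]
  draws <- vapply(1:10000, function(i) {
    mirfuse:::.draw_content(row$mean, row$sd, cfg$seed, i + 50000)
  }, numeric(1))
  rec <- data.frame(species = "B_tomentipes",
                    part = rep(c("stipe", "cap"), each = 10000),
                    content = c(draws, draws))
  s <- summarize_species(rec)
  cell <- s$cells[s$cells$part == "stipe", ]
  expect_lt(abs(cell$mean - row$mean), 3 * row$sd / sqrt(10000))
})
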