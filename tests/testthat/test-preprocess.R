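grid50 <- seq(500, 402, by = -2)

test_that("SG smoothing reproduces polynomials up to its order and preserves constants", {
  set.seed(11)
  for (rep in 1:5) {
    coefs <- rnorm(3)
    x <- outer(seq_along(grid50), 0:2, `^`) %*% coefs
    b <- toy_block(rbind(c(x), c(x)), grid50)
    sm <- sg_smooth(b, 7, 2)
    expect_lt(max(abs(sm$absorbance[1, ] - c(x))), 1e-10)
  }
  const <- toy_block(matrix(3.7, 2, 50), grid50)
  expect_equal(sg_smooth(const, 9)$absorbance, const$absorbance)
})

test_that("SG smoothing equals an explicit sliding least-squares fit", {
  set.seed(12)
  y <- rnorm(50)
  b <- toy_block(rbind(y, y), grid50)
  sm <- sg_smooth(b, 9, 2)
  h <- 4
  oracle <- vapply(seq_along(y), function(j) {
    idx <- max(1, j - h):min(50, j + h)
    df <- data.frame(yy = y[idx], g = grid50[idx])
    fit <- lm(yy ~ g + I(g^2), data = df)
    unname(predict(fit, data.frame(g = grid50[j])))
  }, numeric(1))
  expect_lt(max(abs(sm$absorbance[1, ] - oracle)), 1e-10)
})

test_that("SG interior points agree with signal::sgolayfilt", {
  set.seed(13)
  y <- cumsum(rnorm(50)) / 5
  b <- toy_block(rbind(y, y), grid50)
  sm <- sg_smooth(b, 9, 2)
  ref <- signal::sgolayfilt(y, p = 2, n = 9)
  interior <- 5:46
  expect_lt(max(abs(sm$absorbance[1, interior] - ref[interior])), 1e-10)
})

test_that("SG parameter validation", {
  b <- toy_block(matrix(rnorm(100), 2, 50), grid50)
  expect_error(sg_smooth(b, 8), "odd")
  expect_error(sg_smooth(b, 9, 9), "polyorder")
  expect_error(sg_smooth(b, 3), "\\[5")
})

test_that("SG derivatives are exact for linear and quadratic spectra", {
  a <- 0.003
  lin <- toy_block(rbind(a * grid50 + 1, a * grid50 + 1), grid50)
  d1 <- spectral_derivative(lin, 1, 15)
  expect_lt(max(abs(d1$absorbance - a)), 1e-9)

  quad <- toy_block(rbind(1e-4 * grid50^2, 1e-4 * grid50^2), grid50)
  d2 <- spectral_derivative(quad, 2, 15)
  expect_lt(max(abs(d2$absorbance - 2e-4)), 1e-9)
})

test_that("first SG derivative tracks the finite difference of the smoothed spectrum", {
  set.seed(14)
  grid <- seq(1000, 602, by = -2)
  y <- sin(seq(0, 6, length.out = 200)) + 0.5 * cos(seq(0, 11, length.out = 200))
  b <- toy_block(rbind(y, y), grid)
  d1 <- spectral_derivative(b, 1, 15)$absorbance[1, ]
  sm <- sg_smooth(b, 15, 2)$absorbance[1, ]
  interior <- 10:190
  fd <- (sm[interior + 1] - sm[interior - 1]) /
    (grid[interior + 1] - grid[interior - 1])
  expect_lt(max(abs(d1[interior] - fd) / max(abs(fd))), 0.05)
})

test_that("derivative window validation and gap support", {
  b <- toy_block(matrix(rnorm(100), 2, 50), grid50)
  expect_error(spectral_derivative(b, 1, 101), "exceeds")
  expect_error(spectral_derivative(b, 3), "order")
  ## gap-segment derivative is still exact on linear spectra
  lin <- toy_block(rbind(0.01 * grid50, 0.01 * grid50), grid50)
  d <- spectral_derivative(lin, 1, 7, gap = 3)
  expect_lt(max(abs(d$absorbance - 0.01)), 1e-9)
})

test_that("MSC inverts affine distortions of the reference", {
  ref <- sin(seq(0, 3, length.out = 50)) + 2
  b <- toy_block(rbind(ref, 2 * ref + 3, 0.5 * ref - 1), grid50)
  out <- msc(b, reference = ref)
  for (i in 1:3) {
    expect_lt(max(abs(out$absorbance[i, ] - ref)), 1e-10)
  }
  ## row identical to the (mean) reference is unchanged
  b2 <- toy_block(rbind(ref, ref), grid50)
  expect_equal(msc(b2)$absorbance[1, ], ref, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("MSC coefficients match the explicit normal equations", {
  set.seed(15)
  ref <- rnorm(5)
  x <- rnorm(5)
  b <- toy_block(rbind(x, x), c(900, 800, 700, 600, 500))
  out <- msc(b, reference = ref)
  fit <- lm(x ~ ref)
  a <- coef(fit)[2]; b0 <- coef(fit)[1]
  expect_lt(max(abs(out$absorbance[1, ] - (x - b0) / a)), 1e-12)
})

test_that("MSC is idempotent with a fixed reference and rejects degenerate references", {
  set.seed(16)
  ref <- rnorm(50) + 5
  b <- toy_block(matrix(rnorm(150), 3, 50), grid50)
  once <- msc(b, reference = ref)
  twice <- msc(once, reference = ref)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-10)
  expect_error(msc(b, reference = rep(1, 50)), "degenerate")
})

test_that("SNV centres and scales each spectrum", {
  b <- toy_block(rbind(c(1, 2, 3), c(10, 20, 60)), c(900, 800, 700))
  out <- snv(b)
  expect_equal(unname(out$absorbance[1, ]), c(-1, 0, 1))
  expect_lt(max(abs(rowMeans(out$absorbance))), 1e-12)
  expect_lt(max(abs(apply(out$absorbance, 1, sd) - 1)), 1e-12)
  const <- toy_block(rbind(c(1, 1, 1), c(1, 2, 3)), c(900, 800, 700))
  expect_error(snv(const), "S01")
})

test_that("SNV is invariant to positive affine transforms of a row", {
  set.seed(17)
  x <- rnorm(50)
  b1 <- toy_block(rbind(x, x), grid50)
  b2 <- toy_block(rbind(3.2 * x + 7, x), grid50)
  expect_equal(snv(b1)$absorbance[1, ], snv(b2)$absorbance[1, ],
               tolerance = 1e-12)
})

test_that("min-max 1-2 maps endpoints, degenerate columns, and extrapolates unclipped", {
  out <- minmax_1_2(matrix(c(0, 5, 10), 3, 1))
  expect_equal(out[, 1], c(1, 1.5, 2))
  out2 <- minmax_1_2(matrix(7, 2, 1))
  expect_equal(out2[, 1], c(1.5, 1.5))
  tr <- minmax_1_2(matrix(c(0, 10), 2, 1))
  te <- minmax_1_2(matrix(12, 1, 1), fitted_ranges = attr(tr, "ranges"))
  expect_equal(te[1, 1], 2.2)
})

test_that("all pretreatments preserve the block dimensions", {
  ds <- generate_dataset(small_config(seed = 21))
  b <- ds$caps
  for (f in list(function(x) sg_smooth(x, 9),
                 function(x) spectral_derivative(x, 1),
                 function(x) spectral_derivative(x, 2),
                 msc, snv)) {
    out <- f(b)
    expect_equal(dim(out$absorbance), dim(b$absorbance))
  }
})

test_that("treatment chain strings parse, validate, and round-trip canonically", {
  expect_equal(format(treatment_chain("SNV + FD+SG (9)")), "SNV+FD+SG(9)")
  expect_equal(format(treatment_chain("No")), "No")
  expect_equal(format(treatment_chain("MSC+FD+SG(9)")), "MSC+FD+SG(9)")
  expect_length(treatment_chain("No")$steps, 0)
  expect_error(treatment_chain("SG(8)"), "odd")
  expect_error(treatment_chain("FD+SD"), "at most one derivative")
  expect_error(treatment_chain("WAVELET"), "unknown")
})

test_that("chain application composes the individual steps in order", {
  ds <- generate_dataset(small_config(seed = 22))
  b <- ds$caps
  chain_out <- apply_chain(b, "FD+SG(7)")
  manual <- sg_smooth(spectral_derivative(b, 1, 15), 7)
  expect_equal(chain_out$absorbance, manual$absorbance, tolerance = 1e-12)
  expect_identical(apply_chain(b, "No")$absorbance, b$absorbance)
})

test_that("fitted chains freeze training state and reuse it on test spectra", {
  ds <- generate_dataset(small_config(seed = 23))
  b <- ds$caps
  tr <- b[1:16]; te <- b[17:24]
  fc <- fit_chain("MSC+SG(7)", tr)
  ## the frozen MSC reference is the training mean, not the test mean
  expect_equal(fc$states[[1]], unname(colMeans(tr$absorbance)))
  out_te <- transform_chain(fc, te)
  manual <- sg_smooth(msc(te, reference = colMeans(tr$absorbance)), 7)
  expect_equal(out_te$absorbance, manual$absorbance, tolerance = 1e-12)
  expect_identical(attr(out_te, "treatment"), "MSC+SG(7)")
})
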