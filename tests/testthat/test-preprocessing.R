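test_that("band cropping follows 1-based inclusive numbering", {
  m <- matrix(seq_len(3 * 256), 3, 256)
  out <- crop_bands(m)
  expect_identical(ncol(out), 200L)
  expect_identical(out[, 1], m[, 31])
  expect_identical(out[, 200], m[, 230])
  expect_identical(crop_bands(m, 1, 256), m)
  expect_error(crop_bands(m, 230, 31), class = "hsi_range_error")
  expect_error(crop_bands(m, 0, 10), class = "hsi_range_error")
  expect_error(crop_bands(m, 1, 300), class = "hsi_range_error")
})

test_that("the db6 filter bank is orthonormal and inverts exactly", {
  h <- oleasterHSI:::db6_dec_lo
  expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  for (k in 1:5)
    expect_equal(sum(h * c(rep(0, 2 * k), h)[seq_along(h)]), 0,
                 tolerance = 1e-10)

  set.seed(4)
  x <- rnorm(200)
  w <- dwt_db6(x, 3)
  expect_equal(idwt_db6(w), x, tolerance = 1e-9)
  expect_equal(sum(x^2), sum(w$approx^2) + sum(unlist(w$details)^2),
               tolerance = 1e-8)
  # threshold 0 is exact reconstruction through the denoiser too
  expect_equal(wavelet_denoise(x, threshold = 0), x, tolerance = 1e-9)
})

test_that("wavelet denoising reduces noise on smooth spectra", {
  expect_equal(wavelet_denoise(numeric(200)), numeric(200))
  t0 <- seq(0, 1, length.out = 200)
  clean <- sin(6 * t0) + 0.5 * exp(-((t0 - 0.5) / 0.1)^2)
  set.seed(6)
  wins <- replicate(100, {
    noisy <- clean + rnorm(200, 0, 0.01)
    den <- wavelet_denoise(noisy)
    sqrt(mean((den - clean)^2)) < sqrt(mean((noisy - clean)^2))
  })
  expect_gte(mean(wins), 0.95)
  expect_error(wavelet_denoise(rnorm(10)), class = "hsi_length_error")
  expect_error(wavelet_denoise(rnorm(25)), class = "hsi_length_error")
})

test_that("area normalization is a scale-invariant unit-sum map", {
  x <- rep(3.2, 200)
  expect_equal(area_normalize(x), rep(1 / 200, 200))
  set.seed(7)
  y <- runif(200, 0.1, 1)
  expect_equal(sum(area_normalize(y)), 1, tolerance = 1e-12)
  expect_equal(area_normalize(5 * y), area_normalize(y), tolerance = 1e-12)
  expect_error(area_normalize(numeric(200)),
               class = "hsi_normalization_error")
})

test_that("ROI averaging is the arithmetic mean with sane edge cases", {
  one <- matrix(rnorm(200), 1, 200)
  expect_equal(average_roi(one), as.vector(one))
  same <- matrix(rep(one, each = 5), 5, 200)
  expect_equal(average_roi(same), as.vector(one))
  set.seed(8)
  m <- matrix(rnorm(600), 3, 200)
  expect_equal(mean(average_roi(m)), mean(rowMeans(m)), tolerance = 1e-12)
  expect_error(average_roi(matrix(nrow = 0, ncol = 5)),
               class = "hsi_empty_input")
})

test_that("the preprocessing pipeline yields unit-sum deterministic rows", {
  set.seed(9)
  pix <- matrix(runif(40 * 256, 0.2, 0.8), 40, 256)
  s1 <- preprocess_roi(pix)
  s2 <- preprocess_roi(pix)
  expect_identical(s1, s2)
  expect_length(s1, 200L)
  expect_equal(sum(s1), 1, tolerance = 1e-10)
})

test_that("spectrum tables round-trip through CSV", {
  tb <- demo_table()
  tb$split <- rep(c("calibration", "validation", "prediction"), length.out = 60)
  path <- file.path(withr::local_tempdir(), "table.csv")
  write_spectrum_table(tb, path)
  back <- read_spectrum_table(path)
  expect_equal(back$spectra, tb$spectra, tolerance = 1e-12)
  expect_identical(back$label, tb$label)
  expect_identical(back$split, tb$split)
  expect_equal(back$wavelength, tb$wavelength, tolerance = 1e-4)
})

test_that("table construction and split subsetting validate inputs", {
  expect_error(spectrum_table(matrix(0, 2, 3), 1:2, c(0, 1)),
               class = "hsi_format_error")
  expect_error(spectrum_table(matrix(0, 2, 3), 1:3, c(0, 5)),
               class = "hsi_label_error")
  tb <- demo_table()
  expect_error(table_split(tb, "calibration"),
               class = "hsi_invalid_argument")
})
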