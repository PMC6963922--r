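test_that("the Savitzky-Golay second derivative matches closed forms", {
  x <- seq_len(120)
  lin <- second_derivative(rbind(2 + 3 * x, 1 - 0.5 * x), window = 9)
  expect_equal(max(abs(lin$deriv)), 0, tolerance = 1e-9)

  quad <- second_derivative(rbind(x^2, x^2), window = 13)
  expect_equal(quad$deriv[1, ], rep(2, 120), tolerance = 1e-8)

  # sine: d2/di2 sin(w i) = -w^2 sin(w i); interior agreement within 2%
  w <- 2 * pi / 60
  y <- sin(w * x)
  d <- second_derivative(rbind(y, y), window = 9)$deriv[1, ]
  interior <- 10:110
  expect_lt(max(abs(d[interior] + w^2 * y[interior])) / w^2, 0.02)

  expect_error(second_derivative(rbind(y, y), window = 8),
               class = "hsi_parameter_error")
  expect_error(second_derivative(rbind(y, y), window = 9, polyorder = 9),
               class = "hsi_parameter_error")
  expect_error(second_derivative(rbind(y, y), window = 201),
               class = "hsi_parameter_error")
})

planted_curves <- function(centers, deltas, wl, sigma = 12) {
  base <- 0.5 - 0.08 * exp(-((wl - 1300) / 200)^2)
  t(vapply(seq_along(deltas[[1]]) , function(o) {
    r <- base
    for (k in seq_along(centers))
      r <- r - deltas[[k]][o] * exp(-0.5 * ((wl - centers[k]) / sigma)^2)
    r
  }, numeric(length(wl))))
}

test_that("selection recovers planted class-contrast features", {
  wl <- crop_bands(default_wavelengths())
  centers <- c(1050, 1150, 1250, 1380, 1550)
  deltas <- list(c(0.02, 0.05, 0.08), c(0.08, 0.05, 0.02),
                 c(0.05, 0.08, 0.02), c(0.02, 0.08, 0.05),
                 c(0.08, 0.02, 0.05))
  cm <- planted_curves(centers, deltas, wl)
  ew <- select_effective(second_derivative(cm), wl)
  spacing <- diff(wl[1:2])
  for (cc in centers)
    expect_lte(min(abs(ew$wavelength - cc)), spacing)

  # identical class curves produce an empty selection, not an error
  same <- planted_curves(centers, rep(list(c(0.05, 0.05, 0.05)), 5), wl)
  ew0 <- select_effective(second_derivative(same), wl)
  expect_length(ew0$index, 0L)
})

test_that("n_max keeps exactly the largest-spread centers (oracle)", {
  wl <- crop_bands(default_wavelengths())
  centers <- c(1050, 1150, 1250, 1380, 1550)
  mag <- c(0.010, 0.030, 0.050, 0.020, 0.040)
  deltas <- lapply(mag, function(m) c(-m, 0, m) + 0.05)
  cm <- planted_curves(centers, deltas, wl)
  d <- second_derivative(cm)
  ew <- select_effective(d, wl, n_max = 3L)
  expect_length(ew$index, 3L)
  # brute-force oracle: spread at each planted center, top three
  spread <- apply(d$deriv, 2L, max) - apply(d$deriv, 2L, min)
  bands <- vapply(centers, function(cc) which.min(abs(wl - cc)), integer(1))
  oracle <- centers[order(spread[bands], decreasing = TRUE)][1:3]
  for (cc in oracle)
    expect_lte(min(abs(ew$wavelength - cc)), diff(wl[1:2]))
})

test_that("selection is invariant to class order and common scaling", {
  wl <- crop_bands(default_wavelengths())
  cm <- planted_curves(c(1100, 1300, 1500),
                       list(c(0.02, 0.05, 0.08), c(0.08, 0.02, 0.05),
                            c(0.05, 0.08, 0.02)), wl)
  e1 <- select_effective(second_derivative(cm), wl)
  e2 <- select_effective(second_derivative(cm[c(3, 1, 2), ]), wl)
  e3 <- select_effective(second_derivative(cm * 4.2), wl)
  expect_identical(e1$index, e2$index)
  expect_identical(e1$index, e3$index)
})

test_that("min_separation and fixed wavelength subsetting behave", {
  tb <- demo_table()
  cmn <- class_mean_spectra(tb)
  ew <- select_effective(second_derivative(cmn), tb$wavelength,
                         min_separation_nm = 25)
  if (length(ew$index) > 1)
    expect_true(all(diff(ew$wavelength) >= 25))

  fixed <- fixed_wavelengths(candidate_feature_wavelengths()[1:5],
                             tb$wavelength)
  expect_length(fixed$index, 5L)
  expect_true(all(abs(fixed$wavelength -
                        candidate_feature_wavelengths()[1:5]) <
                    diff(tb$wavelength[1:2])))
})

test_that("subset_table keeps rows, labels and order intact", {
  tb <- demo_table()
  ew <- fixed_wavelengths(candidate_feature_wavelengths(), tb$wavelength)
  sub <- subset_table(tb, ew)
  expect_identical(ncol(sub$spectra), length(ew$index))
  expect_identical(sub$label, tb$label)
  expect_identical(sub$sample_id, tb$sample_id)
  expect_equal(sub$spectra[, 1], tb$spectra[, ew$index[1]])

  all_ew <- fixed_wavelengths(tb$wavelength, tb$wavelength)
  expect_equal(subset_table(tb, all_ew)$spectra, tb$spectra)

  bad <- all_ew; bad$index <- c(1L, 9999L)
  expect_error(subset_table(tb, bad), class = "hsi_range_error")
})
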