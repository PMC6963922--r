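test_that("band_image picks the nearest band and checks the range", {
  cube <- hypercube(array(seq_len(4 * 4 * 256), c(4, 4, 256)),
                    default_wavelengths(), kind = "reflectance")
  bi <- band_image(cube, 1119)
  spacing <- diff(cube$wavelength[1:2])
  expect_lte(bi$delta_nm, spacing / 2)
  exact <- band_image(cube, cube$wavelength[100])
  expect_identical(exact$band, 100L)
  expect_identical(exact$delta_nm, 0)
  expect_error(band_image(cube, 500), class = "hsi_range_error")
})

test_that("binarization separates a two-level image exactly", {
  img <- matrix(0.05, 30, 30)
  img[10:20, 12:22] <- 0.6
  mask <- binarize(img)
  expect_identical(mask, img > 0.3)
  expect_error(binarize(matrix(0.5, 5, 5)), class = "hsi_degenerate_image")
  # fixed threshold override
  expect_identical(binarize(img, method = "fixed", threshold = 0.5),
                   img >= 0.5)
})

test_that("segmentation recovers the generated fruits", {
  sc <- demo_scene()
  cube <- demo_cube()
  rois <- segment_fruits(cube)
  truth <- sc$truth

  mask_agree <- mean((rois$label_image > 0) == (truth$label_image > 0))
  expect_gte(mask_agree, 0.99)
  expect_identical(length(rois$fruit_ids), 18L)

  # per-fruit Jaccard vs ground truth
  for (id in rois$fruit_ids) {
    seg <- rois$label_image == id
    tid <- names(which.max(table(truth$label_image[seg][
      truth$label_image[seg] > 0])))
    tru <- truth$label_image == as.integer(tid)
    expect_gte(sum(seg & tru) / sum(seg | tru), 0.95)
  }

  org <- roi_origins(rois, truth)
  expect_equal(sort(org), sort(truth$fruit_origins))
})

test_that("component labelling filters specks and keeps blobs disjoint", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:12, 5:12] <- TRUE
  mask[25:33, 20:28] <- TRUE
  mask[38, 38] <- TRUE # 1-px speck
  rois <- label_fruits(mask, min_area = 30)
  expect_identical(length(rois$fruit_ids), 2L)
  expect_identical(sum(rois$areas), sum(mask) - 1L)
  expect_false(any(rois$label_image == 1L & rois$label_image == 2L))

  speck <- matrix(FALSE, 10, 10); speck[1:3, 1] <- TRUE
  expect_error(label_fruits(speck, min_area = 30),
               class = "hsi_empty_scene")
})

test_that("8-connectivity joins diagonal pixels", {
  mask <- matrix(FALSE, 6, 6)
  mask[cbind(1:4, 1:4)] <- TRUE # a pure diagonal
  rois <- label_fruits(mask, min_area = 1)
  expect_identical(length(rois$fruit_ids), 1L)
})

test_that("pixel spectra extraction conserves pixels and shapes", {
  sc <- demo_scene()
  cube <- demo_cube()
  rois <- segment_fruits(cube)
  pix <- extract_pixel_spectra(cube, rois)

  expect_identical(vapply(pix, nrow, integer(1)),
                   stats::setNames(as.integer(rois$areas),
                                   names(pix)))
  expect_true(all(vapply(pix, ncol, integer(1)) == dim(cube)[3]))
  expect_identical(sum(vapply(pix, nrow, integer(1))),
                   sum(rois$label_image > 0))

  # conservation: summed rows equal the masked cube sum, band by band
  total <- Reduce(`+`, lapply(pix, colSums))
  flat <- matrix(cube$data, prod(dim(cube)[1:2]), dim(cube)[3])
  expect_equal(total, colSums(flat[as.vector(rois$label_image > 0), ]),
               tolerance = 1e-10)

  expect_error(extract_pixel_spectra(sc$raw, rois),
               class = "hsi_invalid_argument")
  bad <- rois; bad$label_image <- bad$label_image[1:10, 1:10]
  expect_error(extract_pixel_spectra(cube, bad), class = "hsi_shape_error")
})

test_that("noiseless pixel spectra equal the origin signature row-wise", {
  sc <- demo_scene_noiseless()
  cube <- correct_reflectance(sc$raw, sc$dark, sc$white)
  rois <- segment_fruits(cube)
  org <- roi_origins(rois, sc$truth)
  pix <- extract_pixel_spectra(cube, rois)
  sigs <- demo_signatures()
  for (k in seq_along(pix)) {
    expect_equal(pix[[k]],
                 matrix(sigs[[org[k] + 1]]$reflectance, nrow(pix[[k]]),
                        ncol(pix[[k]]), byrow = TRUE),
                 tolerance = 1e-12)
  }
})
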