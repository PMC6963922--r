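#' Crop a spectral matrix to a waveband range
#'
#' Band numbers are 1-based and inclusive; the default pipeline retains
#' wavebands 31 to 230 (975--1646 nm), i.e. 200 variables, discarding the
#' noisy spectrograph edges.
#'
#' @param x spectra matrix (rows = pixels or samples, columns = bands) or a
#'   numeric vector (one spectrum).
#' @param first_band,last_band 1-based inclusive band numbers.
#' @return cropped matrix/vector.
#' @export
crop_bands <- function(x, first_band = 31L, last_band = 230L) {
  nb <- if (is.matrix(x)) ncol(x) else length(x)
  if (first_band < 1L || last_band > nb || first_band > last_band)
    hsi_abort(sprintf(
      "invalid band range %d-%d for %d bands (1-based, inclusive, first <= last)",
      first_band, last_band, nb), "hsi_range_error")
  if (is.matrix(x)) x[, first_band:last_band, drop = FALSE]
  else x[first_band:last_band]
}

#' Area-normalize a spectrum
#'
#' Divides each value by the sum over the retained bands so the spectrum
#' sums to one, removing intensity effects of sample size and shape.
#'
#' @param x numeric spectrum (or matrix, normalized row-wise).
#' @return normalized spectrum/matrix.
#' @export
area_normalize <- function(x) {
  if (is.matrix(x)) {
    s <- rowSums(x)
    if (any(abs(s) < 1e-300))
      hsi_abort("zero-sum spectrum cannot be area-normalized",
                "hsi_normalization_error")
    return(x / s)
  }
  s <- sum(x)
  if (abs(s) < 1e-300)
    hsi_abort("zero-sum spectrum cannot be area-normalized",
              "hsi_normalization_error")
  x / s
}

#' Average preprocessed pixel spectra over one fruit
#'
#' @param pixmat pixels x bands matrix (already preprocessed).
#' @return numeric vector, the per-band arithmetic mean.
#' @export
average_roi <- function(pixmat) {
  if (!is.matrix(pixmat) || nrow(pixmat) < 1L)
    hsi_abort("ROI has no pixel spectra to average", "hsi_empty_input")
  colMeans(pixmat)
}

#' Preprocess one fruit's pixel spectra to a single sample spectrum
#'
#' Fixed pipeline order: crop bands, wavelet-denoise each pixel spectrum,
#' area-normalize each pixel spectrum, then average over pixels. Because
#' averaging is convex, the resulting sample spectrum still sums to one.
#'
#' @param pixmat pixels x bands reflectance matrix.
#' @param first_band,last_band crop range (1-based inclusive).
#' @param denoise logical; apply [wavelet_denoise()] per pixel.
#' @param normalize logical; apply [area_normalize()] per pixel.
#' @param level wavelet decomposition depth.
#' @return numeric spectrum over the retained bands.
#' @export
preprocess_roi <- function(pixmat, first_band = 31L, last_band = 230L,
                           denoise = TRUE, normalize = TRUE, level = 3L) {
  m <- crop_bands(pixmat, first_band, last_band)
  if (denoise) m <- t(apply(m, 1L, wavelet_denoise, level = level))
  if (normalize) m <- area_normalize(m)
  average_roi(m)
}

#' Table of per-fruit spectra
#'
#' The contract between the imaging and modelling halves of the pipeline:
#' one row per fruit over the retained wavelengths, with origin labels
#' (0 = Gansu, 1 = Ningxia, 2 = Xinjiang), sample ids and (optionally) a
#' split assignment.
#'
#' @param spectra samples x bands numeric matrix.
#' @param wavelength retained wavelength axis, nm.
#' @param label integer origin codes in 0:2.
#' @param sample_id character ids (default `s1..sn`).
#' @param split optional character vector in
#'   `c("calibration", "validation", "prediction")`.
#' @return a `spectrum_table`.
#' @export
spectrum_table <- function(spectra, wavelength, label,
                           sample_id = NULL, split = NULL) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelength))
    hsi_abort(sprintf("spectra have %d columns but axis has %d wavelengths",
                      ncol(spectra), length(wavelength)), "hsi_format_error")
  if (nrow(spectra) != length(label))
    hsi_abort("one label per row required", "hsi_shape_error")
  if (!all(label %in% 0:2))
    hsi_abort("labels must be origin codes 0, 1 or 2", "hsi_label_error")
  structure(list(
    spectra = unname(spectra), wavelength = as.numeric(wavelength),
    label = as.integer(label),
    sample_id = sample_id %||% paste0("s", seq_len(nrow(spectra))),
    split = split), class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelength), max(x$wavelength)))
  print(table(origin = x$label,
              split = x$split %||% rep("unassigned", length(x$label))))
  invisible(x)
}

#' @export
dim.spectrum_table <- function(x) dim(x$spectra)

#' Subset a spectrum table by split
#' @param table a `spectrum_table`.
#' @param split one of `"calibration"`, `"validation"`, `"prediction"`.
#' @return a `spectrum_table` restricted to that split.
#' @export
table_split <- function(table, split) {
  if (is.null(table$split))
    hsi_abort("table has no split assignment", "hsi_invalid_argument")
  keep <- table$split == split
  spectrum_table(table$spectra[keep, , drop = FALSE], table$wavelength,
                 table$label[keep], table$sample_id[keep],
                 table$split[keep])
}

#' Serialize a spectrum table to CSV
#'
#' Columns: `sample_id`, `origin`, `split`, then one column per wavelength
#' named `nm<wavelength>`. Reading back reconstructs the table.
#'
#' @param table a `spectrum_table`.
#' @param path CSV path.
#' @export
write_spectrum_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_id, origin = table$label,
                   split = table$split %||% NA_character_,
                   table$spectra, check.names = FALSE)
  names(df)[-(1:3)] <- sprintf("nm%.4f", table$wavelength)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_table
#' @export
read_spectrum_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl_cols <- grep("^nm", names(df))
  spectrum_table(as.matrix(df[, wl_cols]),
                 as.numeric(sub("^nm", "", names(df)[wl_cols])),
                 df$origin, df$sample_id,
                 if (all(is.na(df$split))) NULL else df$split)
}

#' Build the sample spectrum table from rendered scenes
#'
#' Runs correction, segmentation, per-fruit preprocessing and ground-truth
#' origin matching over every scene of a dataset.
#'
#' @param dataset output of [generate_dataset()].
#' @param first_band,last_band crop range.
#' @param segmentation_nm segmentation wavelength (default 1119 nm).
#' @param min_area minimum fruit area, px.
#' @param denoise,normalize preprocessing switches.
#' @return a `spectrum_table` (no split assigned yet).
#' @export
dataset_to_table <- function(dataset, first_band = 31L, last_band = 230L,
                             segmentation_nm = 1119, min_area = 30L,
                             denoise = TRUE, normalize = TRUE) {
  rows <- list(); labels <- integer(0); ids <- character(0)
  wl_out <- NULL
  for (si in seq_along(dataset$scenes)) {
    sc <- dataset$scenes[[si]]
    cube <- correct_reflectance(sc$raw, sc$dark, sc$white)
    rois <- segment_fruits(cube, segmentation_nm, min_area = min_area)
    origins <- roi_origins(rois, sc$truth)
    pix <- extract_pixel_spectra(cube, rois)
    for (k in seq_along(pix)) {
      rows[[length(rows) + 1L]] <-
        preprocess_roi(pix[[k]], first_band, last_band,
                       denoise = denoise, normalize = normalize)
      labels <- c(labels, origins[k])
      ids <- c(ids, sprintf("scene%02d_fruit%03d", si, k))
    }
    if (is.null(wl_out))
      wl_out <- crop_bands(sc$wavelength, first_band, last_band)
  }
  spectrum_table(do.call(rbind, rows), wl_out, labels, ids)
}
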