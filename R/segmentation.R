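#' Extract a single-band gray-scale image
#'
#' Returns the band whose axis wavelength is nearest the request (the
#' segmentation band defaults to 1119 nm elsewhere in the pipeline).
#'
#' @param cube a `hypercube`.
#' @param wavelength_nm requested wavelength; must lie within the axis range.
#' @return list with `image` (width x length matrix), `band` (index),
#'   `wavelength` (axis value used), `delta_nm`.
#' @export
band_image <- function(cube, wavelength_nm) {
  wl <- cube$wavelength
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    hsi_abort(sprintf("wavelength %.1f nm outside axis range %.1f-%.1f nm",
                      wavelength_nm, min(wl), max(wl)), "hsi_range_error")
  b <- which.min(abs(wl - wavelength_nm))
  list(image = cube$data[, , b], band = b, wavelength = wl[b],
       delta_nm = abs(wl[b] - wavelength_nm))
}

# Otsu's threshold on a 256-bin histogram: maximize between-class variance.
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (!is.finite(diff(r)) || diff(r) <= 0)
    hsi_abort("cannot threshold a constant image", "hsi_degenerate_image")
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  r[1] + k / n_bins * diff(r)
}

#' Binarize a gray-scale image
#'
#' Foreground (fruit) is where the image is at or above the threshold.
#' The default automatic threshold is Otsu's method; a fixed threshold may
#' be supplied instead.
#'
#' @param image numeric matrix, finite-valued.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric, required for `method = "fixed"`.
#' @return logical matrix (`TRUE` = fruit).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  if (!all(is.finite(image)))
    hsi_abort("image contains non-finite values", "hsi_invalid_argument")
  thr <- if (method == "fixed") {
    if (is.null(threshold))
      hsi_abort("method 'fixed' needs a threshold", "hsi_invalid_argument")
    threshold
  } else otsu_threshold(image)
  image >= thr
}

# 8-connected components via run-length union-find: foreground runs along
# each column are unioned with runs in the previous column whose row span,
# dilated by one pixel, overlaps.
label_components <- function(mask) {
  W <- nrow(mask); L <- ncol(mask)
  run_col <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (j in seq_len(L)) {
    col <- mask[, j]
    if (!any(col)) next
    d <- diff(c(FALSE, col, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    run_col <- c(run_col, rep(j, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
  }
  nr <- length(run_s)
  if (!nr) return(matrix(0L, W, L))
  parent <- seq_len(nr)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  prev <- integer(0)
  for (j in sort(unique(run_col))) {
    cur <- which(run_col == j)
    for (i in cur) for (k in prev) {
      if (run_col[k] == j - 1L &&
          run_s[i] <= run_e[k] + 1L && run_e[i] >= run_s[k] - 1L) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[ri] <- rk
      }
    }
    prev <- cur
  }
  root <- vapply(seq_len(nr), find, integer(1))
  comp <- match(root, unique(root))
  lab <- matrix(0L, W, L)
  for (i in seq_len(nr))
    lab[run_s[i]:run_e[i], run_col[i]] <- comp[i]
  lab
}

#' Label individual fruits in a binary mask
#'
#' 8-connected components; components smaller than `min_area` pixels are
#' discarded as specks; surviving ids are renumbered 1..K in raster order
#' of each component's first pixel (column-major, the array order).
#'
#' @param mask logical matrix from [binarize()].
#' @param min_area minimum component area in px (default 30).
#' @param band_used wavelength (nm) recorded as provenance.
#' @return an `roi_set`: list with `label_image`, `fruit_ids`, `areas`,
#'   `band_used`.
#' @export
label_fruits <- function(mask, min_area = 30L, band_used = NA_real_) {
  if (!is.logical(mask)) mask <- mask > 0
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (!length(keep))
    hsi_abort(sprintf(
      "no fruit regions of at least %d px survive labelling", min_area),
      "hsi_empty_scene")
  lab[!(lab %in% keep)] <- 0L
  first_pix <- vapply(keep, function(k) which(lab == k)[1], numeric(1))
  ord <- keep[order(first_pix)]
  relab <- integer(max(ord)); relab[ord] <- seq_along(ord)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  structure(list(label_image = lab, fruit_ids = seq_along(ord),
                 areas = tabulate(lab[lab > 0L], length(ord)),
                 band_used = band_used),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d fruits, areas %d-%d px (band %.0f nm)\n",
              length(x$fruit_ids), min(x$areas), max(x$areas), x$band_used))
  invisible(x)
}

#' Segment fruits from a reflectance cube
#'
#' Convenience wrapper: gray-scale image at the segmentation wavelength
#' (default 1119 nm), automatic binarization, component labelling.
#'
#' @param cube reflectance `hypercube`.
#' @param wavelength_nm segmentation band, nm.
#' @param min_area minimum fruit area, px.
#' @inheritParams binarize
#' @return an `roi_set`.
#' @export
segment_fruits <- function(cube, wavelength_nm = 1119, min_area = 30L,
                           method = "otsu", threshold = NULL) {
  bi <- band_image(cube, wavelength_nm)
  mask <- binarize(bi$image, method = method, threshold = threshold)
  label_fruits(mask, min_area = min_area, band_used = bi$wavelength)
}

#' Extract per-fruit pixel spectra
#'
#' @param cube reflectance `hypercube`.
#' @param roiset an `roi_set` with matching spatial shape.
#' @return named list, one `pixels x bands` matrix per fruit id.
#' @export
extract_pixel_spectra <- function(cube, roiset) {
  if (cube$kind != "reflectance")
    hsi_abort("pixel spectra are extracted from a reflectance cube",
              "hsi_invalid_argument")
  d <- dim(cube$data)
  if (!all(dim(roiset$label_image) == d[1:2]))
    hsi_abort(sprintf(
      "label image is %d x %d but cube is %d x %d",
      nrow(roiset$label_image), ncol(roiset$label_image), d[1], d[2]),
      "hsi_shape_error")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  lab <- as.vector(roiset$label_image)
  out <- lapply(roiset$fruit_ids, function(id)
    flat[lab == id, , drop = FALSE])
  names(out) <- as.character(roiset$fruit_ids)
  out
}

#' Map segmented fruits to ground-truth origins
#'
#' For synthetic scenes: assigns each segmented ROI the origin of the
#' ground-truth fruit it overlaps most.
#'
#' @param roiset an `roi_set`.
#' @param truth the `truth` element of a rendered scene.
#' @return integer vector of origin codes, one per fruit id.
#' @export
roi_origins <- function(roiset, truth) {
  vapply(roiset$fruit_ids, function(id) {
    tl <- truth$label_image[roiset$label_image == id]
    tl <- tl[tl > 0L]
    if (!length(tl)) return(NA_integer_)
    truth$fruit_origins[as.integer(names(which.max(table(tl))))]
  }, integer(1))
}
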