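#' Default spectrograph wavelength axis
#'
#' The instrument emulated throughout the package samples 256 wavebands
#' evenly over 874--1734 nm (about 3.37 nm per band). Band numbering is
#' 1-based everywhere.
#'
#' @param n_bands number of wavebands.
#' @param range_nm two-element numeric, first and last wavelength in nm.
#' @return numeric vector of length `n_bands`, strictly increasing.
#' @export
#' @examples
#' ax <- default_wavelengths()
#' ax[c(31, 230)]  # the retained-range endpoints, ~975 and ~1646 nm
default_wavelengths <- function(n_bands = 256L, range_nm = c(874, 1734)) {
  seq(range_nm[1], range_nm[2], length.out = n_bands)
}

#' Hyperspectral cube container
#'
#' A line-scan hypercube: `data` is a 3-D array indexed
#' (width pixel, scan-line, band). `kind` records whether values are raw
#' digital numbers or corrected reflectance.
#'
#' @param data 3-D numeric array, width x length x bands.
#' @param wavelength strictly increasing numeric axis, one value per band.
#' @param kind `"raw"` or `"reflectance"`.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, wavelength = default_wavelengths(dim(data)[3]),
                      kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L)
    hsi_abort("`data` must be a 3-D array (width x length x bands)",
              "hsi_shape_error")
  if (dim(data)[3] != length(wavelength))
    hsi_abort(sprintf(
      "band dimension (%d) does not match wavelength axis length (%d)",
      dim(data)[3], length(wavelength)), "hsi_format_error")
  if (any(diff(wavelength) <= 0))
    hsi_abort("wavelength axis must be strictly increasing", "hsi_format_error")
  structure(list(data = data, wavelength = as.numeric(wavelength), kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%.1f-%.1f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength), x$kind))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

# Broadcast a per-line reference frame (width x bands) to cube shape slice
# by slice; a full-shape array is passed through.
conform_reference <- function(ref, d, what) {
  if (is.matrix(ref) && all(dim(ref) == d[c(1, 3)])) return(ref)
  if (length(dim(ref)) == 3L && all(dim(ref) == d)) return(ref)
  hsi_abort(sprintf(
    "%s reference must be a %d x %d per-line frame or a full %d x %d x %d array",
    what, d[1], d[3], d[1], d[2], d[3]), "hsi_shape_error")
}

#' White/dark reflectance correction
#'
#' Converts raw digital numbers to relative reflectance,
#' \deqn{I_c = (I_r - I_d) / (I_w - I_d),}
#' where \eqn{I_r} is the raw cube and \eqn{I_d}, \eqn{I_w} are the dark and
#' white reference frames. References are per-scan-line frames
#' (width x bands), broadcast along the scan direction, matching how a
#' push-broom camera is calibrated; full cube-shaped references are also
#' accepted. Values outside [0, 1] are deliberately not clipped.
#'
#' @param raw a `hypercube` with `kind = "raw"`.
#' @param dark,white reference frames (width x bands matrices or arrays of
#'   the cube's shape).
#' @param tol denominator guard: any `(white - dark)` element `<= tol`
#'   raises a degenerate-reference error naming the first offending index.
#' @return a `hypercube` with `kind = "reflectance"`.
#' @export
correct_reflectance <- function(raw, dark, white, tol = 1e-9) {
  if (!inherits(raw, "hypercube") || raw$kind != "raw")
    hsi_abort("`raw` must be a hypercube of kind 'raw'", "hsi_invalid_argument")
  d <- dim(raw$data)
  dk <- conform_reference(dark, d, "dark")
  wt <- conform_reference(white, d, "white")
  span <- wt - dk
  bad <- which(span <= tol)
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(span))
    hsi_abort(sprintf(
      "degenerate reference: (white - dark) <= %g at element [%s]",
      tol, paste(idx[1, ], collapse = ", ")), "hsi_degenerate_reference")
  }
  out <- array(0, d)
  per_line <- is.matrix(dk)
  for (b in seq_len(d[3])) {
    if (per_line) {
      out[, , b] <- (raw$data[, , b] - dk[, b]) / span[, b]
    } else {
      out[, , b] <- (raw$data[, , b] - dk[, , b]) / span[, , b]
    }
  }
  hypercube(out, raw$wavelength, kind = "reflectance")
}
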