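# Savitzky-Golay: least-squares polynomial fit coefficients. Central
# window for interior points; asymmetric windows at the edges so the
# output keeps the input length.
savgol_deriv2 <- function(y, window, polyorder, delta = 1) {
  n <- length(y)
  if (window %% 2L != 1L || window <= polyorder || polyorder < 2L ||
      window > n)
    hsi_abort(sprintf(
      "invalid Savitzky-Golay parameters: window %d (odd, > polyorder, <= length %d), polyorder %d (>= 2)",
      window, n, polyorder), "hsi_parameter_error")
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  # design for offsets -h..h; second-derivative filter = 2 * row 3 of the
  # pseudoinverse (coefficient of t^2, times 2!)
  A <- outer(-h:h, 0:polyorder, `^`)
  Pinv <- solve(crossprod(A), t(A))
  w2 <- 2 * Pinv[3L, ]
  for (i in (h + 1L):(n - h)) out[i] <- sum(w2 * y[(i - h):(i + h)])
  # edges: fit the first/last window once, evaluate its 2nd derivative at
  # the uncovered offsets
  edge_fit <- function(idx, offs) {
    B <- outer(offs, 0:polyorder, `^`)
    cf <- solve(crossprod(B), crossprod(B, y[idx]))
    function(t0) sum(cf[3:(polyorder + 1L)] *
                       (2:polyorder) * (1:(polyorder - 1L)) *
                       t0^(0:(polyorder - 2L)))
  }
  fl <- edge_fit(1:window, 0:(window - 1L))
  for (i in 1:h) out[i] <- fl(i - 1)
  fr <- edge_fit((n - window + 1L):n, 0:(window - 1L))
  for (i in (n - h + 1L):n) out[i] <- fr(i - (n - window + 1L))
  out / delta^2
}

#' Second-derivative spectra of class means
#'
#' Savitzky-Golay second derivative of each class-mean spectrum. The
#' derivative is taken with respect to band index by default (`delta = 1`);
#' supply the band spacing in nm to obtain nm^-2 units -- the selection
#' rule is scale-invariant either way.
#'
#' @param class_means classes x bands matrix (one row per origin).
#' @param window odd window length (default 9 bands, about 30 nm on the
#'   retained grid -- matched to the ~10 nm absorption features so their
#'   extrema stay localized; class means are already heavily averaged, so
#'   little extra noise suppression is needed).
#' @param polyorder polynomial order (default 2).
#' @param delta abscissa spacing.
#' @return a `second_derivative_set`: list with `deriv` (same shape as
#'   `class_means`), `window`, `polyorder`, `delta`.
#' @export
second_derivative <- function(class_means, window = 9L, polyorder = 2L,
                              delta = 1) {
  class_means <- as.matrix(class_means)
  deriv <- t(apply(class_means, 1L, savgol_deriv2,
                   window = window, polyorder = polyorder, delta = delta))
  structure(list(deriv = deriv, window = as.integer(window),
                 polyorder = as.integer(polyorder), delta = delta),
            class = "second_derivative_set")
}

#' Class-mean spectra of a table
#'
#' @param table a `spectrum_table`.
#' @param split optional split to restrict to (e.g. `"calibration"`).
#' @return classes x bands matrix, rows ordered by origin code 0,1,2.
#' @export
class_mean_spectra <- function(table, split = NULL) {
  if (!is.null(split)) table <- table_split(table, split)
  t(vapply(0:2, function(cl)
    colMeans(table$spectra[table$label == cl, , drop = FALSE]),
    numeric(ncol(table$spectra))))
}

local_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[(y[i] > y[i - 1L] & y[i] >= y[i + 1L]) |
    (y[i] < y[i - 1L] & y[i] <= y[i + 1L])]
}

#' Select effective wavelengths from second-derivative curves
#'
#' Automates the manual reading of second-derivative class-mean spectra:
#' candidate bands are interior local extrema (positive or negative peaks)
#' of any class curve; each candidate is scored by its between-class
#' spread (max minus min across the class curves at that band); candidates
#' scoring below the `spread_quantile` quantile of candidate spreads are
#' dropped; the rest are kept greedily in descending spread order subject
#' to a minimum mutual separation, up to `n_max` selections. Identical
#' class curves yield an empty selection.
#'
#' @param deriv a `second_derivative_set`.
#' @param wavelength retained wavelength axis, nm.
#' @param n_max maximum selections (default 22).
#' @param min_separation_nm minimum distance between kept wavelengths
#'   (default 8 nm).
#' @param spread_quantile candidate-spread quantile below which candidates
#'   are discarded (default 0.5).
#' @return an `effective_wavelengths`: list with ascending `wavelength`,
#'   `index` (into the retained axis), `score`, and the parameters used.
#' @export
select_effective <- function(deriv, wavelength, n_max = 22L,
                             min_separation_nm = 8,
                             spread_quantile = 0.5) {
  D <- deriv$deriv
  if (nrow(D) < 2L)
    hsi_abort("need at least two class curves", "hsi_invalid_argument")
  cand <- sort(unique(unlist(lapply(seq_len(nrow(D)), function(r)
    local_extrema(D[r, ])))))
  spread <- apply(D, 2L, max) - apply(D, 2L, min)
  eps <- 1e-12 * max(abs(D), 1e-300)
  cand <- cand[spread[cand] > eps]
  if (length(cand)) {
    thr <- quantile(spread[cand], spread_quantile, names = FALSE)
    cand <- cand[spread[cand] >= thr]
  }
  kept <- integer(0)
  for (b in cand[order(spread[cand], decreasing = TRUE)]) {
    if (length(kept) &&
        any(abs(wavelength[kept] - wavelength[b]) < min_separation_nm)) next
    kept <- c(kept, b)
    if (length(kept) >= n_max) break
  }
  kept <- sort(kept)
  structure(list(wavelength = wavelength[kept], index = kept,
                 score = spread[kept],
                 params = list(n_max = n_max,
                               min_separation_nm = min_separation_nm,
                               spread_quantile = spread_quantile,
                               window = deriv$window,
                               polyorder = deriv$polyorder)),
            class = "effective_wavelengths")
}

#' Fixed effective wavelengths
#'
#' Bypass selection: map an explicit nm list (e.g. a previously published
#' set) to the nearest retained bands.
#'
#' @param wavelengths_nm numeric list of wavelengths.
#' @param wavelength retained axis.
#' @return an `effective_wavelengths`.
#' @export
fixed_wavelengths <- function(wavelengths_nm, wavelength) {
  idx <- sort(unique(vapply(wavelengths_nm, function(w)
    which.min(abs(wavelength - w)), integer(1))))
  structure(list(wavelength = wavelength[idx], index = idx,
                 score = rep(NA_real_, length(idx)),
                 params = list(fixed = TRUE)),
            class = "effective_wavelengths")
}

#' @export
print.effective_wavelengths <- function(x, ...) {
  cat(sprintf("<effective_wavelengths> %d bands: %s nm\n", length(x$index),
              paste(round(x$wavelength), collapse = ", ")))
  invisible(x)
}

#' Serialize an effective-wavelength set to JSON
#' @param ew an `effective_wavelengths`.
#' @param path JSON path.
#' @export
write_effective_wavelengths <- function(ew, path) {
  jsonlite::write_json(
    list(wavelength = ew$wavelength, index = ew$index, score = ew$score,
         params = ew$params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Column-subset a spectrum table to selected wavelengths
#'
#' @param table a `spectrum_table`.
#' @param ew an `effective_wavelengths` (indices into the table's axis).
#' @return a `spectrum_table` over the selected wavelengths; rows, labels
#'   and split assignment unchanged.
#' @export
subset_table <- function(table, ew) {
  idx <- ew$index
  if (any(idx < 1L | idx > ncol(table$spectra)))
    hsi_abort(sprintf("selection index outside the %d retained bands",
                      ncol(table$spectra)), "hsi_range_error")
  spectrum_table(table$spectra[, idx, drop = FALSE], table$wavelength[idx],
                 table$label, table$sample_id, table$split)
}
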