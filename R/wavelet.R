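# Daubechies-6 (12-tap, 6 vanishing moments) orthonormal scaling filter.
# Orthonormality (unit energy, orthogonal even shifts, sum sqrt(2)) is
# asserted by the test suite rather than trusted.
db6_dec_lo <- c(
   0.111540743350109550,  0.494623890398453300,  0.751133908021095800,
   0.315250351709198360, -0.226264693965440280, -0.129766867567262560,
   0.097501605587322490,  0.027522865530305727, -0.031582039318486616,
   0.000553842201161496,  0.004777257511010651, -0.001077301085308480)

# Quadrature-mirror high-pass: g[k] = (-1)^k h[L-1-k]
db6_dec_hi <- rev(db6_dec_lo) * (-1)^(seq_along(db6_dec_lo) - 1)

# One periodized analysis step: a_k = sum_m h[m] x[(2k + m) mod N].
# Periodization keeps the transform exactly orthonormal for even N >= 12,
# so synthesis is the transpose and reconstruction is exact.
dwt_step <- function(x, lo = db6_dec_lo, hi = db6_dec_hi) {
  n <- length(x)
  m <- length(lo)
  half <- n %/% 2L
  a <- d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L)) + seq_len(m) - 1L) %% n + 1L
    xs <- x[idx]
    a[k] <- sum(lo * xs)
    d[k] <- sum(hi * xs)
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo = db6_dec_lo, hi = db6_dec_hi) {
  half <- length(a)
  n <- 2L * half
  m <- length(lo)
  x <- numeric(n)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L)) + seq_len(m) - 1L) %% n + 1L
    x[idx] <- x[idx] + lo * a[k] + hi * d[k]
  }
  x
}

check_dwt_length <- function(n, level) {
  len <- n
  for (l in seq_len(level)) {
    if (len %% 2L != 0L || len < length(db6_dec_lo))
      hsi_abort(sprintf(
        "length %d cannot be decomposed to level %d with a 12-tap filter (level %d input has length %d)",
        n, level, l, len), "hsi_length_error")
    len <- len %/% 2L
  }
  invisible(TRUE)
}

#' Periodized Daubechies-6 wavelet decomposition
#'
#' @param x numeric vector; its length must be divisible by 2^level and at
#'   least 12 at every level.
#' @param level decomposition depth (default 3).
#' @return list with `approx` (coarsest approximation) and `details`
#'   (list of detail vectors, level 1 = finest).
#' @export
dwt_db6 <- function(x, level = 3L) {
  check_dwt_length(length(x), level)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, level = level, n = length(x))
}

#' @rdname dwt_db6
#' @param w a decomposition from [dwt_db6()].
#' @export
idwt_db6 <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$level)))
    a <- idwt_step(a, w$details[[l]])
  a
}

#' Wavelet denoising of a spectrum
#'
#' Daubechies-6 decomposition to `level`, soft-thresholding of detail
#' coefficients, reconstruction. The default threshold is the universal
#' (VisuShrink) rule `sigma * sqrt(2 log n)` with the noise scale
#' estimated as `median(|d1|) / 0.6745` from the finest detail level.
#'
#' By default only the finest detail level is thresholded
#' (`threshold_levels = 1`): white noise spreads its energy evenly over
#' scales, while the ~10 nm absorption features of NIR spectra live in
#' the coarser levels, so thresholding every level at the universal rate
#' systematically erases feature structure that later pixel averaging
#' could not restore. Set `threshold_levels = level` for classical
#' all-level VisuShrink. A threshold of 0 reconstructs the input to
#' round-off.
#'
#' @param x numeric spectrum.
#' @param level decomposition depth (default 3).
#' @param threshold soft threshold; `NULL` for the universal rule.
#' @param threshold_levels how many of the finest detail levels to
#'   threshold (default 1).
#' @return denoised spectrum, same length as `x`.
#' @export
wavelet_denoise <- function(x, level = 3L, threshold = NULL,
                            threshold_levels = 1L) {
  w <- dwt_db6(x, level)
  if (is.null(threshold)) {
    sigma <- median(abs(w$details[[1]])) / 0.6745
    threshold <- sigma * sqrt(2 * log(length(x)))
  }
  if (threshold > 0) {
    for (l in seq_len(min(threshold_levels, level))) {
      d <- w$details[[l]]
      w$details[[l]] <- sign(d) * pmax(abs(d) - threshold, 0)
    }
  }
  idwt_db6(w)
}
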