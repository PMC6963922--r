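#' Write and read a scene container
#'
#' The native single-file container for a scene: the raw (or corrected)
#' cube, reference frames, wavelength axis and, for synthetic scenes, the
#' ground truth. Stored as an RDS file written at run time.
#'
#' @param scene a list as produced by [render_scene()], or any list with a
#'   `$raw` or `$cube` hypercube element.
#' @param path file path (conventionally `.rds`).
#' @return `path`, invisibly (write) / the scene list (read).
#' @export
write_scene <- function(scene, path) {
  saveRDS(scene, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  if (!file.exists(path))
    hsi_abort(sprintf("no such scene file: %s", path), "hsi_format_error")
  readRDS(path)
}

#' ENVI-style cube export and import
#'
#' Writes `<base>.hdr` (plain-text header with samples/lines/bands,
#' interleave, data type and the wavelength list) and `<base>.dat`
#' (band-sequential little-endian float64), the interoperability format of
#' hyperspectral software. Doubles round-trip bit-exactly.
#'
#' @param cube a `hypercube`.
#' @param base path without extension.
#' @return `base`, invisibly.
#' @export
write_envi <- function(cube, base) {
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[1]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("kind = %s", cube$kind),
    paste0("wavelength = { ",
           paste(format(cube$wavelength, digits = 15), collapse = ", "),
           " }"))
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band-major; within a band, samples vary fastest then lines --
  # exactly R's array layout for [sample, line, band].
  writeBin(as.vector(cube$data), con, size = 8, endian = "little")
  invisible(base)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(sprintf("%s\\s*=\\s*([0-9]+)", key), txt))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  get_str <- function(key) {
    m <- regmatches(txt, regexec(sprintf("%s\\s*=\\s*([a-zA-Z]+)", key), txt))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  wl <- NA
  m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(m) == 2)
    wl <- as.numeric(strsplit(gsub("[\n ]", "", m[2]), ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = tolower(get_str("interleave") %||% "bsq"),
       kind = get_str("kind"), wavelength = wl)
}

#' @rdname write_envi
#' @export
read_envi <- function(base) {
  hdr_path <- if (file.exists(paste0(base, ".hdr"))) paste0(base, ".hdr") else base
  if (!file.exists(hdr_path))
    hsi_abort(sprintf("no ENVI header at %s", base), "hsi_format_error")
  h <- parse_envi_header(hdr_path)
  if (anyNA(c(h$samples, h$lines, h$bands)))
    hsi_abort("ENVI header missing samples/lines/bands", "hsi_format_error")
  if (length(h$wavelength) > 1 && length(h$wavelength) != h$bands)
    hsi_abort(sprintf(
      "header lists %d wavelengths but %d bands", length(h$wavelength),
      h$bands), "hsi_format_error")
  if (!h$interleave %in% c("bsq", "bil"))
    hsi_abort(sprintf("unsupported interleave '%s'", h$interleave),
              "hsi_format_error")
  size <- if (identical(h$data_type, 4L)) 4L else 8L
  dat_path <- sub("\\.hdr$", ".dat", hdr_path)
  if (!file.exists(dat_path)) dat_path <- sub("\\.hdr$", "", hdr_path)
  n <- h$samples * h$lines * h$bands
  con <- file(dat_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  if (length(v) != n)
    hsi_abort(sprintf("expected %d values, file holds %d", n, length(v)),
              "hsi_format_error")
  arr <- if (h$interleave == "bsq") {
    array(v, c(h$samples, h$lines, h$bands))
  } else { # bil: sample fastest, then band, then line
    aperm(array(v, c(h$samples, h$bands, h$lines)), c(1, 3, 2))
  }
  wl <- if (length(h$wavelength) > 1) h$wavelength
        else default_wavelengths(h$bands)
  kind <- if (identical(h$kind, "reflectance")) "reflectance" else "raw"
  hypercube(arr, wl, kind = kind)
}
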