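# Hypercube container, ENVI-style I/O, dark/white reflectance calibration,
# band trimming and ROI spectrum extraction.

#' Hypercube container
#'
#' @param data numeric array, rows x cols x bands.
#' @param wavelength band centres in nm, strictly increasing.
#' @param unit `"counts"` for raw cubes, `"percent"` for calibrated relative
#'   reflectance.
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelength, unit = c("counts", "percent")) {
  unit <- match.arg(unit)
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("cube must be a rows x cols x bands array")
  if (dim(data)[3] != length(wavelength))
    stop("wavelength length != number of bands")
  if (any(diff(wavelength) <= 0)) stop("wavelength axis must be strictly increasing")
  if (!all(is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, wavelength = as.numeric(wavelength), unit = unit),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat("<hsi_cube> ", d[1], " x ", d[2], " pixels x ", d[3], " bands (",
      round(min(x$wavelength), 1), "-", round(max(x$wavelength), 1),
      " nm), unit = ", x$unit, "\n", sep = "")
  invisible(x)
}

# coerce a reference frame (vector per band, matrix, or cube) to a full array
ref_frame_array <- function(f, dims) {
  if (inherits(f, "hsi_cube")) f <- f$data
  if (is.null(dim(f)) && length(f) == dims[3])
    f <- aperm(array(f, dims[c(3, 1, 2)]), c(2, 3, 1))
  f <- as.array(f)
  if (!identical(dim(f), dims)) stop("reference frame shape mismatch")
  f
}

#' Dark/white reflectance calibration
#'
#' Converts raw detector counts to relative reflectance in percent:
#' `I = (I0 - D) / (W - D) * 100`, elementwise, where `D` is the dark frame
#' (0 % reference) and `W` the white frame (100 % reference). No clipping is
#' applied: specular pixels may legitimately exceed 100 %.
#'
#' @param raw an [hsi_cube()] of raw counts (or a bare array with a
#'   `wavelength` attribute supplied via `wavelength`).
#' @param dark,white reference frames: per-band vectors or arrays matching
#'   the cube.
#' @param wavelength required if `raw` is a bare array.
#' @return an [hsi_cube()] with `unit = "percent"`.
#' @export
calibrate_reflectance <- function(raw, dark, white, wavelength = NULL) {
  if (!inherits(raw, "hsi_cube")) {
    if (is.null(wavelength)) stop("wavelength required for a bare array")
    raw <- hsi_cube(raw, wavelength, "counts")
  }
  dims <- dim(raw$data)
  D <- ref_frame_array(dark, dims)
  W <- ref_frame_array(white, dims)
  denom <- W - D
  bad <- which(apply(denom <= 0, 3, any))
  if (length(bad))
    stop("white reference does not exceed dark reference at band(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (", round(raw$wavelength[bad[1]], 1), " nm)")
  hsi_cube((raw$data - D) / denom * 100, raw$wavelength, "percent")
}

#' Trim to an analysis wavelength window
#'
#' Retains bands with `low <= lambda <= high` (inclusive), preserving order.
#' Works on both cubes and spectrum sets; trimming is idempotent.
#'
#' @param x an [hsi_cube()] or [spectrum_set()].
#' @param low,high window endpoints in nm.
#' @return same kind of object restricted to the window.
#' @export
trim_bands <- function(x, low, high) UseMethod("trim_bands")

trim_idx <- function(wavelength, low, high) {
  keep <- which(wavelength >= low & wavelength <= high)
  if (!length(keep))
    stop("no bands inside [", low, ", ", high, "] nm")
  keep
}

#' @export
trim_bands.hsi_cube <- function(x, low, high) {
  keep <- trim_idx(x$wavelength, low, high)
  hsi_cube(x$data[, , keep, drop = FALSE], x$wavelength[keep], x$unit)
}

#' @export
trim_bands.spectrum_set <- function(x, low, high) {
  keep <- trim_idx(x$wavelength, low, high)
  x[, keep]
}

#' Mean ROI spectrum
#'
#' Per-band arithmetic mean over the pixels flagged true in the mask — one
#' specimen's representative spectrum.
#'
#' @param cube an [hsi_cube()].
#' @param mask logical matrix matching the cube's spatial grid.
#' @return numeric vector of length `bands`, named by wavelength.
#' @export
extract_roi_mean <- function(cube, mask) {
  stopifnot(inherits(cube, "hsi_cube"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(cube$data)[1:2]))
    stop("mask shape does not match cube")
  if (!any(mask)) stop("ROI mask is empty")
  flat <- matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3])
  out <- colMeans(flat[as.vector(mask), , drop = FALSE])
  names(out) <- format(cube$wavelength, trim = TRUE)
  out
}

#' Threshold background mask
#'
#' Flags foreground pixels whose reflectance at a reference band exceeds a
#' threshold — a stand-in for manual ROI definition on a dark background
#' plate.
#'
#' @param cube calibrated [hsi_cube()].
#' @param threshold reflectance threshold in %.
#' @param reference_nm band (nearest match) at which to threshold.
#' @return logical matrix, `TRUE` = foreground.
#' @export
background_mask <- function(cube, threshold = 10, reference_nm = 800) {
  stopifnot(inherits(cube, "hsi_cube"))
  band <- which.min(abs(cube$wavelength - reference_nm))
  cube$data[, , band] > threshold
}

#' Write / read an ENVI-style cube
#'
#' Plain-text `.hdr` plus flat binary (band-interleaved-by-line, 64-bit
#' little-endian float by default); `wavelength`, `interleave` and
#' `data type` header fields are honoured on read.
#'
#' @param cube an [hsi_cube()].
#' @param path base path; `.hdr` and `.img` are appended.
#' @return `write_envi` returns `path` invisibly; `read_envi` an
#'   [hsi_cube()].
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bil",
           "byte order = 0",
           paste0("wavelength units = nm"),
           paste0("wavelength = { ",
                  paste(format(cube$wavelength, trim = TRUE, digits = 10),
                        collapse = ", "), " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL: line-major, within each line all bands, within each band the samples
  con <- file(paste0(path, ".img"), "wb")
  on.exit(close(con))
  for (i in seq_len(d[1]))
    for (b in seq_len(d[3]))
      writeBin(as.double(cube$data[i, , b]), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_envi
#' @param unit unit to stamp on the cube read back.
#' @export
read_envi <- function(path, unit = "percent") {
  hdr_lines <- readLines(paste0(path, ".hdr"))
  hdr <- paste(hdr_lines, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, "\\s*=\\s*[^\n{]+"), hdr))
    if (!length(m)) stop("missing ENVI header field: ", name)
    trimws(sub(".*=", "", m))
  }
  samples <- as.integer(get_field("samples"))
  lines_n <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  wl_txt <- regmatches(hdr, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", hdr))
  if (!length(wl_txt)) stop("missing wavelength list in ENVI header")
  wavelength <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_txt), ",")[[1]])
  vals <- readBin(paste0(path, ".img"), "double", n = samples * lines_n * bands,
                  size = size, endian = "little")
  cube <- array(NA_real_, c(lines_n, samples, bands))
  if (interleave == "bil") {
    arr <- array(vals, c(samples, bands, lines_n))   # fastest index first
    cube <- aperm(arr, c(3, 1, 2))
  } else if (interleave == "bsq") {
    arr <- array(vals, c(samples, lines_n, bands))
    cube <- aperm(arr, c(2, 1, 3))
  } else if (interleave == "bip") {
    arr <- array(vals, c(bands, samples, lines_n))
    cube <- aperm(arr, c(3, 2, 1))
  } else stop("unsupported interleave: ", interleave)
  hsi_cube(cube, wavelength, unit)
}
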