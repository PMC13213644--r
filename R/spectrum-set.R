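#' Spectrum set container
#'
#' Bundles a samples x bands reflectance (or pre-processed) matrix with its
#' wavelength axis, per-sample class labels, and optional reference analyte
#' concentrations. This is the object most of the pipeline consumes and
#' returns.
#'
#' @param spectra numeric matrix, samples in rows, bands in columns.
#' @param wavelength numeric vector of band centres in nm, strictly
#'   increasing, length `ncol(spectra)`.
#' @param label optional factor/character of per-sample class labels.
#' @param concentration optional numeric matrix (samples x analytes) of
#'   reference concentrations; column names identify the analytes.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, wavelength, label = NULL, concentration = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) != ncol(spectra))
    stop("wavelength length (", length(wavelength), ") != number of bands (",
         ncol(spectra), ")")
  if (any(diff(wavelength) <= 0))
    stop("wavelength axis must be strictly increasing")
  if (!is.null(label)) {
    label <- as.factor(label)
    if (length(label) != nrow(spectra))
      stop("label length != number of samples")
  }
  if (!is.null(concentration)) {
    concentration <- as.matrix(concentration)
    if (nrow(concentration) != nrow(spectra))
      stop("concentration rows != number of samples")
  }
  structure(
    list(spectra = spectra, wavelength = wavelength,
         label = label, concentration = concentration),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$spectra), " samples x ", ncol(x$spectra),
      " bands (", round(min(x$wavelength), 1), "-",
      round(max(x$wavelength), 1), " nm)\n", sep = "")
  if (!is.null(x$label)) {
    tab <- table(x$label)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$concentration))
    cat("  analytes:", paste(colnames(x$concentration), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$spectra)

#' Subset a spectrum set by sample and/or band
#'
#' @param x a `spectrum_set`.
#' @param i sample indices (optional).
#' @param j band indices (optional).
#' @param ... ignored.
#' @return A `spectrum_set` with the selected samples/bands.
#' @export
`[.spectrum_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$spectra))
  if (missing(j)) j <- seq_len(ncol(x$spectra))
  spectrum_set(x$spectra[i, j, drop = FALSE], x$wavelength[j],
               label = if (!is.null(x$label)) x$label[i],
               concentration = if (!is.null(x$concentration))
                 x$concentration[i, , drop = FALSE])
}

#' Write / read a spectrum set as CSV
#'
#' One sample per row; the wavelength axis forms the spectral column names
#' (`wl_<nm>`), with leading `label` and `conc_<analyte>` columns when
#' present.
#'
#' @param x a `spectrum_set`.
#' @param path file path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   a `spectrum_set`.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  df <- data.frame(row.names = seq_len(nrow(x$spectra)))
  if (!is.null(x$label)) df$label <- as.character(x$label)
  if (!is.null(x$concentration)) {
    cn <- colnames(x$concentration)
    if (is.null(cn)) cn <- paste0("analyte", seq_len(ncol(x$concentration)))
    for (k in seq_along(cn)) df[[paste0("conc_", cn[k])]] <- x$concentration[, k]
  }
  sp <- as.data.frame(x$spectra)
  names(sp) <- paste0("wl_", format(x$wavelength, trim = TRUE, digits = 10))
  utils::write.csv(cbind(df, sp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  wavelength <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  conc_cols <- grep("^conc_", names(df))
  conc <- NULL
  if (length(conc_cols)) {
    conc <- as.matrix(df[conc_cols])
    colnames(conc) <- sub("^conc_", "", names(df)[conc_cols])
  }
  spectrum_set(as.matrix(df[wl_cols]), wavelength,
               label = if ("label" %in% names(df)) df$label,
               concentration = conc)
}
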