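# Spectral pre-processing: standard normal variate, Savitzky-Golay
# smoothing/derivatives, and the named chains used for model screening
# (Raw, SG, SNV, 1stD, 2ndD, 1stD-SG, 2ndD-SG).

#' Standard normal variate
#'
#' Centres and scales each spectrum (row) to zero mean and unit standard
#' deviation (sample SD, n-1 denominator), removing additive offsets and
#' multiplicative surface-scatter effects.
#'
#' @param spectra samples x bands matrix (or a [spectrum_set()]).
#' @return same shape as the input.
#' @export
snv <- function(spectra) {
  if (inherits(spectra, "spectrum_set")) {
    spectra$spectra <- snv(spectra$spectra)
    return(spectra)
  }
  x <- as.matrix(spectra)
  if (ncol(x) < 2) stop("SNV needs at least 2 bands")
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0))
    stop("constant spectrum (zero SD) in row(s) ",
         paste(which(s == 0), collapse = ", "))
  (x - m) / s
}

#' Savitzky-Golay filtering and derivatives
#'
#' Per-row local polynomial convolution; `deriv = 0` smooths, `deriv = 1`/`2`
#' estimate first/second derivatives per band-index step. Edge points are
#' handled by the polynomial fits on the boundary windows (no signal
#' shortening).
#'
#' @param spectra samples x bands matrix (or [spectrum_set()]).
#' @param window odd filter length, `window > polyorder`.
#' @param polyorder polynomial degree, `>= deriv`.
#' @param deriv derivative order, 0, 1 or 2.
#' @return same shape as the input.
#' @export
sg_filter <- function(spectra, window = 11, polyorder = 3, deriv = 0) {
  if (inherits(spectra, "spectrum_set")) {
    spectra$spectra <- sg_filter(spectra$spectra, window, polyorder, deriv)
    return(spectra)
  }
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("window must exceed polyorder")
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("polyorder must be >= deriv")
  x <- as.matrix(spectra)
  if (ncol(x) < window) stop("fewer bands than the filter window")
  t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window, m = deriv))
}

#' Pre-processing chain
#'
#' An ordered list of steps from SNV and SG smoothing/derivative filters.
#' The standard chain names map as: `Raw` (identity), `SG` (smoothing),
#' `SNV`, `1stD`, `2ndD` (SG derivatives), `1stD-SG` and `2ndD-SG`
#' (derivative followed by smoothing, per the hyphen order).
#'
#' @param name one of the standard chain names, or `NULL` when `steps` is
#'   given explicitly.
#' @param steps explicit list of steps, each `list(kind = "snv")` or
#'   `list(kind = "sg", window =, polyorder =, deriv =)`.
#' @param window,polyorder SG settings used by the named chains.
#' @return object of class `preprocess_chain`.
#' @export
preprocess_chain <- function(name = "Raw", steps = NULL,
                             window = 11, polyorder = 3) {
  sg <- function(d) list(kind = "sg", window = window,
                         polyorder = polyorder, deriv = d)
  if (is.null(steps)) {
    steps <- switch(name,
      "Raw" = list(),
      "SG" = list(sg(0)),
      "SNV" = list(list(kind = "snv")),
      "1stD" = list(sg(1)),
      "2ndD" = list(sg(2)),
      "1stD-SG" = list(sg(1), sg(0)),
      "2ndD-SG" = list(sg(2), sg(0)),
      stop("unknown chain name: ", name))
  }
  for (s in steps)
    if (!s$kind %in% c("snv", "sg")) stop("unknown step kind: ", s$kind)
  structure(list(name = name, steps = steps), class = "preprocess_chain")
}

#' Standard chain names
#' @return character vector of the seven screening chains.
#' @export
standard_chains <- function() c("Raw", "SG", "SNV", "1stD", "2ndD",
                                "1stD-SG", "2ndD-SG")

#' Apply a pre-processing chain
#'
#' Steps are applied left to right. All steps are row-local: permuting
#' samples permutes the output identically.
#'
#' @param spectra samples x bands matrix or [spectrum_set()].
#' @param chain a [preprocess_chain()] or a standard chain name.
#' @return same shape as the input.
#' @export
apply_chain <- function(spectra, chain) {
  if (is.character(chain)) chain <- preprocess_chain(chain)
  stopifnot(inherits(chain, "preprocess_chain"))
  for (s in chain$steps) {
    spectra <- switch(s$kind,
      snv = snv(spectra),
      sg = sg_filter(spectra, s$window, s$polyorder, s$deriv))
  }
  spectra
}
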