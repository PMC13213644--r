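# Pixel-wise concentration mapping: apply a trained calibration model to
# every foreground pixel of a reflectance cube and render the predicted
# analyte distribution as a red (high) to black (low) pseudo-colour image.

#' Predict a pixel-wise concentration map
#'
#' Every foreground pixel's spectrum passes through the model's stored
#' pre-processing chain, band subset and learner; background pixels carry
#' no prediction.
#'
#' @param cube calibrated [hsi_cube()] whose band axis matches the model's.
#' @param model a regression `trained_predictor`.
#' @param mask logical foreground mask (e.g. from [background_mask()]).
#' @return object of class `concentration_map`: `values` (matrix, NA on
#'   background), `mask`, `wavelength`, `analyte` model kind.
#' @export
predict_pixel_map <- function(cube, model, mask) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(model, "trained_predictor"))
  if (model$task != "regression") stop("model must be a regression predictor")
  if (!is.null(model$wavelength) &&
      (length(cube$wavelength) != length(model$wavelength) ||
       any(abs(cube$wavelength - model$wavelength) > 1e-8)))
    stop("band axis mismatch between cube and model")
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(cube$data)[1:2])) stop("mask shape mismatch")
  if (!any(mask)) stop("empty foreground")
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  fg <- which(as.vector(mask))
  pred <- predict(model, flat[fg, , drop = FALSE])
  values <- matrix(NA_real_, d[1], d[2])
  values[fg] <- pred
  structure(list(values = values, mask = mask, wavelength = cube$wavelength,
                 model_kind = model$kind),
            class = "concentration_map")
}

#' @export
print.concentration_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<concentration_map> %d x %d px, %d foreground; range %.4g-%.4g\n",
              nrow(x$values), ncol(x$values), sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Render a concentration map to PNG
#'
#' Linear red-to-black gradient: the scale maximum renders pure red, the
#' minimum and all background pixels render black. Predictions below the
#' scale minimum (e.g. negative model output) clamp to the black endpoint;
#' the numeric grid is left untouched. A horizontal colour bar with the
#' scale bounds is written alongside.
#'
#' @param map a `concentration_map`.
#' @param file output PNG path.
#' @param bounds optional length-2 scale bounds; default foreground
#'   min/max. A degenerate scale (min = max) renders single-colour with a
#'   warning.
#' @param colorbar_file optional path for the colour-bar PNG.
#' @return invisibly, the rendered rows x cols x 3 RGB array.
#' @export
render_map <- function(map, file, bounds = NULL, colorbar_file = NULL) {
  stopifnot(inherits(map, "concentration_map"))
  v <- map$values
  fg <- map$mask & !is.na(v)
  if (is.null(bounds)) bounds <- range(v[fg])
  if (!all(is.finite(bounds))) stop("non-finite scale bounds")
  degenerate <- bounds[2] <= bounds[1]
  if (degenerate) warning("degenerate colour scale (min = max): single-colour render")
  intensity <- matrix(0, nrow(v), ncol(v))
  if (degenerate) {
    intensity[fg] <- 1
  } else {
    intensity[fg] <- pmin(pmax((v[fg] - bounds[1]) / diff(bounds), 0), 1)
  }
  rgb_arr <- array(0, c(nrow(v), ncol(v), 3))
  rgb_arr[, , 1] <- intensity                       # red channel only
  png::writePNG(rgb_arr, file)
  if (!is.null(colorbar_file)) {
    ramp <- seq(0, 1, length.out = 256)
    bar <- array(0, c(24, 256, 3))
    bar[, , 1] <- matrix(ramp, 24, 256, byrow = TRUE)
    png::writePNG(bar, colorbar_file)
  }
  invisible(rgb_arr)
}

#' Map summary over a region
#'
#' Mean predicted concentration over an ROI, reported next to the model's
#' prediction of the ROI-mean spectrum. The two coincide only for linear
#' models, so both are returned without any equality claim.
#'
#' @param map a `concentration_map`.
#' @param cube the calibrated cube the map came from.
#' @param model the predictor used.
#' @param roi logical matrix selecting the region (foreground pixels only
#'   are used).
#' @return list with `mean_of_predictions` and `prediction_of_mean`.
#' @export
map_roi_summary <- function(map, cube, model, roi) {
  roi <- as.matrix(roi) & map$mask
  if (!any(roi)) stop("ROI has no foreground pixels")
  mean_spec <- extract_roi_mean(cube, roi)
  list(mean_of_predictions = mean(map$values[roi]),
       prediction_of_mean = unname(predict(model, matrix(mean_spec, 1))))
}
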