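# model trained on normally varying spectra; cube built from low-spread
# profiles so any planted spatial gradient dominates pixel noise
map_fixture <- function(gradient = NULL, conc_sdlog = 0.02, noise_sd = 0.02,
                        seed = 1, m = 14) {
  train <- simulate_spectrum_set(sim_config(
    samples_per_class = c(tuberous = 40, taproot = 15, old = 15),
    seed = seed + 100))
  model <- lssvm_train(train, "norisoboldine", chain = "SNV")
  cfg <- sim_config(samples_per_class = c(tuberous = 2, taproot = 2, old = 2),
                    noise_sd = noise_sd, scatter_sdlog = 0.01,
                    scatter_add_sd = 0.1, seed = seed)
  cp <- class_profiles()
  for (nm in names(cp)) cp[[nm]]$conc_sdlog <- rep(conc_sdlog, 3)
  layout <- matrix("", m, m)
  layout[2:(m - 1), 2:(m - 1)] <- "tuberous"
  hc <- simulate_hypercube(cfg, layout, classes = cp, gradient = gradient)
  cube <- calibrate_reflectance(hsi_cube(hc$raw, hc$wavelength),
                                hc$dark, hc$white)
  list(cube = cube, model = model, mask = background_mask(cube),
       truth = hc$truth)
}

test_that("a spatially uniform cube yields a uniform concentration map", {
  nb <- 270
  wl <- default_wavelength(nb)
  s <- small_spectrum_set(seed = 5)
  model <- lssvm_train(s, "norisoboldine", chain = "SNV")
  spec <- s$spectra[1, ]
  cube <- hsi_cube(aperm(array(spec, c(nb, 6, 6)), c(2, 3, 1)), wl, "percent")
  mask <- matrix(TRUE, 6, 6)
  cm <- predict_pixel_map(cube, model, mask)
  expect_equal(max(cm$values) - min(cm$values), 0, tolerance = 1e-10)
})

test_that("background pixels carry no prediction and are excluded from statistics", {
  fx <- map_fixture(seed = 2)
  cm <- predict_pixel_map(fx$cube, fx$model, fx$mask)
  expect_true(all(is.na(cm$values[!fx$mask])))
  expect_true(all(is.finite(cm$values[fx$mask])))
  expect_error(predict_pixel_map(fx$cube, fx$model, matrix(FALSE, 14, 14)),
               "empty foreground")
})

test_that("a planted left-to-right gradient appears in the column means", {
  # gradient kept inside the calibrated concentration range: kernel models
  # flatten once they extrapolate beyond the training support
  fx <- map_fixture(gradient = c(0.5, 1.1), seed = 3)
  cm <- predict_pixel_map(fx$cube, fx$model, fx$mask)
  colm <- colMeans(cm$values, na.rm = TRUE)[2:13]
  expect_true(all(diff(colm) > 0))
})

test_that("planted high-concentration regions predict higher than low regions", {
  for (seed in 1:5) {
    fx <- map_fixture(gradient = c(0.5, 1.5), seed = seed)
    cm <- predict_pixel_map(fx$cube, fx$model, fx$mask)
    left <- mean(cm$values[, 2:5], na.rm = TRUE)
    right <- mean(cm$values[, 10:13], na.rm = TRUE)
    expect_gt(right, left)
  }
})

test_that("rendering maps extremes to red and black and is byte-deterministic", {
  fx <- map_fixture(gradient = c(0.5, 1.5), seed = 4)
  cm <- predict_pixel_map(fx$cube, fx$model, fx$mask)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  arr <- render_map(cm, f1, colorbar_file = tempfile(fileext = ".png"))
  render_map(cm, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  v <- cm$values
  imax <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  imin <- which(v == min(v, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(arr[imax[1], imax[2], ], c(1, 0, 0))   # pure red
  expect_equal(arr[imin[1], imin[2], ], c(0, 0, 0))   # black
  expect_equal(arr[1, 1, ], c(0, 0, 0))               # background black
  # degenerate scale warns
  flat <- cm
  flat$values[fx$mask] <- 1
  expect_warning(render_map(flat, tempfile(fileext = ".png")), "degenerate")
})

test_that("ROI mean prediction equals prediction of the ROI mean for a linear model", {
  s <- small_spectrum_set(seed = 6)
  linear_model <- lssvm_train(s, "norisoboldine", chain = "Raw",
                              config = lssvm_config(kernel = "linear"))
  fx <- map_fixture(seed = 7)
  cm <- predict_pixel_map(fx$cube, linear_model, fx$mask)
  roi <- matrix(FALSE, 14, 14); roi[4:8, 4:8] <- TRUE
  s1 <- map_roi_summary(cm, fx$cube, linear_model, roi)
  expect_equal(s1$mean_of_predictions, s1$prediction_of_mean,
               tolerance = 1e-8)
  # nonlinear model: both values reported, no equality claim
  cm_rbf <- predict_pixel_map(fx$cube, fx$model, fx$mask)
  s2 <- map_roi_summary(cm_rbf, fx$cube, fx$model, roi)
  expect_true(is.finite(s2$mean_of_predictions))
  expect_true(is.finite(s2$prediction_of_mean))
})
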