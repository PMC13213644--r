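# Synthetic-data generators: three root classes (tuberous / taproot / old),
# three marker analytes, reflectance model
#   R(lambda) = a * B_c(lambda) * exp(-sum_k c_k eps_k(lambda)) + b + noise
# truncated to [0, 100] — Beer-Lambert absorption on a class baseline with
# multiplicative/additive scatter, the structure SNV and derivative
# pre-processing are designed to remove.

# run expr under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Default band grid
#'
#' @param n_bands number of bands.
#' @param range wavelength range in nm (inclusive endpoints).
#' @return numeric vector of band centres.
#' @export
default_wavelength <- function(n_bands = 270, range = c(427, 994)) {
  seq(range[1], range[2], length.out = n_bands)
}

gaussian_peaks <- function(wavelength, centers, widths, heights) {
  eps <- numeric(length(wavelength))
  for (k in seq_along(centers))
    eps <- eps + heights[k] * exp(-((wavelength - centers[k]) / widths[k])^2)
  eps
}

#' Analyte absorptivity library
#'
#' Builds the per-analyte absorptivity profiles eps_k(lambda) used by the
#' reflectance model, each a sum of Gaussian peaks strictly inside the band
#' window. Peak positions sit mostly in the NIR overtone region (720-994 nm)
#' with one visible-range peak each, emulating O-H / C-H overtone absorption
#' plus pigment colour. The peak-centre band indices are recorded as ground
#' truth for wavelength-selector recovery tests.
#'
#' @param wavelength band grid in nm.
#' @return list with `names`, `epsilon` (bands x analytes matrix, all >= 0),
#'   and `peak_bands` (list of band indices nearest each peak centre).
#' @export
analyte_library <- function(wavelength = default_wavelength()) {
  spec <- list(
    norisoboldine = list(centers = c(520, 760, 930), widths = c(30, 22, 26),
                         heights = c(0.10, 0.22, 0.16)),
    linderane     = list(centers = c(585, 820, 960), widths = c(28, 24, 22),
                         heights = c(0.12, 0.30, 0.20)),
    lindenenol    = list(centers = c(478, 700, 880), widths = c(26, 24, 25),
                         heights = c(0.09, 0.18, 0.24)))
  eps <- sapply(spec, function(s)
    gaussian_peaks(wavelength, s$centers, s$widths, s$heights))
  peak_bands <- lapply(spec, function(s)
    vapply(s$centers, function(ctr) which.min(abs(wavelength - ctr)), 1L))
  structure(list(names = names(spec), epsilon = eps, peak_bands = peak_bands,
                 wavelength = wavelength),
            class = "analyte_library")
}

#' Root-class reflectance and concentration profiles
#'
#' Baseline reflectance curves rise from the visible into the NIR plateau;
#' the old-root baseline is strictly below the tuberous and taproot baselines
#' at every band, and median concentrations of all three analytes are highest
#' in the tuberous class (the accepted medicinal material).
#'
#' @param wavelength band grid in nm.
#' @return named list of class profiles, each with `baseline` (% reflectance)
#'   and `conc_meanlog` / `conc_sdlog` (log-normal parameters per analyte).
#' @export
class_profiles <- function(wavelength = default_wavelength()) {
  s <- 28 + 48 / (1 + exp(-(wavelength - 620) / 70))   # rise to NIR plateau
  vis_tint <- 3 * exp(-((wavelength - 500) / 60)^2)    # taproot colour bump
  med <- list(tuberous = c(norisoboldine = 1.60, linderane = 0.45, lindenenol = 1.30),
              taproot  = c(norisoboldine = 0.55, linderane = 0.16, lindenenol = 0.50),
              old      = c(norisoboldine = 0.50, linderane = 0.14, lindenenol = 0.45))
  base <- list(tuberous = s, taproot = 0.98 * s + vis_tint, old = 0.78 * s)
  out <- lapply(names(med), function(cl)
    list(label = cl, baseline = base[[cl]],
         conc_meanlog = log(med[[cl]]), conc_sdlog = rep(0.25, 3)))
  names(out) <- names(med)
  out
}

#' Simulation configuration
#'
#' @param n_bands number of spectral bands (default 270).
#' @param range wavelength window in nm (default 427-994).
#' @param samples_per_class named counts for tuberous/taproot/old (defaults
#'   mirror an unbalanced field collection: 87/30/30).
#' @param scatter_sdlog sdlog of the multiplicative scatter factor `a`
#'   (log-normal, median 1).
#' @param scatter_add_sd SD of the additive scatter offset `b` (% units).
#' @param noise_sd per-band instrument noise SD (% units).
#' @param seed integer; fully determines all generated outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bands = 270, range = c(427, 994),
                       samples_per_class = c(tuberous = 87, taproot = 30, old = 30),
                       scatter_sdlog = 0.08, scatter_add_sd = 0.8,
                       noise_sd = 0.15, seed = 1) {
  if (n_bands < 10) stop("n_bands must be >= 10")
  if (any(samples_per_class < 2)) stop("need >= 2 samples per class")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (scatter_add_sd < 0) stop("scatter_add_sd must be non-negative")
  structure(list(n_bands = n_bands, range = range,
                 samples_per_class = samples_per_class,
                 scatter_sdlog = scatter_sdlog, scatter_add_sd = scatter_add_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

# one reflectance spectrum from the generative model (no truncation)
model_reflectance <- function(baseline, epsilon, conc, a, b) {
  a * baseline * exp(-drop(epsilon %*% conc)) + b
}

#' Simulate a labelled spectrum set
#'
#' Draws per-sample analyte concentrations from the class log-normal
#' distributions, applies Beer-Lambert attenuation to the class baseline,
#' adds multiplicative/additive scatter and band noise, and truncates to
#' the physical range [0, 100] %.
#'
#' @param config a [sim_config()].
#' @param classes class profiles from [class_profiles()].
#' @param library analyte library from [analyte_library()].
#' @return a [spectrum_set()] with labels and true concentrations.
#' @export
simulate_spectrum_set <- function(config = sim_config(),
                                  classes = NULL, library = NULL) {
  stopifnot(inherits(config, "sim_config"))
  wl <- default_wavelength(config$n_bands, config$range)
  if (is.null(classes)) classes <- class_profiles(wl)
  if (is.null(library)) library <- analyte_library(wl)
  for (cl in classes)
    if (any(cl$baseline <= 0)) stop("class baseline must be strictly positive")
  with_seed(config$seed, {
    rows <- list(); labs <- character(0); concs <- list()
    for (cl_name in names(config$samples_per_class)) {
      prof <- classes[[cl_name]]
      n <- config$samples_per_class[[cl_name]]
      for (i in seq_len(n)) {
        conc <- stats::rlnorm(3, prof$conc_meanlog, prof$conc_sdlog)
        a <- stats::rlnorm(1, 0, config$scatter_sdlog)
        b <- stats::rnorm(1, 0, config$scatter_add_sd)
        r <- model_reflectance(prof$baseline, library$epsilon, conc, a, b) +
          stats::rnorm(config$n_bands, 0, config$noise_sd)
        rows[[length(rows) + 1L]] <- pmin(pmax(r, 0), 100)
        labs <- c(labs, cl_name)
        concs[[length(concs) + 1L]] <- conc
      }
    }
    conc_mat <- do.call(rbind, concs)
    colnames(conc_mat) <- library$names
    spectrum_set(do.call(rbind, rows), wl, label = labs, concentration = conc_mat)
  })
}

#' Simulate a raw hypercube with reference frames
#'
#' Builds a spatial class layout into a raw-count cube via
#' `raw = D + (W - D) * R / 100`, so that dark/white calibration inverts the
#' construction exactly. Background pixels carry a distinct near-dark
#' constant reflectance so threshold masking is testable.
#'
#' @param config a [sim_config()].
#' @param layout character matrix of class names; `NA` or `""` marks
#'   background pixels.
#' @param classes,library as in [simulate_spectrum_set()].
#' @param gradient optional length-2 numeric: multiply concentrations by a
#'   left-to-right linear ramp between these factors (planted spatial
#'   gradient for mapping tests).
#' @param background_reflectance constant background reflectance in %.
#' @return list with `raw` (rows x cols x bands), `dark`, `white` (same
#'   shape), `wavelength`, `truth` (rows x cols x analytes true
#'   concentrations, NA on background), and `class_map`.
#' @export
simulate_hypercube <- function(config = sim_config(), layout,
                               classes = NULL, library = NULL,
                               gradient = NULL,
                               background_reflectance = 2.5) {
  stopifnot(inherits(config, "sim_config"))
  layout <- as.matrix(layout)
  wl <- default_wavelength(config$n_bands, config$range)
  if (is.null(classes)) classes <- class_profiles(wl)
  if (is.null(library)) library <- analyte_library(wl)
  nr <- nrow(layout); nc <- ncol(layout); nb <- config$n_bands
  dark_spec <- 90 + 25 * exp(-((wl - 550) / 200)^2)       # detector counts
  white_spec <- 3200 + 600 * exp(-((wl - 700) / 250)^2)
  if (any(white_spec <= dark_spec)) stop("white frame must exceed dark frame")
  dark <- aperm(array(dark_spec, c(nb, nr, nc)), c(2, 3, 1))
  white <- aperm(array(white_spec, c(nb, nr, nc)), c(2, 3, 1))
  raw <- array(NA_real_, c(nr, nc, nb))
  truth <- array(NA_real_, c(nr, nc, 3),
                 dimnames = list(NULL, NULL, library$names))
  with_seed(config$seed, {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      cl <- layout[i, j]
      if (is.na(cl) || !nzchar(cl)) {
        r <- rep(background_reflectance, nb)
      } else {
        prof <- classes[[cl]]
        if (is.null(prof)) stop("unknown class in layout: ", cl)
        conc <- stats::rlnorm(3, prof$conc_meanlog, prof$conc_sdlog)
        if (!is.null(gradient))
          conc <- conc * (gradient[1] + (gradient[2] - gradient[1]) *
                            (j - 1) / max(nc - 1, 1))
        a <- stats::rlnorm(1, 0, config$scatter_sdlog)
        b <- stats::rnorm(1, 0, config$scatter_add_sd)
        r <- model_reflectance(prof$baseline, library$epsilon, conc, a, b) +
          stats::rnorm(nb, 0, config$noise_sd)
        r <- pmin(pmax(r, 0), 100)
        truth[i, j, ] <- conc
      }
      raw[i, j, ] <- dark[i, j, ] + (white[i, j, ] - dark[i, j, ]) * r / 100
    }
  })
  list(raw = raw, dark = dark, white = white, wavelength = wl,
       truth = truth, class_map = layout)
}

#' Simulate a metabolomics feature table with planted differentials
#'
#' Intensities are log-normal around per-feature base means; a chosen set of
#' features is planted with a between-group mean ratio `fc` (the up-regulated
#' group cycles through the three root classes). QC samples are drawn around
#' the grand profile with reduced variance.
#'
#' @param n_per_group samples per root-class group.
#' @param n_features total features.
#' @param n_differential number of planted differential features.
#' @param fc planted fold change (> 1) between the up group and the others.
#' @param n_qc number of pooled-QC samples.
#' @param sdlog_within within-group biological+technical log-scale SD.
#' @param seed integer seed.
#' @return list of class `feature_table`: `intensity` (features x samples),
#'   `group` factor (levels tuberous/taproot/old/QC), `planted` indices,
#'   `planted_group` the up-regulated group per planted feature.
#' @export
simulate_feature_table <- function(n_per_group = 16, n_features = 600,
                                   n_differential = 30, fc = 4,
                                   n_qc = 5, sdlog_within = 0.35, seed = 1) {
  if (fc <= 1) stop("fc must be > 1")
  if (n_differential > n_features) stop("n_differential > n_features")
  groups <- c("tuberous", "taproot", "old")
  with_seed(seed, {
    base <- stats::rlnorm(n_features, log(3e4), 1)
    gmean <- matrix(base, n_features, 3)
    colnames(gmean) <- groups
    planted <- sort(sample.int(n_features, n_differential))
    up <- groups[(seq_len(n_differential) - 1L) %% 3L + 1L]
    for (k in seq_len(n_differential))
      gmean[planted[k], up[k]] <- gmean[planted[k], up[k]] * fc
    n_tot <- 3 * n_per_group + n_qc
    intensity <- matrix(NA_real_, n_features, n_tot)
    group <- character(n_tot)
    col <- 0L
    for (g in groups) for (i in seq_len(n_per_group)) {
      col <- col + 1L
      # meanlog set so the arithmetic group mean equals gmean
      intensity[, col] <- stats::rlnorm(n_features,
                                        log(gmean[, g]) - sdlog_within^2 / 2,
                                        sdlog_within)
      group[col] <- g
    }
    pooled <- rowMeans(gmean)
    for (i in seq_len(n_qc)) {
      col <- col + 1L
      intensity[, col] <- stats::rlnorm(n_features,
                                        log(pooled) - (sdlog_within / 3)^2 / 2,
                                        sdlog_within / 3)
      group[col] <- "QC"
    }
    rownames(intensity) <- paste0("F", seq_len(n_features))
    colnames(intensity) <- paste0("S", seq_len(n_tot))
    structure(list(intensity = intensity,
                   group = factor(group, levels = c(groups, "QC")),
                   planted = planted, planted_group = up, fc = fc),
              class = "feature_table")
  })
}

#' Planted-band regression set for wavelength-selector benchmarks
#'
#' Generates a spectra-like design matrix with mild inter-band correlation
#' and a response carried by a known sparse set of bands, the ground truth
#' against which selector recovery is scored.
#'
#' @param n_samples,n_bands design size.
#' @param n_informative number of planted informative bands.
#' @param coef common regression weight of the planted bands.
#' @param noise_sd SD of the response noise (response signal has SD about
#'   `coef * sqrt(n_informative)`).
#' @param smooth add neighbouring-band correlation (moving average across
#'   bands). Set `FALSE` for benchmarks scored on exact band indices, where
#'   correlated neighbours would alias the planted bands.
#' @param seed integer seed.
#' @return list with `X`, `y`, `planted` (band indices), `wavelength`.
#' @export
simulate_planted_bands <- function(n_samples = 100, n_bands = 270,
                                   n_informative = 10, coef = 1,
                                   noise_sd = 0.5, smooth = TRUE, seed = 1) {
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * n_bands), n_samples, n_bands)
    X <- Z
    if (smooth && n_bands >= 3)
      X[, 2:(n_bands - 1)] <- (Z[, 1:(n_bands - 2)] + Z[, 2:(n_bands - 1)] +
                                 Z[, 3:n_bands]) / sqrt(3)
    gap <- max(floor(n_bands / (n_informative + 1)), 1L)
    planted <- gap * seq_len(n_informative)
    y <- drop(X[, planted, drop = FALSE] %*% rep(coef, n_informative)) +
      stats::rnorm(n_samples, 0, noise_sd)
    list(X = X, y = y, planted = planted,
         wavelength = default_wavelength(n_bands))
  })
}
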