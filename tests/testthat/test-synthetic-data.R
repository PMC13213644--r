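test_that("zero concentration, unit scatter and no noise reproduce the class baseline", {
  cfg <- clean_config(samples_per_class = c(tuberous = 2, taproot = 2, old = 2))
  wl <- default_wavelength()
  cp <- zero_conc_profiles(wl)
  s <- simulate_spectrum_set(cfg, classes = cp)
  for (i in seq_len(nrow(s$spectra))) {
    cl <- as.character(s$label[i])
    expect_equal(unname(s$spectra[i, ]), unname(cp[[cl]]$baseline),
                 tolerance = 1e-12)
  }
  expect_true(all(s$concentration == 0))
})

test_that("SNV removes multiplicative and additive scatter exactly at zero noise", {
  cfg <- sim_config(samples_per_class = c(tuberous = 6, taproot = 2, old = 2),
                    scatter_sdlog = 0.2, scatter_add_sd = 3, noise_sd = 0,
                    seed = 3)
  cp <- fixed_conc_profiles(c(1.2, 0.4, 0.9))
  s <- simulate_spectrum_set(cfg, classes = cp)
  tub <- s$spectra[s$label == "tuberous", ]
  z <- snv(tub)
  for (i in 2:nrow(z))
    expect_equal(z[i, ], z[1, ], tolerance = 1e-8)
})

test_that("raising a concentration strictly lowers reflectance at absorbing bands", {
  lib <- analyte_library()
  cfg <- clean_config(samples_per_class = c(tuberous = 2, taproot = 2, old = 2))
  lo <- simulate_spectrum_set(cfg, classes = fixed_conc_profiles(c(0.5, 0, 0)))
  hi <- simulate_spectrum_set(cfg, classes = fixed_conc_profiles(c(1.0, 0, 0)))
  peaks <- lib$peak_bands$norisoboldine
  expect_true(all(hi$spectra[, peaks] < lo$spectra[, peaks]))
})

test_that("a fixed seed determines the spectrum set bit for bit", {
  a <- simulate_spectrum_set(sim_config(samples_per_class = c(tuberous = 5, taproot = 5, old = 5), seed = 42))
  b <- simulate_spectrum_set(sim_config(samples_per_class = c(tuberous = 5, taproot = 5, old = 5), seed = 42))
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$concentration, b$concentration)
})

test_that("tuberous roots have the highest median concentration of every analyte", {
  for (seed in 1:3) {
    s <- simulate_spectrum_set(sim_config(
      samples_per_class = c(tuberous = 20, taproot = 20, old = 20), seed = seed))
    med <- apply(s$concentration, 2, function(v) tapply(v, s$label, stats::median))
    for (k in colnames(s$concentration)) {
      expect_gt(med["tuberous", k], med["taproot", k])
      expect_gt(med["tuberous", k], med["old", k])
    }
  }
})

test_that("old-root baseline lies strictly below the other class baselines", {
  cp <- class_profiles()
  expect_true(all(cp$old$baseline < cp$tuberous$baseline))
  expect_true(all(cp$old$baseline < cp$taproot$baseline))
  for (p in cp) expect_true(all(p$baseline > 0 & p$baseline <= 100))
})

test_that("analyte library satisfies its peak invariants", {
  wl <- default_wavelength()
  lib <- analyte_library(wl)
  expect_true(all(lib$epsilon >= 0))
  for (pk in lib$peak_bands) {
    expect_gte(length(pk), 2)
    expect_true(all(wl[pk] > 427 & wl[pk] < 994))
  }
  expect_false(identical(lib$peak_bands[[1]], lib$peak_bands[[2]]))
  expect_false(identical(lib$peak_bands[[2]], lib$peak_bands[[3]]))
})

test_that("planted absorption bands correlate with concentration more than off-peak bands", {
  # conditioned on one class so baseline differences between classes do not
  # inflate off-peak correlations
  s <- simulate_spectrum_set(sim_config(samples_per_class = c(tuberous = 60),
                                        seed = 2))
  lib <- analyte_library()
  for (k in seq_along(lib$names)) {
    cors <- abs(cor(s$spectra, s$concentration[, k]))
    on_peak <- lib$peak_bands[[k]]
    all_peaks <- unlist(lib$peak_bands)
    off <- setdiff(seq_along(cors), unlist(lapply(all_peaks, function(p)
      (p - 5):(p + 5))))
    expect_gt(min(cors[on_peak]), stats::median(cors[off]))
  }
})

test_that("feature-table simulation validates inputs and honours its seed", {
  expect_error(simulate_feature_table(fc = 1), "fc")
  expect_error(simulate_feature_table(n_features = 10, n_differential = 11),
               "n_differential")
  a <- simulate_feature_table(n_per_group = 4, n_features = 50, seed = 9)
  b <- simulate_feature_table(n_per_group = 4, n_features = 50, seed = 9)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$planted, b$planted)
  expect_true(all(a$intensity > 0))
  expect_equal(levels(a$group), c("tuberous", "taproot", "old", "QC"))
})

test_that("planted features carry the requested between-group mean ratio", {
  ft <- simulate_feature_table(n_per_group = 200, n_features = 60,
                               n_differential = 6, fc = 4, seed = 5)
  for (i in seq_along(ft$planted)) {
    f <- ft$planted[i]
    up <- ft$planted_group[i]
    others <- setdiff(c("tuberous", "taproot", "old"), up)
    m_up <- mean(ft$intensity[f, ft$group == up])
    m_rest <- sapply(others, function(g) mean(ft$intensity[f, ft$group == g]))
    expect_equal(unname(m_up / mean(m_rest)), 4, tolerance = 0.25)
  }
})
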