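# End-to-end orchestration: simulate -> calibrate -> classify -> quantify
# -> map, plus the metabolomics screen, with CSV reports and a JSON
# reproducibility manifest.

# small stable content hash (polynomial rolling hash over the serialised
# object, mod 2^31 - 1)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' @param out_dir output directory for reports, models and maps.
#' @param seed global seed; together with the config it fully determines
#'   every output.
#' @param stages which stages to run, in order, from
#'   `c("simulate", "classify", "quantify", "map", "screen")`.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param chains pre-processing chains screened by the classification
#'   stage.
#' @param classifiers classifier kinds for the screening grid.
#' @param quant_chain chain applied before wavelength selection and
#'   quantitative modelling.
#' @param analytes analyte names to calibrate.
#' @param selectors wavelength selectors to run (`"FS"` = full spectrum,
#'   `"CARS"`, `"SPA"`, `"RF"`).
#' @param regressors regression learners (`"LSSVM"`, `"ELM"`, `"BPNN"`).
#' @param cars,spa,frog selector configurations.
#' @param cv_folds folds for the classification CV column.
#' @param map_size spatial grid edge for the demo hypercube.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("rootspec_run_"), seed = 1,
                       stages = c("simulate", "classify", "quantify",
                                  "map", "screen"),
                       sim = sim_config(seed = seed),
                       chains = standard_chains(),
                       classifiers = c("LR", "SVM", "MLP"),
                       quant_chain = "SNV",
                       analytes = c("norisoboldine", "linderane", "lindenenol"),
                       selectors = c("FS", "CARS", "SPA", "RF"),
                       regressors = c("LSSVM", "ELM", "BPNN"),
                       cars = cars_config(seed = seed),
                       spa = spa_config(),
                       frog = frog_config(seed = seed),
                       cv_folds = 5, map_size = 24) {
  sim$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, stages = stages, sim = sim,
                 chains = chains, classifiers = classifiers,
                 quant_chain = quant_chain, analytes = analytes,
                 selectors = selectors, regressors = regressors,
                 cars = cars, spa = spa, frog = frog, cv_folds = cv_folds,
                 map_size = map_size),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr,
           error = function(e) stop("stage '", name, "' failed: ",
                                    conditionMessage(e), call. = FALSE))
}

#' Quantitative calibration report grid
#'
#' For one pre-processed analyte response: SPXY 2:1 calibration/prediction
#' split, optional wavelength selection on the calibration set, one model
#' per regressor, and the standard metric block (Rc2, RMSEC, Rp2, RMSEP,
#' RPD).
#'
#' @param data a [spectrum_set()] with concentrations.
#' @param analyte analyte (concentration column) name.
#' @param config a [run_config()] (selector/regressor lists and configs).
#' @return list with the report `data.frame` rows, trained models and
#'   subsets.
#' @export
quantify_analyte <- function(data, analyte, config = run_config()) {
  y <- data$concentration[, analyte]
  chain <- config$quant_chain
  Z <- apply_chain(data$spectra, chain)
  split <- spxy_split(Z, y, 1 / 3)
  cal <- split$calibration; prd <- split$test
  rows <- list(); models <- list(); subsets <- list()
  for (sel in config$selectors) {
    subset <- switch(sel,
      FS = NULL,
      CARS = cars_select(Z[cal, , drop = FALSE], y[cal], config$cars),
      SPA = spa_select(Z[cal, , drop = FALSE], y[cal], config$spa),
      RF = random_frog_select(Z[cal, , drop = FALSE], y[cal], config$frog),
      stop("unknown selector: ", sel))
    n_ew <- if (is.null(subset)) ncol(Z) else length(subset$bands)
    for (reg in config$regressors) {
      model <- switch(reg,
        LSSVM = lssvm_train(data$spectra[cal, , drop = FALSE], y[cal],
                            lssvm_config(), chain = chain, subset = subset,
                            wavelength = data$wavelength),
        ELM = elm_train(data$spectra[cal, , drop = FALSE], y[cal],
                        elm_config(seed = config$seed), chain = chain,
                        subset = subset, wavelength = data$wavelength),
        BPNN = bpnn_train(data$spectra[cal, , drop = FALSE], y[cal],
                          bpnn_config(seed = config$seed), chain = chain,
                          subset = subset, wavelength = data$wavelength),
        stop("unknown regressor: ", reg))
      mc <- regression_metrics(y[cal],
                               predict(model, data$spectra[cal, , drop = FALSE]))
      mp <- regression_metrics(y[prd],
                               predict(model, data$spectra[prd, , drop = FALSE]))
      rows[[length(rows) + 1L]] <- data.frame(
        constituent = analyte, model = reg, selector = sel, n_ew = n_ew,
        reduction = variable_reduction(ncol(Z), n_ew),
        rc2 = mc$r2, rmsec = mc$rmse, rp2 = mp$r2, rmsep = mp$rmse,
        rpd = mp$rpd)
      models[[paste(analyte, reg, sel, sep = "_")]] <- model
    }
    subsets[[sel]] <- subset
  }
  list(report = do.call(rbind, rows), models = models, subsets = subsets,
       split = split)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order on synthetic data, writing CSV
#' reports (classification accuracy grid, quantitative calibration grid,
#' differential screen), the pixel map, and a JSON manifest recording the
#' seed, config hash and stage products. A stage failure aborts with the
#' stage name; earlier outputs are retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage products and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "rootspec",
                   version = as.character(utils::packageVersion("rootspec")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = config$stages, outputs = character(0))
  out <- list()
  add_output <- function(path) {
    manifest$outputs <<- c(manifest$outputs, basename(path))
    path
  }
  spectra <- NULL
  if ("simulate" %in% config$stages || length(intersect(
      c("classify", "quantify", "map"), config$stages))) {
    spectra <- run_stage("simulate", simulate_spectrum_set(config$sim))
    write_spectra(spectra, add_output(file.path(config$out_dir, "spectra.csv")))
    out$spectra <- spectra
  }
  if ("classify" %in% config$stages) {
    rep_cls <- run_stage("classify",
      evaluation_report(spectra, config$chains, config$classifiers,
                        cv_folds = config$cv_folds, seed = config$seed))
    utils::write.csv(rep_cls,
                     add_output(file.path(config$out_dir,
                                          "classification_report.csv")),
                     row.names = FALSE)
    out$classification <- rep_cls
  }
  if ("quantify" %in% config$stages) {
    quant <- run_stage("quantify", {
      res <- lapply(config$analytes, quantify_analyte, data = spectra,
                    config = config)
      names(res) <- config$analytes
      res
    })
    report <- do.call(rbind, lapply(quant, `[[`, "report"))
    utils::write.csv(report,
                     add_output(file.path(config$out_dir,
                                          "calibration_report.csv")),
                     row.names = FALSE)
    out$quantification <- quant
    out$calibration_report <- report
  }
  if ("map" %in% config$stages) {
    out$map <- run_stage("map", {
      m <- config$map_size
      layout <- matrix("", m, m)
      layout[3:(m - 2), 3:(m - 2)] <- "tuberous"
      sim_cube <- simulate_hypercube(config$sim, layout,
                                     gradient = c(0.6, 1.4))
      cube <- calibrate_reflectance(hsi_cube(sim_cube$raw, sim_cube$wavelength),
                                    sim_cube$dark, sim_cube$white)
      mask <- background_mask(cube)
      analyte <- config$analytes[1]
      model <- if (!is.null(out$quantification))
        out$quantification[[analyte]]$models[[1]]
      else lssvm_train(spectra, analyte, chain = config$quant_chain)
      cmap <- predict_pixel_map(cube, model, mask)
      render_map(cmap, add_output(file.path(config$out_dir, "map.png")),
                 colorbar_file = file.path(config$out_dir, "map_colorbar.png"))
      utils::write.csv(cmap$values,
                       add_output(file.path(config$out_dir, "map_values.csv")),
                       row.names = FALSE)
      list(cube = cube, map = cmap, truth = sim_cube$truth)
    })
  }
  if ("screen" %in% config$stages) {
    out$screen <- run_stage("screen", {
      ft <- simulate_feature_table(seed = config$seed)
      ft_f <- filter_features(ft)
      ds <- anova_fc_screen(ft_f)
      utils::write.csv(ds$table,
                       add_output(file.path(config$out_dir, "screen.csv")),
                       row.names = FALSE)
      pca <- pca_scores(ft_f)
      pls <- plsda_fit(ft_f, seed = config$seed)
      hca <- if (length(ds$features) >= 2)
        hca_heatmap(ft_f, features = ds$features,
                    file = add_output(file.path(config$out_dir, "heatmap.png")))
      list(table = ft_f, differential = ds, pca = pca, plsda = pls, hca = hca)
    })
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
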