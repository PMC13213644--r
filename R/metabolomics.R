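# Differential-metabolite screening on feature tables: response/occurrence
# filtering, per-sample normalisation, one-way ANOVA + fold-change screen,
# PCA, PLS-DA with R2X/R2Y/Q2, and hierarchical clustering with heatmap
# rendering.

root_groups <- function(table) setdiff(levels(table$group), "QC")

#' Construct a feature table
#'
#' Wraps a features x samples intensity matrix with its group labels (the
#' three root-class groups plus optional pooled-QC samples) in the
#' container the screening operations consume.
#'
#' @param intensity non-negative features x samples matrix.
#' @param group per-sample group labels; `"QC"` marks pooled quality
#'   controls.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(intensity, group) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (length(group) != ncol(intensity))
    stop("one group label per sample required")
  group <- as.factor(group)
  structure(list(intensity = intensity, group = group,
                 planted = NULL, planted_group = NULL),
            class = "feature_table")
}

#' Response / occurrence feature filter
#'
#' Keeps a feature when its intensity reaches `min_response` in at least
#' `occurrence` of the samples of at least one root-class group (QC samples
#' are not counted towards occurrence).
#'
#' @param table a `feature_table` (see [simulate_feature_table()]).
#' @param min_response minimum intensity in counts (default 5000).
#' @param occurrence required within-group occurrence fraction
#'   (default 0.8).
#' @return the filtered `feature_table` (planted indices re-mapped).
#' @export
filter_features <- function(table, min_response = 5000, occurrence = 0.8) {
  stopifnot(inherits(table, "feature_table"))
  if (min_response < 0 || occurrence < 0) stop("thresholds must be >= 0")
  keep <- rep(FALSE, nrow(table$intensity))
  for (g in root_groups(table)) {
    cols <- table$group == g
    frac <- rowMeans(table$intensity[, cols, drop = FALSE] >= min_response)
    keep <- keep | (frac >= occurrence)
  }
  if (!any(keep)) warning("no features pass the filter")
  idx <- which(keep)
  out <- table
  out$intensity <- table$intensity[idx, , drop = FALSE]
  if (!is.null(table$planted)) {
    kept_planted <- table$planted %in% idx
    out$planted <- match(table$planted[kept_planted], idx)
    out$planted_group <- table$planted_group[kept_planted]
  }
  out
}

#' Per-sample median normalisation
#'
#' Scales every sample so its median intensity equals the median of the
#' per-sample medians, removing global loading/injection differences.
#'
#' @param table a `feature_table`.
#' @return the normalised `feature_table`.
#' @export
normalize_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  med <- apply(table$intensity, 2, stats::median)
  if (any(med <= 0)) stop("non-positive sample median; cannot normalise")
  table$intensity <- sweep(table$intensity, 2, stats::median(med) / med, "*")
  table
}

#' ANOVA + fold-change differential screen
#'
#' Per feature: one-way ANOVA across the three root-class groups on log2
#' intensities (after per-sample median normalisation), and fold change
#' defined as the maximum pairwise ratio of raw-scale group means. Features
#' with `p < p_threshold` and `FC > fc_threshold` (both strict) form the
#' differential set.
#'
#' @param table a `feature_table`.
#' @param p_threshold ANOVA p-value cutoff (default 0.05).
#' @param fc_threshold fold-change cutoff (default 2.0).
#' @param normalize apply [normalize_features()] first.
#' @param welch use Welch's unequal-variance ANOVA.
#' @return list of class `differential_set`: `features` (kept ids),
#'   `table` (per-feature fc, p, up-regulated group, kept flag).
#' @export
anova_fc_screen <- function(table, p_threshold = 0.05, fc_threshold = 2.0,
                            normalize = TRUE, welch = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  groups <- root_groups(table)
  if (length(groups) < 2) stop("need >= 2 non-QC groups")
  if (any(table(table$group)[groups] < 2))
    stop("every group needs >= 2 samples")
  if (normalize) table <- normalize_features(table)
  cols <- table$group %in% groups
  x <- table$intensity[, cols, drop = FALSE]
  g <- droplevels(table$group[cols])
  gm <- do.call(cbind, lapply(groups, function(gg)
    rowMeans(x[, g == gg, drop = FALSE])))         # raw-scale group means
  colnames(gm) <- groups
  if (any(gm == 0))
    stop("zero group mean for feature(s) ",
         paste(utils::head(which(rowSums(gm == 0) > 0), 5), collapse = ", "),
         ": fold change undefined")
  fc <- apply(gm, 1, function(m) max(m) / min(m))
  up <- groups[apply(gm, 1, which.max)]
  lx <- log2(x)
  p <- vapply(seq_len(nrow(lx)), function(i)
    stats::oneway.test(lx[i, ] ~ g, var.equal = !welch)$p.value, numeric(1))
  p[is.nan(p)] <- 1           # zero within- and between-group variance
  kept <- p < p_threshold & fc > fc_threshold
  ids <- rownames(table$intensity)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  structure(list(
    features = which(kept),
    table = data.frame(feature = ids, fc = fc, p = p, up_group = up,
                       kept = kept, row.names = NULL)),
    class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat("<differential_set> ", length(x$features), " of ", nrow(x$table),
      " features pass p/FC thresholds\n", sep = "")
  invisible(x)
}

#' PCA scores of a feature table
#'
#' Mean-centred PCA of samples in log2 intensity space (QC samples
#' included, so their central clustering is visible).
#'
#' @param table a `feature_table` or a samples x variables matrix.
#' @param n_components number of components to return.
#' @param log2_transform log2-transform intensities first (tables only).
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions), and `group` when available.
#' @export
pca_scores <- function(table, n_components = 2, log2_transform = TRUE) {
  if (inherits(table, "feature_table")) {
    X <- t(if (log2_transform) log2(table$intensity) else table$intensity)
    group <- table$group
  } else {
    X <- as.matrix(table)
    group <- NULL
  }
  if (n_components > min(ncol(X), nrow(X) - 1))
    stop("n_components exceeds min(features, samples - 1)")
  if (all(apply(X, 2, stats::sd) == 0)) stop("constant matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = ev[seq_len(n_components)], group = group)
}

#' PLS-DA with R2X / R2Y / Q2
#'
#' PLS2 regression of one-hot class membership on log2 intensities (QC
#' samples excluded). R2X and R2Y are the cumulative explained variance of
#' the X and Y blocks; Q2 is `1 - PRESS/SS` under seeded k-fold
#' cross-validation.
#'
#' @param table a `feature_table`, or a samples x variables matrix (then
#'   supply `labels`).
#' @param labels class labels when `table` is a matrix.
#' @param n_components latent variables (default 2).
#' @param folds CV folds for Q2 (default 7).
#' @param seed integer seed for the fold assignment.
#' @return list of class `plsda_result` with `r2x`, `r2y`, `q2`, `scores`,
#'   `n_components`.
#' @export
plsda_fit <- function(table, labels = NULL, n_components = 2, folds = 7,
                      seed = 1) {
  if (inherits(table, "feature_table")) {
    cols <- table$group %in% root_groups(table)
    X <- t(log2(table$intensity[, cols, drop = FALSE]))
    labels <- droplevels(table$group[cols])
  } else {
    X <- as.matrix(table)
    if (is.null(labels)) stop("labels required for a bare matrix")
    labels <- factor(labels)
  }
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  n <- nrow(X)
  if (n_components > min(n - 1, ncol(X))) stop("too many components for rank")
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  fit <- pls_fit(X, Y, n_components)
  r2x <- 1 - fit$x_ss_residual / fit$x_ss_total
  Yc <- sweep(Y, 2, colMeans(Y))
  pred <- predict(fit, X)
  r2y <- 1 - sum((Y - pred)^2) / sum(Yc^2)
  folds <- min(folds, n)
  fold_id <- kfold_indices(n, folds, seed = seed, stratify = labels)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    a <- min(n_components, sum(tr) - 1L)
    m <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], a)
    press <- press + sum((Y[!tr, ] - predict(m, X[!tr, , drop = FALSE]))^2)
  }
  structure(list(r2x = r2x, r2y = r2y, q2 = 1 - press / sum(Yc^2),
                 scores = fit$scores, n_components = fit$n_lv,
                 labels = labels),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf("<plsda_result> %d components: R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
              x$n_components, x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' Hierarchical clustering and heatmap of differential features
#'
#' Clusters features and samples (row-standardised log2 intensities) and
#' optionally renders a blue-to-red heatmap in dendrogram order.
#'
#' @param x features x samples matrix, or a `feature_table` (optionally
#'   restricted via `features`).
#' @param features optional row indices (e.g. a differential set).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param file optional PNG path to render the heatmap to.
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`,
#'   and the standardised matrix.
#' @export
hca_heatmap <- function(x, features = NULL, metric = "euclidean",
                        linkage = "ward.D2", file = NULL) {
  if (inherits(x, "feature_table")) {
    m <- log2(x$intensity)
  } else m <- as.matrix(x)
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 features")
  if (!all(is.finite(m))) stop("non-finite values in matrix")
  sdv <- apply(m, 1, stats::sd)
  z <- (m - rowMeans(m)) / ifelse(sdv == 0, 1, sdv)
  rh <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  ch <- stats::hclust(stats::dist(t(z), method = metric), method = linkage)
  if (!is.null(file)) {
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
    ordered <- z[rh$order, ch$order, drop = FALSE]
    rng <- range(ordered)
    scaled <- if (diff(rng) == 0) matrix(128L, nrow(ordered), ncol(ordered))
              else matrix(findInterval(ordered,
                                       seq(rng[1], rng[2], length.out = 256),
                                       all.inside = TRUE),
                          nrow(ordered))
    rgb_arr <- array(t(grDevices::col2rgb(pal[scaled])) / 255,
                     c(nrow(scaled), ncol(scaled), 3))
    png::writePNG(rgb_arr, file)
  }
  list(row_hclust = rh, col_hclust = ch,
       row_order = rh$order, col_order = ch$order, z = z)
}
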