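# Data partitioning and model-evaluation metrics: R2 / RMSE / RPD for
# calibration models, accuracy / macro precision / recall / F1 / kappa for
# classifiers.

#' Stratified train/validation/test split
#'
#' Allocates each class across the partitions proportionally (largest
#' remainder rounding) after a seeded within-class shuffle; partitions are
#' disjoint and exhaustive.
#'
#' @param labels per-sample class labels.
#' @param fractions named partition fractions summing to 1
#'   (default 60/20/20).
#' @param seed integer seed.
#' @return named list of index vectors, one per partition.
#' @export
stratified_split <- function(labels,
                             fractions = c(train = 0.6, validation = 0.2,
                                           test = 0.2),
                             seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  labels <- as.factor(labels)
  if (any(table(labels) < length(fractions)))
    stop("every class needs at least as many samples as partitions")
  out <- stats::setNames(vector("list", length(fractions)), names(fractions))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      quota <- fractions * n
      base <- floor(quota)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      at <- 0L
      for (k in seq_along(fractions)) {
        take <- idx[at + seq_len(base[k])]
        out[[k]] <- c(out[[k]], take)
        at <- at + base[k]
      }
    }
  })
  lapply(out, sort)
}

#' Seeded k-fold assignment
#'
#' @param n number of samples.
#' @param k number of folds (fold sizes differ by at most 1).
#' @param seed integer seed.
#' @param stratify optional labels; folds then balance classes.
#' @return integer vector of fold ids in 1..k.
#' @export
kfold_indices <- function(n, k, seed = 1, stratify = NULL) {
  if (k > n) stop("k must be <= n")
  if (k < 2) stop("k must be >= 2")
  fold <- integer(n)
  with_seed(seed, {
    if (is.null(stratify)) {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    } else {
      stratify <- as.factor(stratify)
      offset <- 0L
      for (cl in levels(stratify)) {
        idx <- sample(which(stratify == cl))
        ids <- (offset + seq_along(idx) - 1L) %% k + 1L
        fold[idx] <- ids
        offset <- offset + length(idx)
      }
    }
  })
  fold
}

#' Regression metrics: R2, RMSE, RPD
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `RMSE = sqrt(mean((yhat - y)^2))` (1/n denominator); `RPD = sd(y)/RMSE`
#' with the population SD (n denominator) of the true values of the
#' evaluated partition.
#'
#' @param y_true,y_pred equal-length numeric vectors (n >= 2).
#' @return list with `r2`, `rmse`, `rpd`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  n <- length(y_true)
  if (length(y_pred) != n || n < 2) stop("need equal lengths >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("zero-variance reference values: R2 and RPD undefined")
  rmse <- sqrt(mean((y_pred - y_true)^2))
  if (rmse == 0) stop("zero RMSE: RPD undefined")
  sigma <- sqrt(ss_tot / n)
  list(r2 = 1 - sum((y_true - y_pred)^2) / ss_tot,
       rmse = rmse, rpd = sigma / rmse, n = n)
}

#' Confusion matrix
#'
#' @param y_true,y_pred labels (factors or characters).
#' @param levels optional class ordering.
#' @return classes x classes count matrix, rows = truth.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(y_true),
                                               as.character(y_pred))))
  as.matrix(table(factor(y_true, levels), factor(y_pred, levels)))
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy (trace/total); per-class precision, recall and F1 via
#' one-vs-rest collapse, macro-averaged (unweighted mean over classes;
#' `average = "weighted"` weights by class support); Cohen's kappa
#' `K = (Po - Pe) / (1 - Pe)` with `Po = trace/total` and
#' `Pe = sum(row_i * col_i) / total^2`. Per-class ratios with empty
#' denominators are set to 0.
#'
#' @param cm square count matrix (rows = truth) from [confusion_matrix()].
#' @param average `"macro"` (default) or `"weighted"`.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `kappa`, and
#'   the `per_class` table.
#' @export
classification_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- safe(2 * precision * recall, precision + recall)
  w <- if (average == "macro") rep(1 / nrow(cm), nrow(cm))
       else rowSums(cm) / total
  po <- sum(tp) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(cm)))
  list(accuracy = po,
       precision = sum(w * precision), recall = sum(w * recall),
       f1 = sum(w * f1), kappa = kappa,
       per_class = data.frame(class = cls, precision = precision,
                              recall = recall, f1 = f1, row.names = NULL))
}

#' Classification screening report (chains x classifiers)
#'
#' Fits every pre-processing chain x classifier combination on a stratified
#' 60/20/20 split of the labelled spectra and tabulates accuracy on each
#' partition plus stratified k-fold cross-validated accuracy on the training
#' portion.
#'
#' @param data labelled [spectrum_set()].
#' @param chains chain names (default the seven standard chains).
#' @param classifiers subset of `c("LR", "SVM", "MLP")`.
#' @param cv_folds folds for the CV column.
#' @param seed integer seed (split, CV, and learner initialisation).
#' @return data.frame, one row per chain x classifier.
#' @export
evaluation_report <- function(data, chains = standard_chains(),
                              classifiers = c("LR", "SVM", "MLP"),
                              cv_folds = 5, seed = 1) {
  stopifnot(inherits(data, "spectrum_set"), !is.null(data$label))
  parts <- stratified_split(data$label, seed = seed)
  rows <- list()
  for (ch in chains) {
    for (kind in classifiers) {
      spec <- classifier_spec(kind, seed = seed)
      model <- train_classifier(data[parts$train, ], spec, chain = ch)
      acc <- vapply(parts, function(idx) {
        pred <- predict(model, data[idx, ])
        mean(pred == data$label[idx])
      }, numeric(1))
      # stratified CV on the training partition
      tr <- parts$train
      fold <- kfold_indices(length(tr), cv_folds, seed = seed,
                            stratify = data$label[tr])
      hits <- 0L
      for (f in seq_len(cv_folds)) {
        m <- train_classifier(data[tr[fold != f], ], spec, chain = ch)
        pred <- predict(m, data[tr[fold == f], ])
        hits <- hits + sum(pred == data$label[tr[fold == f]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, model = kind,
        train = unname(acc["train"]), validation = unname(acc["validation"]),
        test = unname(acc["test"]), cv = hits / length(tr))
    }
  }
  do.call(rbind, rows)
}
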