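# brute-force one-vs-rest metric oracle, independent of the implementation
oracle_metrics <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  prec <- rec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[i] <- if (prec[i] + rec[i] == 0) 0 else
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
  }
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  list(accuracy = po, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), kappa = (po - pe) / (1 - pe))
}

test_that("stratified 60/20/20 split allocates exactly and reproducibly", {
  labels <- rep("x", 30)
  sp <- stratified_split(labels, seed = 1)
  expect_equal(lengths(sp), c(train = 18, validation = 6, test = 6))
  labels3 <- rep(c("a", "b", "c"), c(20, 10, 10))
  sp3 <- stratified_split(labels3, seed = 2)
  all_idx <- unlist(sp3)
  expect_setequal(all_idx, seq_along(labels3))
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_identical(sp3, stratified_split(labels3, seed = 2))
  expect_error(stratified_split(c("a", "a", "b"), seed = 1), "class")
})

test_that("k-fold assignment balances fold sizes and respects stratification", {
  f <- kfold_indices(10, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(f, kfold_indices(10, 5, seed = 3))
  labs <- rep(c("a", "b"), each = 10)
  fs <- kfold_indices(20, 5, seed = 4, stratify = labs)
  per_fold <- table(labs, fs)
  expect_true(all(per_fold == 2))
  expect_error(kfold_indices(3, 5), "k must be <= n")
})

test_that("regression metrics match hand arithmetic and guard degenerate cases", {
  m <- regression_metrics(c(1, 2, 3, 4), c(1, 2, 3, 6))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 1 - 4 / 5)
  const_pred <- regression_metrics(c(1, 2, 3, 4), rep(2.5, 4))
  expect_equal(const_pred$r2, 0)
  expect_error(regression_metrics(1:4, 1:4), "RPD undefined")
  expect_error(regression_metrics(rep(2, 4), c(1, 2, 3, 4)), "zero-variance")
})

test_that("RPD times RMSE returns the population SD of the reference values", {
  set.seed(5)
  for (i in 1:5) {
    y <- rnorm(20); p <- y + rnorm(20, 0, 0.3)
    m <- regression_metrics(y, p)
    expect_equal(m$rpd * m$rmse, sqrt(mean((y - mean(y))^2)),
                 tolerance = 1e-12)
  }
})

test_that("classification metrics are exact on canonical matrices", {
  d <- diag(c(4, 6, 5))
  m <- classification_metrics(d)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1", "kappa")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, kappa = 1))
  chance <- matrix(5, 2, 2)
  m2 <- classification_metrics(chance)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$kappa, 0)
  cm3 <- matrix(c(8, 1, 1, 1, 8, 1, 0, 2, 8), 3, byrow = TRUE)
  got <- classification_metrics(cm3)
  want <- oracle_metrics(cm3)
  for (nm in names(want)) expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
})

test_that("metrics agree with the brute-force oracle on random confusion matrices", {
  set.seed(6)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4), k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    got <- classification_metrics(cm)
    want <- oracle_metrics(cm)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
  }
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  set.seed(7)
  cm <- matrix(rpois(16, 5), 4)
  perm <- sample(4)
  expect_equal(classification_metrics(cm)$kappa,
               classification_metrics(cm[perm, perm])$kappa,
               tolerance = 1e-12)
})

test_that("the screening report covers the grid and matches direct metric calls", {
  s <- small_spectrum_set(seed = 2)
  rep <- evaluation_report(s, chains = c("Raw", "SNV"), classifiers = "LR",
                           cv_folds = 3, seed = 9)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$train >= 0 & rep$train <= 1))
  # reproduce one cell by hand
  parts <- stratified_split(s$label, seed = 9)
  m <- train_classifier(s[parts$train, ], classifier_spec("LR", seed = 9),
                        chain = "SNV")
  acc <- mean(predict(m, s[parts$test, ]) == s$label[parts$test])
  expect_equal(rep$test[rep$chain == "SNV"], acc)
  rep2 <- evaluation_report(s, chains = c("Raw", "SNV"), classifiers = "LR",
                            cv_folds = 3, seed = 9)
  expect_identical(rep, rep2)
})
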