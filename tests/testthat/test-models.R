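# toy 3-class problem, linearly separable in 20 bands
toy_classes <- function(n_per = 8, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(rep(2, 10), rep(0, 10)),
                   c(rep(0, 10), rep(2, 10)),
                   c(rep(-2, 10), rep(-2, 10)))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 20, 0, 0.2), n_per), 2, centers[k, ], "+")))
  list(X = X, y = rep(c("a", "b", "c"), each = n_per))
}

test_that("logistic regression separates a separable toy and ignores row order", {
  toy <- toy_classes()
  m <- train_classifier(toy$X, classifier_spec("LR"), labels = toy$y)
  expect_equal(mean(predict(m, toy$X) == toy$y), 1)
  perm <- sample(nrow(toy$X))
  m2 <- train_classifier(toy$X[perm, ], classifier_spec("LR"),
                         labels = toy$y[perm])
  expect_equal(as.character(predict(m2, toy$X)),
               as.character(predict(m, toy$X)))
  expect_error(train_classifier(toy$X, labels = rep("a", nrow(toy$X))),
               "2 classes")
})

test_that("SVM and MLP classifiers fit the toy and are seed-deterministic", {
  toy <- toy_classes()
  for (kind in c("SVM", "MLP")) {
    m <- train_classifier(toy$X, classifier_spec(kind, seed = 4),
                          labels = toy$y)
    expect_gte(mean(predict(m, toy$X) == toy$y), 0.95)
    m2 <- train_classifier(toy$X, classifier_spec(kind, seed = 4),
                           labels = toy$y)
    expect_identical(as.character(predict(m, toy$X)),
                     as.character(predict(m2, toy$X)))
    expect_true(all(predict(m, toy$X) %in% c("a", "b", "c")))
  }
})

test_that("LSSVM solves the assembled KKT system and the RBF kernel is unit at zero distance", {
  set.seed(6)
  X <- matrix(rnorm(15 * 4), 15)
  y <- rnorm(15)
  cfg <- lssvm_config(gamma = 2, sigma2 = 2)
  m <- lssvm_train(X, y, cfg)
  K <- unname(exp(-as.matrix(dist(m$fit$X))^2 / cfg$sigma2))
  expect_equal(diag(K), rep(1, 15))
  n <- 15
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / cfg$gamma))
  sol <- unname(solve(M, c(0, y)))
  expect_equal(m$fit$b, sol[1], tolerance = 1e-8)
  expect_equal(m$fit$alpha, sol[-1], tolerance = 1e-8)
})

test_that("LSSVM interpolates in the large-gamma limit and matches OLS with a linear kernel", {
  set.seed(7)
  X5 <- matrix(rnorm(5 * 2), 5)
  y5 <- rnorm(5)
  m <- lssvm_train(X5, y5, lssvm_config(gamma = 1e8, sigma2 = 2))
  expect_equal(predict(m, X5), y5, tolerance = 1e-4)
  # linear kernel, large gamma ~ OLS on a full-rank toy
  X <- matrix(rnorm(40 * 3), 40)
  y <- drop(X %*% c(1.5, -2, 0.7)) + rnorm(40, 0, 0.05)
  ml <- lssvm_train(X, y, lssvm_config(gamma = 1e7, kernel = "linear"))
  ols <- lm.fit(cbind(1, X), y)$coefficients
  # recover implicit linear coefficients: f(x) = sum alpha_i <x_i, x> + b
  w_lssvm <- unname(drop(crossprod(ml$fit$X, ml$fit$alpha)))
  Xc <- scale(X, scale = FALSE)
  w_ols <- unname(drop(solve(crossprod(Xc), crossprod(Xc, y - mean(y)))))
  expect_equal(w_lssvm, w_ols, tolerance = 1e-3)
})

test_that("ELM output weights satisfy the least-squares normal equations", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  m <- elm_train(X, y, elm_config(nodes = 12, seed = 3))
  Z <- sweep(sweep(X, 2, m$norm$center), 2, m$norm$scale, "/")
  H <- 1 / (1 + exp(-sweep(Z %*% m$fit$W, 2, m$fit$bias, "+")))
  resid <- crossprod(H, H %*% m$fit$beta - y)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("an ELM with at least as many nodes as samples interpolates", {
  set.seed(9)
  X <- matrix(rnorm(10 * 3), 10)
  y <- rnorm(10)
  m <- elm_train(X, y, elm_config(nodes = 15, seed = 2))
  expect_lt(mean((predict(m, X) - y)^2), 1e-6)
  m2 <- elm_train(X, y, elm_config(nodes = 15, seed = 2))
  expect_identical(m$fit$beta, m2$fit$beta)
  expect_identical(predict(m, X), predict(m2, X))
})

test_that("BPNN descends its loss, stops early at the target, and honours its seed", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30)
  y <- drop(X %*% rnorm(5)) + rnorm(30, 0, 0.1)
  m <- bpnn_train(X, y, bpnn_config(epochs = 500, seed = 1))
  expect_lt(utils::tail(m$fit$loss, 1), m$fit$loss[1])
  expect_true(all(is.finite(m$fit$loss)))
  m2 <- bpnn_train(X, y, bpnn_config(epochs = 500, seed = 1))
  expect_identical(m$fit$loss, m2$fit$loss)
  # generous target triggers the early-stop flag immediately
  easy <- bpnn_train(X, y, bpnn_config(epochs = 500, target_mse = 10, seed = 1))
  expect_true(easy$fit$early_stop)
  expect_length(easy$fit$loss, 1)
})

test_that("prediction is pure and enforces the training band axis", {
  s <- small_spectrum_set(seed = 3)
  m <- lssvm_train(s, "norisoboldine", chain = "SNV")
  p1 <- predict(m, s)
  expect_identical(p1, predict(m, s))
  shifted <- spectrum_set(s$spectra, s$wavelength + 5)
  expect_error(predict(m, shifted), "band axis")
})
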