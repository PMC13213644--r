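# Classification learners (LR, SVM, MLP) and quantitative calibration
# learners (LSSVM, ELM, BPNN). Every trained predictor carries its
# pre-processing chain, band subset and normalisation constants, and
# re-applies them at prediction time.

# resolve (spectra matrix, wavelength, labels/response) from inputs
resolve_xy <- function(x, y = NULL, wavelength = NULL) {
  if (inherits(x, "spectrum_set")) {
    spectra <- x$spectra
    wavelength <- x$wavelength
    if (is.null(y)) y <- x$label
    else if (is.character(y) && length(y) == 1L && !is.null(x$concentration))
      y <- x$concentration[, y]
  } else {
    spectra <- as.matrix(x)
  }
  list(spectra = spectra, wavelength = wavelength, y = y)
}

# chain -> subset -> column normalisation; returns processed matrix + state.
# scale = FALSE centres only (kernel methods keep the scale set by the
# pre-processing chain); TRUE autoscales (LR/SVM/MLP/ELM); "minmax" maps
# each band to [-1, 1] (BPNN, the convention the fixed eta assumes).
prep_features <- function(spectra, chain, subset, state = NULL, scale = TRUE) {
  if (is.character(chain)) chain <- preprocess_chain(chain)
  Z <- apply_chain(spectra, chain)
  if (!is.null(subset)) {
    bands <- if (inherits(subset, "wavelength_subset")) subset$bands else subset
    Z <- Z[, bands, drop = FALSE]
  }
  colnames(Z) <- paste0("b", seq_len(ncol(Z)))   # stable names for formula learners
  if (is.null(state)) {
    if (identical(scale, "minmax")) {
      hi <- apply(Z, 2, max); lo <- apply(Z, 2, min)
      ctr <- (hi + lo) / 2
      scl <- (hi - lo) / 2
      scl[scl == 0] <- 1
    } else {
      ctr <- colMeans(Z)
      if (isTRUE(scale)) {
        scl <- apply(Z, 2, stats::sd)
        scl[scl == 0] <- 1
      } else scl <- rep(1, ncol(Z))
    }
    state <- list(center = ctr, scale = scl)
  }
  list(Z = sweep(sweep(Z, 2, state$center), 2, state$scale, "/"),
       state = state, chain = chain)
}

new_trained_predictor <- function(kind, task, fit, chain, subset, wavelength,
                                  norm, extra = list()) {
  structure(c(list(kind = kind, task = task, fit = fit, chain = chain,
                   subset = subset, wavelength = wavelength, norm = norm),
              extra),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat("<trained_predictor> ", x$kind, " (", x$task, "), chain = ",
      x$chain$name,
      if (!is.null(x$subset)) paste0(", ", length(x$subset$bands), " bands")
      else ", full spectrum", "\n", sep = "")
  invisible(x)
}

#' Classifier specification
#'
#' @param kind `"LR"` (multinomial logistic regression), `"SVM"` (RBF
#'   kernel, one-vs-one voting) or `"MLP"` (single hidden layer, softmax
#'   output).
#' @param hidden MLP hidden-layer width (default 50).
#' @param cost SVM regularisation constant.
#' @param maxit iteration cap for LR / MLP optimisation.
#' @param seed fixes random initialisation (MLP weights).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("LR", "SVM", "MLP"), hidden = 50,
                            cost = 10, maxit = 300, seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hidden = hidden, cost = cost, maxit = maxit,
                 seed = seed),
            class = "classifier_spec")
}

#' Train a root-type classifier
#'
#' Applies the pre-processing chain and optional band subset, standardises
#' the resulting features on the training set, and fits the requested
#' learner. Deterministic under the spec's seed.
#'
#' @param x labelled [spectrum_set()], or a samples x bands matrix (then
#'   supply `labels` and optionally `wavelength`).
#' @param spec a [classifier_spec()].
#' @param chain chain name or [preprocess_chain()] (default `"Raw"`).
#' @param subset optional `wavelength_subset` or band indices.
#' @param labels,wavelength used when `x` is a bare matrix.
#' @return a `trained_predictor`.
#' @export
train_classifier <- function(x, spec = classifier_spec(), chain = "Raw",
                             subset = NULL, labels = NULL, wavelength = NULL) {
  inp <- resolve_xy(x, labels, wavelength)
  lab <- factor(inp$y)
  if (nlevels(lab) < 2) stop("need at least 2 classes")
  if (any(table(lab) < 2)) stop("every class needs >= 2 training samples")
  pp <- prep_features(inp$spectra, chain, subset)
  fit <- switch(spec$kind,
    LR = {
      df <- data.frame(.label = lab, pp$Z)
      nnet::multinom(.label ~ ., df, trace = FALSE, maxit = spec$maxit,
                     MaxNWts = 100000)
    },
    SVM = e1071::svm(pp$Z, lab, kernel = "radial", cost = spec$cost,
                     scale = FALSE),
    MLP = with_seed(spec$seed,
      nnet::nnet(pp$Z, nnet::class.ind(lab), size = spec$hidden,
                 softmax = TRUE, maxit = spec$maxit, MaxNWts = 1e6,
                 trace = FALSE)))
  sub <- if (inherits(subset, "wavelength_subset")) subset
         else if (!is.null(subset)) new_wavelength_subset(subset, "manual")
  new_trained_predictor(spec$kind, "classification", fit, pp$chain, sub,
                        inp$wavelength, pp$state,
                        list(levels = levels(lab), spec = spec))
}

#' LSSVM configuration
#'
#' RBF kernel `K(u, v) = exp(-||u - v||^2 / sigma2)` with ridge-style
#' regularisation `gamma`; defaults gamma = sigma2 = 2.
#'
#' @param gamma regularisation constant (> 0).
#' @param sigma2 RBF kernel width (> 0); `kernel = "linear"` ignores it.
#' @param kernel `"rbf"` or `"linear"`.
#' @return list of class `lssvm_config`.
#' @export
lssvm_config <- function(gamma = 2, sigma2 = 2, kernel = c("rbf", "linear")) {
  if (gamma <= 0 || sigma2 <= 0) stop("gamma and sigma2 must be > 0")
  structure(list(gamma = gamma, sigma2 = sigma2, kernel = match.arg(kernel)),
            class = "lssvm_config")
}

lssvm_kernel <- function(U, V, config) {
  if (config$kernel == "linear") return(tcrossprod(U, V))
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
  exp(-pmax(d2, 0) / config$sigma2)
}

#' Train a least-squares SVM regressor
#'
#' Solves the LS-SVM dual system
#' `[[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y]`
#' in one dense solve; predictions are `sum_i alpha_i K(x_i, .) + b`.
#'
#' @param x [spectrum_set()] or matrix.
#' @param y response vector, or an analyte name when `x` is a spectrum set
#'   with concentrations.
#' @param config an [lssvm_config()].
#' @inheritParams train_classifier
#' @return a `trained_predictor`.
#' @export
lssvm_train <- function(x, y = NULL, config = lssvm_config(), chain = "Raw",
                        subset = NULL, wavelength = NULL) {
  inp <- resolve_xy(x, y, wavelength)
  yv <- as.numeric(inp$y)
  n <- length(yv)
  if (n < 2) stop("need at least 2 samples")
  # centre only: the chain (e.g. SNV) sets the scale the kernel width
  # refers to; per-band autoscaling would inflate spectral distances
  pp <- prep_features(inp$spectra, chain, subset, scale = FALSE)
  K <- lssvm_kernel(pp$Z, pp$Z, config)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / config$gamma))
  sol <- tryCatch(solve(M, c(0, yv)),
                  error = function(e) stop("singular LS-SVM system: ",
                                           conditionMessage(e)))
  sub <- if (inherits(subset, "wavelength_subset")) subset
         else if (!is.null(subset)) new_wavelength_subset(subset, "manual")
  new_trained_predictor("LSSVM", "regression",
                        list(b = sol[1], alpha = sol[-1], X = pp$Z,
                             config = config),
                        pp$chain, sub, inp$wavelength, pp$state)
}

#' ELM configuration
#'
#' @param nodes hidden sigmoid nodes (default 40).
#' @param seed fixes the random input weights (uniform(-1, 1)) and biases
#'   (uniform(0, 1)).
#' @return list of class `elm_config`.
#' @export
elm_config <- function(nodes = 40, seed = 1) {
  if (nodes < 1) stop("nodes must be >= 1")
  structure(list(nodes = nodes, seed = seed), class = "elm_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train an extreme learning machine
#'
#' Random fixed input weights, sigmoid hidden layer, and minimum-norm
#' least-squares output weights via the Moore-Penrose pseudoinverse.
#'
#' @inheritParams lssvm_train
#' @param config an [elm_config()].
#' @return a `trained_predictor`.
#' @export
elm_train <- function(x, y = NULL, config = elm_config(), chain = "Raw",
                      subset = NULL, wavelength = NULL) {
  inp <- resolve_xy(x, y, wavelength)
  yv <- as.numeric(inp$y)
  pp <- prep_features(inp$spectra, chain, subset)
  p <- ncol(pp$Z)
  with_seed(config$seed, {
    W <- matrix(stats::runif(p * config$nodes, -1, 1), p, config$nodes)
    bias <- stats::runif(config$nodes, 0, 1)
    H <- sigmoid(sweep(pp$Z %*% W, 2, bias, "+"))
    beta <- drop(MASS::ginv(H) %*% yv)
    sub <- if (inherits(subset, "wavelength_subset")) subset
           else if (!is.null(subset)) new_wavelength_subset(subset, "manual")
    new_trained_predictor("ELM", "regression",
                          list(W = W, bias = bias, beta = beta,
                               config = config),
                          pp$chain, sub, inp$wavelength, pp$state)
  })
}

#' BPNN configuration
#'
#' @param hidden hidden neurons (default 8).
#' @param epochs full-batch gradient-descent epochs (default 1000).
#' @param lr learning rate eta (default 0.6).
#' @param target_mse early-stop threshold on the training MSE, computed on
#'   the standardised response scale (default 1e-5).
#' @param seed fixes weight initialisation.
#' @return list of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden = 8, epochs = 1000, lr = 0.6,
                        target_mse = 1e-5, seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  structure(list(hidden = hidden, epochs = epochs, lr = lr,
                 target_mse = target_mse, seed = seed),
            class = "bpnn_config")
}

#' Train a back-propagation neural network
#'
#' Single sigmoid hidden layer, linear output, full-batch gradient descent
#' on the mean squared error of the standardised response. Stops at the
#' epoch limit or when the target MSE is reached; the loss trajectory is
#' recorded and divergence (non-finite loss) is reported with its epoch.
#'
#' @inheritParams lssvm_train
#' @param config a [bpnn_config()].
#' @return a `trained_predictor` whose fit records `loss` (per-epoch MSE)
#'   and `early_stop`.
#' @export
bpnn_train <- function(x, y = NULL, config = bpnn_config(), chain = "Raw",
                       subset = NULL, wavelength = NULL) {
  inp <- resolve_xy(x, y, wavelength)
  yv <- as.numeric(inp$y)
  # classical BPNN convention: inputs and target mapped to [-1, 1], which
  # is the scale the fixed learning rate is stable on
  pp <- prep_features(inp$spectra, chain, subset, scale = "minmax")
  n <- nrow(pp$Z); p <- ncol(pp$Z); h <- config$hidden
  y_ctr <- (max(yv) + min(yv)) / 2
  y_scl <- (max(yv) - min(yv)) / 2
  if (y_scl == 0) stop("response has zero variance")
  ys <- (yv - y_ctr) / y_scl
  with_seed(config$seed, {
    W1 <- matrix(stats::runif(p * h, -0.5, 0.5), p, h) / sqrt(p)
    b1 <- rep(0, h)
    w2 <- stats::runif(h, -0.5, 0.5) / sqrt(h)
    b2 <- 0
    loss <- numeric(0)
    early <- FALSE
    for (epoch in seq_len(config$epochs)) {
      A <- sigmoid(sweep(pp$Z %*% W1, 2, b1, "+"))   # n x h
      pred <- drop(A %*% w2) + b2
      err <- pred - ys
      mse <- mean(err^2)
      if (!is.finite(mse))
        stop("BPNN diverged (non-finite loss) at epoch ", epoch)
      loss <- c(loss, mse)
      if (mse <= config$target_mse) { early <- TRUE; break }
      # gradients of mean(err^2)
      g_pred <- 2 * err / n
      g_w2 <- drop(crossprod(A, g_pred))
      g_b2 <- sum(g_pred)
      g_A <- tcrossprod(g_pred, w2) * A * (1 - A)
      g_W1 <- crossprod(pp$Z, g_A)
      g_b1 <- colSums(g_A)
      W1 <- W1 - config$lr * g_W1
      b1 <- b1 - config$lr * g_b1
      w2 <- w2 - config$lr * g_w2
      b2 <- b2 - config$lr * g_b2
    }
    sub <- if (inherits(subset, "wavelength_subset")) subset
           else if (!is.null(subset)) new_wavelength_subset(subset, "manual")
    new_trained_predictor("BPNN", "regression",
                          list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                               y_center = y_ctr, y_scale = y_scl,
                               loss = loss, early_stop = early,
                               config = config),
                          pp$chain, sub, inp$wavelength, pp$state)
  })
}

#' Predict from a trained predictor
#'
#' Re-applies the stored pre-processing chain, band subset and feature
#' normalisation, then the learner. Spectrum sets must carry a band axis
#' identical to the training axis.
#'
#' @param object a `trained_predictor`.
#' @param newdata [spectrum_set()] or samples x bands matrix on the full
#'   (untrimmed, un-subset) band axis the model was trained on.
#' @param ... ignored.
#' @return factor of class labels (classification) or numeric
#'   concentrations in original units (regression).
#' @export
predict.trained_predictor <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) {
    if (!is.null(object$wavelength) &&
        (length(newdata$wavelength) != length(object$wavelength) ||
         any(abs(newdata$wavelength - object$wavelength) > 1e-8)))
      stop("band axis mismatch between model and new spectra")
    newdata <- newdata$spectra
  }
  pp <- prep_features(newdata, object$chain, object$subset, state = object$norm)
  Z <- pp$Z
  switch(object$kind,
    LR = {
      df <- as.data.frame(Z)
      factor(as.character(stats::predict(object$fit, df)),
             levels = object$levels)
    },
    SVM = factor(as.character(stats::predict(object$fit, Z)),
                 levels = object$levels),
    MLP = {
      pr <- stats::predict(object$fit, Z)
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = object$levels)
    },
    LSSVM = {
      K <- lssvm_kernel(Z, object$fit$X, object$fit$config)
      drop(K %*% object$fit$alpha) + object$fit$b
    },
    ELM = {
      H <- sigmoid(sweep(Z %*% object$fit$W, 2, object$fit$bias, "+"))
      drop(H %*% object$fit$beta)
    },
    BPNN = {
      A <- sigmoid(sweep(Z %*% object$fit$W1, 2, object$fit$b1, "+"))
      (drop(A %*% object$fit$w2) + object$fit$b2) * object$fit$y_scale +
        object$fit$y_center
    },
    stop("unknown learner kind: ", object$kind))
}
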