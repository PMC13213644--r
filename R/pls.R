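# Partial least squares core (NIPALS), shared by the wavelength selectors,
# cross-validation scoring, and PLS-DA.

#' Fit a PLS regression model
#'
#' NIPALS with deflation; handles a single response (PLS1) or a response
#' matrix (PLS2, used for one-hot discriminant analysis). Data are centred
#' internally; successive score vectors are mutually orthogonal by
#' construction. Extraction stops early if the residual X carries no
#' variance.
#'
#' @param X samples x bands matrix.
#' @param y response vector or samples x responses matrix.
#' @param n_lv number of latent variables, `<= min(samples - 1, bands)`.
#' @return object of class `pls_model` with scores, weights, loadings and
#'   the regression coefficients `coef` (bands x responses) plus
#'   `intercept`.
#' @export
pls_fit <- function(X, y, n_lv) {
  X <- as.matrix(X)
  Y <- as.matrix(y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and y sizes disagree")
  if (n_lv > min(n - 1, p))
    stop("n_lv must be <= min(samples - 1, bands)")
  if (all(apply(Y, 2, stats::sd) == 0)) stop("response has zero variance")
  x_center <- colMeans(X); y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center); Yc <- sweep(Y, 2, y_center)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, ncol(Y), n_lv); TT <- matrix(0, n, n_lv)
  a_used <- 0L
  ssx_tot <- sum(Xc^2)
  for (a in seq_len(n_lv)) {
    S <- crossprod(Xc, Yc)                    # p x m covariance
    if (sqrt(sum(S^2)) < 1e-12 * (1 + ssx_tot)) break
    w <- if (ncol(Yc) == 1L) S[, 1] else svd(S, nu = 1, nv = 0)$u[, 1]
    w <- w / sqrt(sum(w^2))
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12 * (1 + ssx_tot)) break
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- drop(crossprod(Yc, t_a)) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    Yc <- Yc - tcrossprod(t_a, q_a)
    W[, a] <- w; P[, a] <- p_a; Q[, a] <- q_a; TT[, a] <- t_a
    a_used <- a
  }
  if (a_used == 0L) stop("no extractable latent variable (degenerate X)")
  idx <- seq_len(a_used)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Q <- Q[, idx, drop = FALSE]; TT <- TT[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_lv = a_used, weights = W, loadings = P, y_loadings = Q,
                 scores = TT, coef = B,
                 x_center = x_center, y_center = y_center,
                 intercept = drop(y_center - crossprod(x_center, B)),
                 x_ss_total = ssx_tot, x_ss_residual = sum(Xc^2)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- sweep(newdata %*% object$coef, 2, -object$intercept)
  if (ncol(out) == 1L) drop(out) else out
}

#' Cross-validated PLS error
#'
#' Root-mean-square of out-of-fold prediction errors under seeded k-fold
#' partitioning; the quantity minimised by the wavelength selectors.
#'
#' @param X,y as in [pls_fit()].
#' @param n_lv latent variables (capped per training fold size).
#' @param folds number of folds (>= 2).
#' @param seed integer; fixes the fold assignment.
#' @return RMSECV value.
#' @export
rmsecv <- function(X, y, n_lv, folds = 10, seed = 1) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > n) stop("more folds than samples")
  fold_id <- kfold_indices(n, folds, seed = seed)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    a <- min(n_lv, sum(tr) - 1L, ncol(X))
    fit <- pls_fit(X[tr, , drop = FALSE], y[tr], a)
    press <- press + sum((y[te] - predict(fit, X[te, , drop = FALSE]))^2)
  }
  sqrt(press / n)
}
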