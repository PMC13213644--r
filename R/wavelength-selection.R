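# Effective-wavelength selection: competitive adaptive reweighted sampling
# (CARS), successive projections algorithm (SPA) with SPXY partitioning,
# and random frog. All selectors are deterministic under a fixed seed and
# return a `wavelength_subset` with per-iteration diagnostics.

new_wavelength_subset <- function(bands, selector, diagnostics = list()) {
  bands <- as.integer(bands)
  if (!length(bands)) stop("empty wavelength subset")
  if (anyDuplicated(bands)) stop("duplicate band indices in subset")
  structure(list(bands = bands, selector = selector,
                 diagnostics = diagnostics),
            class = "wavelength_subset")
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat("<wavelength_subset> ", length(x$bands), " bands by ", x$selector,
      ": ", paste(utils::head(x$bands, 12), collapse = ", "),
      if (length(x$bands) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Variable-reduction percentage
#'
#' `100 * (1 - retained/total)`, reported to 2 decimals — the bookkeeping
#' used to compare selector parsimony (e.g. 53 of 270 bands kept = 80.37 %
#' reduction).
#'
#' @param total total band count.
#' @param retained a `wavelength_subset` or a retained-band count.
#' @return percentage rounded to 2 decimals.
#' @export
variable_reduction <- function(total, retained) {
  k <- if (inherits(retained, "wavelength_subset")) length(retained$bands)
       else as.numeric(retained)
  if (k < 1 || k > total) stop("retained count must be in [1, total]")
  round(100 * (1 - k / total), 2)
}

# rank weights descending with deterministic tie-break by lower band index
rank_desc <- function(w) order(-w, seq_along(w))

#' CARS configuration
#'
#' @param n_runs number of sampling runs (default 50).
#' @param calibration_fraction Monte Carlo calibration fraction per run.
#' @param max_lv maximum PLS latent variables (default 14).
#' @param folds RMSECV fold count (default 10).
#' @param seed integer seed.
#' @return list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50, calibration_fraction = 0.8,
                        max_lv = 14, folds = 10, seed = 1) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop("calibration_fraction must be in (0, 1)")
  structure(list(n_runs = n_runs, calibration_fraction = calibration_fraction,
                 max_lv = max_lv, folds = folds, seed = seed),
            class = "cars_config")
}

#' Exponentially decreasing retention schedule
#'
#' Fraction of bands retained at each CARS run: `r_i = a * exp(-k * i)`
#' through the endpoints r_1 = 1 (all bands) and r_N = 2/p (two bands).
#'
#' @param n_runs number of runs.
#' @param p number of bands.
#' @return numeric vector of retention fractions.
#' @export
cars_edf <- function(n_runs, p) {
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)                       # so that a * exp(-k * 1) = 1
  a * exp(-k * seq_len(n_runs))
}

#' Competitive adaptive reweighted sampling
#'
#' Each run fits a PLS model on a random calibration subsample, ranks bands
#' by absolute regression coefficient, enforces the exponentially
#' decreasing retention bound, then adaptively resamples the retained bands
#' with probability proportional to normalised |coefficient|. Every run's
#' subset is scored by k-fold RMSECV; the subset with the minimum RMSECV is
#' returned.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param config a [cars_config()].
#' @return `wavelength_subset` with diagnostics: `subset_size`, `rmsecv`
#'   trajectories and the per-run subsets.
#' @export
cars_select <- function(X, y, config = cars_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop("need at least 3 bands")
  ratios <- cars_edf(config$n_runs, p)
  n_cal <- max(2L, round(config$calibration_fraction * n))
  with_seed(config$seed, {
    S <- seq_len(p)
    sizes <- integer(config$n_runs)
    errs <- numeric(config$n_runs)
    subsets <- vector("list", config$n_runs)
    cv_seeds <- sample.int(.Machine$integer.max, config$n_runs)
    for (i in seq_len(config$n_runs)) {
      cal <- sample.int(n, n_cal)
      a <- min(config$max_lv, n_cal - 1L, length(S))
      fit <- tryCatch(pls_fit(X[cal, S, drop = FALSE], y[cal], a),
                      error = function(e)
                        stop("PLS failed at CARS run ", i, ": ",
                             conditionMessage(e)))
      w <- abs(drop(fit$coef))
      keep_n <- max(2L, min(round(ratios[i] * p), length(S)))
      S <- S[rank_desc(w)[seq_len(keep_n)]]
      w <- w[rank_desc(w)[seq_len(keep_n)]]
      # adaptive reweighted sampling: |coef|-weighted draw with replacement
      if (sum(w) > 0) {
        drawn <- unique(sample(seq_along(S), keep_n, replace = TRUE,
                               prob = w / sum(w)))
        if (length(drawn) >= 2L) S <- S[sort(drawn)]
      }
      S <- sort(S)
      subsets[[i]] <- S
      sizes[i] <- length(S)
      a_cv <- min(config$max_lv, length(S))
      errs[i] <- rmsecv(X[, S, drop = FALSE], y, a_cv, config$folds,
                        seed = cv_seeds[i])
    }
    best <- which.min(errs)
    new_wavelength_subset(subsets[[best]], "CARS",
                          list(subset_size = sizes, rmsecv = errs,
                               best_run = best, edf_ratio = ratios,
                               subsets = subsets))
  })
}

#' SPXY calibration/test partition
#'
#' Kennard-Stone-style selection on the joint normalised X-y distance
#' `d = dx/max(dx) + dy/max(dy)`: the calibration set receives the most
#' mutually distant samples, starting from the globally most distant pair;
#' the remainder forms the test set. Fully deterministic (ties broken by
#' lower index).
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param test_ratio fraction assigned to the test set.
#' @return list with sorted `calibration` and `test` index vectors.
#' @export
spxy_split <- function(X, y, test_ratio = 1 / 3) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (test_ratio <= 0 || test_ratio >= 1) stop("test_ratio must be in (0, 1)")
  dx <- as.matrix(stats::dist(X))
  dy <- as.matrix(stats::dist(y))
  mx <- max(dx); my <- max(dy)
  d <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  n_test <- max(1L, round(test_ratio * n))
  n_cal <- n - n_test
  # seed pair: maximal joint distance, first occurrence in index order
  pos <- which(d == max(d), arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  sel <- sort(unique(as.integer(pos[1, ])))
  if (length(sel) == 1L) sel <- c(sel, setdiff(seq_len(n), sel)[1])
  while (length(sel) < n_cal) {
    rest <- setdiff(seq_len(n), sel)
    mind <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(mind)])
  }
  list(calibration = sort(sel), test = sort(setdiff(seq_len(n), sel)))
}

#' SPA configuration
#'
#' @param m_max maximum candidate subset size (default 50).
#' @param test_ratio SPXY test fraction (default 1/3).
#' @param standardize standardise bands on the calibration set first.
#' @param alpha F-test level for the parsimony rule (default 0.25).
#' @return list of class `spa_config`.
#' @export
spa_config <- function(m_max = 50, test_ratio = 1 / 3, standardize = TRUE,
                       alpha = 0.25) {
  if (m_max < 1) stop("m_max must be >= 1")
  structure(list(m_max = m_max, test_ratio = test_ratio,
                 standardize = standardize, alpha = alpha),
            class = "spa_config")
}

# one projection chain: successively most-orthogonal columns from `start`
spa_chain <- function(Xc, start, m_max) {
  p <- ncol(Xc)
  R <- Xc
  chain <- integer(m_max)
  chain[1] <- start
  norms0 <- colSums(Xc^2)
  for (step in seq_len(m_max)) {
    j <- chain[step]
    v <- R[, j]
    vv <- sum(v^2)
    if (vv < 1e-12 * (1 + max(norms0))) { chain <- chain[seq_len(step)]; break }
    R <- R - v %*% (crossprod(v, R) / vv)
    if (step == m_max) break
    nr <- colSums(R^2)
    nr[chain[seq_len(step)]] <- -1
    nr[nr < 1e-10 * (1 + max(norms0))] <- -1     # collinear leftovers
    if (all(nr < 0)) { chain <- chain[seq_len(step)]; break }
    chain[step + 1L] <- which.max(nr)
  }
  chain[chain > 0]
}

#' Successive projections algorithm
#'
#' Builds, from every starting band, a chain of successively
#' most-orthogonal bands (up to `m_max`), scores each candidate subset by
#' the PRESS of a multiple linear regression on an SPXY calibration/test
#' partition, and returns the smallest subset whose PRESS is not
#' significantly worse than the minimum under an F-test at level `alpha`.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param config a [spa_config()].
#' @return `wavelength_subset` with diagnostics: `press` per subset size,
#'   the PRESS-minimal subset, and the chosen size.
#' @export
spa_select <- function(X, y, config = spa_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  split <- spxy_split(X, y, config$test_ratio)
  cal <- split$calibration; tst <- split$test
  m_max <- min(config$m_max, length(cal) - 2L, p)
  if (m_max < 1) stop("m_max too large for the calibration sample count")
  ctr <- colMeans(X[cal, , drop = FALSE])
  scl <- apply(X[cal, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- if (config$standardize) sweep(sweep(X, 2, ctr), 2, scl, "/")
        else sweep(X, 2, ctr)
  Xc <- Xs[cal, , drop = FALSE]
  chains <- lapply(seq_len(p), function(j) spa_chain(Xc, j, m_max))
  press_of <- function(subset) {
    A <- cbind(1, Xs[cal, subset, drop = FALSE])
    fit <- stats::.lm.fit(A, y[cal])
    pred <- drop(cbind(1, Xs[tst, subset, drop = FALSE]) %*% fit$coefficients)
    sum((y[tst] - pred)^2)
  }
  best_press <- rep(Inf, m_max)
  best_subset <- vector("list", m_max)
  for (ch in chains) {
    for (m in seq_along(ch)) {
      pr <- press_of(ch[seq_len(m)])
      if (pr < best_press[m]) { best_press[m] <- pr; best_subset[[m]] <- ch[seq_len(m)] }
    }
  }
  ok <- is.finite(best_press)
  press_min <- min(best_press[ok])
  m_star <- which.min(best_press)
  f_crit <- stats::qf(1 - config$alpha, length(tst), length(tst))
  chosen <- which(ok & best_press <= f_crit * press_min)[1]
  new_wavelength_subset(best_subset[[chosen]], "SPA",
                        list(press = best_press, chosen_size = chosen,
                             press_minimal_size = m_star,
                             press_minimal_subset = best_subset[[m_star]],
                             split = split))
}

#' Random frog configuration
#'
#' @param n_iter chain length (default 2000).
#' @param q_init initial subset size Q (default 2).
#' @param variance_factor SD of the proposed subset size as a fraction of
#'   the current size.
#' @param candidate_factor over-sampling factor when growing a subset.
#' @param eta acceptance damping for worse candidates: a better candidate
#'   is always accepted, a worse one with probability
#'   `eta * perf_cand / perf_cur` (default 0.1, the original random-frog
#'   rule; `eta = 1` gives undamped Metropolis-style ratio acceptance).
#' @param n_lv maximum PLS latent variables for scoring.
#' @param folds cross-validation folds for the performance score.
#' @param threshold optional selection-probability cutoff; when `NULL` the
#'   final subset is the top-k by probability with k chosen by minimal
#'   RMSECV over `k_range`.
#' @param k_range candidate k values for top-k mode.
#' @param seed integer seed.
#' @return list of class `frog_config`.
#' @export
frog_config <- function(n_iter = 2000, q_init = 2, variance_factor = 0.3,
                        candidate_factor = 3, eta = 0.1, n_lv = 10,
                        folds = 5, threshold = NULL, k_range = 2:30,
                        seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (q_init < 1) stop("q_init must be >= 1")
  if (eta <= 0 || eta > 1) stop("eta must be in (0, 1]")
  structure(list(n_iter = n_iter, q_init = q_init,
                 variance_factor = variance_factor,
                 candidate_factor = candidate_factor, eta = eta, n_lv = n_lv,
                 folds = folds, threshold = threshold, k_range = k_range,
                 seed = seed),
            class = "frog_config")
}

#' Random frog selection
#'
#' Runs a stochastic subset chain: each iteration proposes a candidate
#' subset of normally perturbed size (shrunk by dropping the weakest PLS
#' coefficients, or grown by drawing extra bands and re-ranking) and
#' accepts it always when it scores better, and with damped probability
#' `eta * perf_cand / perf_cur` when worse, where performance is the
#' inverse cross-validated PLS RMSECV. A band's
#' selection probability is the fraction of accepted subsets containing
#' it; the returned subset is the top-k by probability (k minimising
#' RMSECV) or all bands above `threshold`.
#'
#' @param X samples x bands matrix.
#' @param y response vector.
#' @param config a [frog_config()].
#' @return `wavelength_subset`; diagnostics carry the full
#'   selection-probability vector and the accepted-size trace.
#' @export
random_frog_select <- function(X, y, config = frog_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (config$q_init > p) stop("q_init must be <= number of bands")
  q_max <- min(p, n - 2L)
  with_seed(config$seed, {
    fold_id <- kfold_indices(n, config$folds,
                             seed = sample.int(.Machine$integer.max, 1))
    score <- function(cols) {          # RMSECV on fixed folds
      press <- 0
      for (f in seq_len(config$folds)) {
        tr <- fold_id != f
        a <- min(config$n_lv, sum(tr) - 1L, length(cols))
        fit <- pls_fit(X[tr, cols, drop = FALSE], y[tr], a)
        press <- press +
          sum((y[!tr] - predict(fit, X[!tr, cols, drop = FALSE]))^2)
      }
      sqrt(press / n)
    }
    V <- sort(sample.int(p, min(config$q_init, q_max)))
    perf_V <- score(V)
    count <- numeric(p)
    size_trace <- integer(config$n_iter)
    for (it in seq_len(config$n_iter)) {
      count[V] <- count[V] + 1          # subset held entering the iteration
      size_trace[it] <- length(V)
      q_cur <- length(V)
      q_star <- round(stats::rnorm(1, q_cur, config$variance_factor * q_cur))
      q_star <- max(1L, min(q_max, q_star))
      if (q_star == q_cur) {
        cand <- V
      } else if (q_star < q_cur) {
        a <- min(config$n_lv, n - 1L, length(V))
        w <- abs(drop(pls_fit(X[, V, drop = FALSE], y, a)$coef))
        cand <- sort(V[rank_desc(w)[seq_len(q_star)]])
      } else {
        outside <- setdiff(seq_len(p), V)
        grow <- min(length(outside),
                    config$candidate_factor * (q_star - q_cur))
        pool <- sort(c(V, sample(outside, grow)))
        a <- min(config$n_lv, n - 1L, length(pool))
        w <- abs(drop(pls_fit(X[, pool, drop = FALSE], y, a)$coef))
        cand <- sort(pool[rank_desc(w)[seq_len(min(q_star, length(pool)))]])
      }
      perf_cand <- if (identical(cand, V)) perf_V else score(cand)
      # perf = 1/RMSECV: better candidates always accepted, worse ones damped
      acc <- if (perf_cand <= perf_V) 1 else config$eta * perf_V / perf_cand
      if (stats::runif(1) <= acc) {
        V <- cand; perf_V <- perf_cand
      }
    }
    prob <- count / config$n_iter
    ranked <- rank_desc(prob)
    if (!is.null(config$threshold)) {
      bands <- which(prob > config$threshold)
      if (!length(bands)) bands <- ranked[seq_len(2)]
      bands <- sort(bands)
      diag_k <- NA_integer_
    } else {
      ks <- config$k_range[config$k_range <= p]
      errs <- vapply(ks, function(k) score(sort(ranked[seq_len(k)])),
                     numeric(1))
      diag_k <- ks[which.min(errs)]
      bands <- sort(ranked[seq_len(diag_k)])
    }
    new_wavelength_subset(bands, "random_frog",
                          list(probability = prob, size_trace = size_trace,
                               chosen_k = diag_k))
  })
}
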