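# deterministic hand-built table: 3 groups x 3 samples + 2 QC
hand_table <- function(rows) {
  group <- c(rep(c("tuberous", "taproot", "old"), each = 3), "QC", "QC")
  feature_table(rows, group)
}

test_that("response/occurrence filtering follows the stated rule exactly", {
  always_high <- rep(6000, 11)
  seventy_pct <- c(6000, 6000, 400, 6000, 6000, 400, 6000, 6000, 400, 6000, 6000)
  one_group_high <- c(rep(6000, 3), rep(400, 6), 6000, 6000)
  tab <- hand_table(rbind(always_high, seventy_pct, one_group_high))
  kept <- filter_features(tab, min_response = 5000, occurrence = 0.8)
  expect_identical(rownames(kept$intensity), c("always_high", "one_group_high"))
})

test_that("filtering matches a brute-force re-scan on a simulated table", {
  ft <- simulate_feature_table(n_per_group = 6, n_features = 200, seed = 12)
  kept <- filter_features(ft, min_response = 20000, occurrence = 0.8)
  brute <- sapply(seq_len(nrow(ft$intensity)), function(i) {
    any(sapply(c("tuberous", "taproot", "old"), function(g)
      mean(ft$intensity[i, ft$group == g] >= 20000) >= 0.8))
  })
  expect_equal(nrow(kept$intensity), sum(brute))
})

test_that("the ANOVA/FC screen excludes the FC = 2 boundary and flat features", {
  base <- matrix(1000, 3, 11)
  base[1, 1:3] <- 2000                     # FC exactly 2, clear ANOVA
  base[2, 1:3] <- 2001                     # FC just above 2
  tab <- hand_table(base)
  ds <- anova_fc_screen(tab, normalize = FALSE)
  expect_false(1 %in% ds$features)   # strict inequality at the boundary
  expect_true(2 %in% ds$features)
  expect_false(3 %in% ds$features)   # identical means: p ~ 1
  expect_gt(ds$table$p[3], 0.9)
  expect_equal(ds$table$fc[1], 2, tolerance = 1e-12)
})

test_that("planted differential features are recovered at high sensitivity", {
  ft <- simulate_feature_table(n_per_group = 16, n_features = 400,
                               n_differential = 20, fc = 4, seed = 21)
  ds <- anova_fc_screen(ft)
  recovery <- mean(ft$planted %in% ds$features)
  expect_gte(recovery, 0.9)
  # false positives stay modest
  expect_lte(length(setdiff(ds$features, ft$planted)), 0.1 * 400)
})

test_that("the screen is invariant to sample order and global intensity rescaling", {
  ft <- simulate_feature_table(n_per_group = 6, n_features = 120, seed = 31)
  ds <- anova_fc_screen(ft)
  perm <- sample(ncol(ft$intensity))
  ft_perm <- feature_table(ft$intensity[, perm], ft$group[perm])
  expect_identical(anova_fc_screen(ft_perm)$features, ds$features)
  ft_scaled <- ft
  ft_scaled$intensity <- ft$intensity * 3.14
  expect_identical(anova_fc_screen(ft_scaled)$features, ds$features)
})

test_that("PCA explains rank-1 data in one component with ordered fractions", {
  u <- rnorm(12); v <- abs(rnorm(40)) + 1
  rank1 <- outer(v, u + 10)                # features x samples, positive
  tab <- feature_table(rank1, rep(c("tuberous", "taproot", "old"), 4))
  pc <- pca_scores(tab, n_components = 3, log2_transform = FALSE)
  expect_gt(pc$explained[1], 0.999)
  ft <- simulate_feature_table(n_per_group = 6, n_features = 100, seed = 41)
  pc2 <- pca_scores(ft, n_components = 5)
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_lte(sum(pc2$explained), 1 + 1e-12)
})

test_that("QC replicates cluster tighter than the biological groups in PCA space", {
  ft <- simulate_feature_table(n_per_group = 10, n_features = 300, seed = 51)
  pc <- pca_scores(ft, n_components = 2)
  qc <- pc$scores[ft$group == "QC", ]
  qc_spread <- mean(dist(qc))
  centroids <- sapply(c("tuberous", "taproot", "old"), function(g)
    colMeans(pc$scores[ft$group == g, , drop = FALSE]))
  between <- mean(dist(t(centroids)))
  expect_lt(qc_spread, between)
})

test_that("PLS-DA separates real groups but not shuffled labels", {
  ft <- simulate_feature_table(n_per_group = 12, n_features = 200,
                               n_differential = 40, fc = 4, seed = 61)
  fit <- plsda_fit(ft, n_components = 2, seed = 1)
  expect_gt(fit$q2, 0.5)
  expect_true(fit$r2x >= 0 && fit$r2x <= 1)
  expect_true(fit$r2y >= 0 && fit$r2y <= 1)
  # R2Y nondecreasing in components
  r2y <- sapply(1:4, function(a)
    plsda_fit(ft, n_components = a, seed = 1)$r2y)
  expect_true(all(diff(r2y) >= -1e-10))
  # permutation baseline
  cols <- ft$group != "QC"
  X <- t(log2(ft$intensity[, cols]))
  labs <- droplevels(ft$group[cols])
  q2_perm <- sapply(1:5, function(i) {
    set.seed(100 + i)
    plsda_fit(X, sample(labs), n_components = 2, seed = 1)$q2
  })
  expect_lte(mean(q2_perm), 0.1)
})

test_that("hierarchical clustering recovers two planted feature clusters", {
  set.seed(71)
  n_s <- 12
  up <- matrix(rnorm(10 * n_s, 12, 0.3), 10)
  down <- matrix(rnorm(10 * n_s, 6, 0.3), 10)
  up[, 1:6] <- up[, 1:6] + 4
  down[, 7:12] <- down[, 7:12] + 4
  m <- rbind(up, down)
  h <- hca_heatmap(m, linkage = "complete")
  cut2 <- stats::cutree(h$row_hclust, 2)
  expect_equal(length(unique(cut2[1:10])), 1)
  expect_equal(length(unique(cut2[11:20])), 1)
  expect_equal(length(h$row_hclust$order), 20)
  h2 <- hca_heatmap(m, linkage = "complete")
  expect_identical(h$row_order, h2$row_order)
  f <- tempfile(fileext = ".png")
  h3 <- hca_heatmap(m, linkage = "complete", file = f)
  expect_true(file.exists(f))
})
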