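# Synthetic feature table builder: reads x positions with controllable
# group shift at chosen positions.
toy_features <- function(n_per_group = 12, positions = 8:12, shift = 0,
                         shifted_positions = integer(0), seed = 1,
                         drop = NULL) {
  set.seed(seed)
  rows <- list()
  for (g in c("native", "control")) {
    for (r in seq_len(n_per_group)) {
      id <- paste0(g, r)
      pos <- positions
      if (!is.null(drop) && id %in% names(drop)) {
        pos <- setdiff(pos, drop[[id]])
      }
      mu <- ifelse(g == "native" & pos %in% shifted_positions, shift, 0)
      rows[[paste0(g, r)]] <- data.frame(
        read_id = id, contig = "c1", ref_position = pos,
        ref_base = "A", group = g,
        mean = rnorm(length(pos), mu, 1),
        median = rnorm(length(pos), mu, 1),
        std = abs(rnorm(length(pos), 1, 0.2)),
        dwell = 1L + rgeom(length(pos), 0.3))
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

test_that("k-mer matrix has 4k columns and honours the window", {
  ft <- toy_features()
  km1 <- assemble_kmer_matrix(ft, center = 10L, k = 1, min_reads = 5)
  expect_equal(ncol(km1$x), 4L)
  km3 <- assemble_kmer_matrix(ft, center = 10L, k = 3, min_reads = 5)
  expect_equal(ncol(km3$x), 12L)
  expect_equal(nrow(km3$x), 24L)
  # k=1 columns are exactly the four single-position features (dwell logged)
  at10 <- ft[ft$ref_position == 10L, ]
  key <- paste(at10$group, at10$read_id)
  ord <- match(paste(km1$group, km1$read_id), key)
  expect_equal(unname(km1$x[, 1]), at10$mean[ord])
  expect_equal(unname(km1$x[, 4]), log10(at10$dwell[ord]))
})

test_that("reads missing a window position are excluded", {
  ft <- toy_features(n_per_group = 5, drop = list(native1 = 9L,
                                                  native2 = 11L))
  km <- assemble_kmer_matrix(ft, center = 10L, k = 3, min_reads = 3)
  expect_equal(sum(km$group == "native"), 3L)
  expect_equal(sum(km$group == "control"), 5L)
  expect_false(any(is.na(km$x)))
})

test_that("too few complete reads is an insufficient-coverage error", {
  ft <- toy_features(n_per_group = 4)
  expect_error(assemble_kmer_matrix(ft, center = 10L, k = 3, min_reads = 10),
               "insufficient coverage")
  expect_error(assemble_kmer_matrix(ft, center = 10L, k = 2), "odd")
})

test_that("rank-1 data loads entirely on the first component", {
  x <- cbind(1:20, 2 * (1:20))
  pc <- pca_project(x, n_components = 2)
  expect_equal(pc$explained_variance_ratio[1], 1)
  expect_lt(abs(mean(pc$scores[, 1])), 1e-9)
})

test_that("PCA scores match the eigendecomposition oracle up to sign", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(6:20, 1); p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    pc <- pca_project(x, n_components = 2)
    oracle <- oracle_pca_scores(x, n_components = 2)
    for (j in 1:2) {
      agree <- min(max(abs(pc$scores[, j] - oracle$scores[, j])),
                   max(abs(pc$scores[, j] + oracle$scores[, j])))
      expect_lt(agree, 1e-8)
    }
    expect_true(all(diff(pc$explained_variance_ratio) < 1e-12))
    expect_true(all(pc$explained_variance_ratio >= -1e-12 &
                      pc$explained_variance_ratio <= 1 + 1e-12))
    expect_true(all(abs(colMeans(pc$scores)) < 1e-9))
  }
})

test_that("zero-variance columns are dropped; all-constant input errors", {
  x <- cbind(v1 = rnorm(10), v2 = rep(3, 10))
  pc <- pca_project(x, n_components = 1)
  expect_equal(pc$dropped_columns, "v2")
  expect_equal(ncol(pc$scores), 1L)
  expect_error(pca_project(cbind(rep(1, 10), rep(2, 10))), "degenerate")
})

test_that("identically distributed groups give a roughly uniform p", {
  set.seed(10)
  ps <- replicate(300, {
    scores <- matrix(rnorm(60 * 2), 60, 2)
    manova_test(scores, rep(c("native", "control"), 30))$p_value
  })
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("a 5-pooled-SD mean shift on PC1 is detected at p < 1e-3", {
  set.seed(11)
  scores <- rbind(cbind(rnorm(50, 0), rnorm(50)),
                  cbind(rnorm(50, 5), rnorm(50)))
  groups <- rep(c("control", "native"), each = 50)
  res <- manova_test(scores, groups)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$method, "manova_pillai")
})

test_that("MANOVA p ranks like a permutation oracle on small fixtures", {
  set.seed(12)
  fixtures <- lapply(1:12, function(i) {
    shift <- runif(1, 0, 1.5)
    list(scores = rbind(cbind(rnorm(15, 0), rnorm(15)),
                        cbind(rnorm(15, shift), rnorm(15))),
         groups = rep(c("control", "native"), each = 15))
  })
  p_pillai <- vapply(fixtures, function(f)
    manova_test(f$scores, f$groups)$p_value, numeric(1))
  p_perm <- vapply(seq_along(fixtures), function(i)
    oracle_permutation_p(fixtures[[i]]$scores, fixtures[[i]]$groups,
                         n_perm = 2000, seed = 100 + i), numeric(1))
  expect_gt(cor(rank(p_pillai), rank(p_perm)), 0.85)
})

test_that("statistics are invariant to row order and label swaps", {
  set.seed(13)
  scores <- rbind(cbind(rnorm(20, 0.8), rnorm(20)),
                  cbind(rnorm(20), rnorm(20)))
  groups <- rep(c("native", "control"), each = 20)
  base <- manova_test(scores, groups)
  perm <- sample(nrow(scores))
  shuffled <- manova_test(scores[perm, ], groups[perm])
  expect_equal(shuffled$statistic, base$statistic)
  expect_equal(shuffled$p_value, base$p_value)
  swapped <- manova_test(scores, ifelse(groups == "native",
                                        "control", "native"))
  expect_equal(swapped$statistic, base$statistic)
  expect_equal(swapped$p_value, base$p_value)
})

test_that("a single retained feature column reduces to one-way ANOVA", {
  set.seed(14)
  x <- c(rnorm(15, 0.5), rnorm(15))
  groups <- rep(c("native", "control"), each = 15)
  res <- manova_test(matrix(x, ncol = 1), groups)
  oracle <- stats::anova(stats::lm(x ~ groups))[["Pr(>F)"]][1]
  expect_equal(res$p_value, oracle, tolerance = 1e-6)
  tt <- stats::t.test(x ~ groups, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-6)
})

test_that("singular within-group covariance falls back to permutation", {
  scores <- cbind(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10))
  scores <- scores + 1e-12  # identical columns: singular within-group cov
  groups <- rep(c("native", "control"), each = 10)
  res <- manova_test(scores, groups, n_perm = 500, seed = 9)
  expect_equal(res$method, "permutation")
  expect_lt(res$p_value, 0.05)
})

test_that("the significance profile flags the shifted site region", {
  ft <- toy_features(n_per_group = 30, positions = 5:15, shift = 2,
                     shifted_positions = 9:11, seed = 20)
  prof <- significance_profile(ft, region = list(contig = "c1", start = 5L,
                                                 end = 16L),
                               k = 3, min_reads = 10)
  res <- prof$results
  expect_equal(res$neg_log10_p, -log10(res$p_value))
  peak <- res$position[which.max(res$neg_log10_p)]
  expect_true(peak %in% 8:12)
  expect_true(all(prof$flagged %in% 8:12))
  expect_true(length(prof$flagged) >= 1)
  # p = 1 would map to neg_log10_p = 0; all values are finite and >= 0
  expect_true(all(res$neg_log10_p >= 0 & is.finite(res$neg_log10_p)))
})

test_that("edge positions without a full window are skipped, not zeroed", {
  ft <- toy_features(n_per_group = 12, positions = 5:9)
  prof <- significance_profile(ft, region = list(contig = "c1", start = 5L,
                                                 end = 10L),
                               k = 3, min_reads = 5)
  expect_equal(prof$results$position, 6:8)
})

test_that("no testable positions is an explicit error", {
  ft <- toy_features(n_per_group = 2)
  expect_error(
    significance_profile(ft, region = list(contig = "c1", start = 8L,
                                           end = 13L), min_reads = 10),
    "no testable positions")
})
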