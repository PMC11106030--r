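#' Assemble the k-mer feature matrix around a center position
#'
#' Because a modified base perturbs the current of its neighbours as well,
#' testing uses a window of k consecutive positions (default 3). Each read
#' contributes one row of k x 4 features, ordered by position offset
#' (-floor(k/2) .. +floor(k/2)) then feature (mean, median, std, dwell).
#' Reads missing any window position are excluded — rows are complete by
#' construction. Dwell times are log10-transformed before inclusion to tame
#' their heavy tail (switchable).
#'
#' @param features Feature table from [build_feature_table()].
#' @param center 0-based reference position at the window center.
#' @param k Odd window width >= 1.
#' @param min_reads Minimum complete rows required per group.
#' @param log10_dwell Log-transform dwell before use.
#' @return List of class `kmer_feature_matrix`: `x` (numeric matrix, 4k
#'   columns), `group` (factor), `read_id`, `center`, `k`.
#' @export
assemble_kmer_matrix <- function(features, center, k = 3, min_reads = 10,
                                 log10_dwell = TRUE) {
  if (k < 1 || k %% 2 == 0) stop("k must be an odd integer >= 1")
  half <- (k - 1L) %/% 2L
  window <- (center - half):(center + half)
  sub <- features[features$ref_position %in% window, , drop = FALSE]
  feat_names <- c("mean", "median", "std", "dwell")

  key <- paste(sub$group, sub$read_id, sep = "\r")
  tab <- table(key)
  complete <- names(tab)[tab == k]
  sub <- sub[key %in% complete, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("insufficient coverage at position ", center,
         ": no read covers the full ", k, "-mer window")
  }

  sub$dwell_val <- if (log10_dwell) log10(sub$dwell) else as.numeric(sub$dwell)
  sub <- sub[order(match(paste(sub$group, sub$read_id, sep = "\r"), complete),
                   sub$ref_position), , drop = FALSE]
  n_rows <- length(complete)
  x <- matrix(NA_real_, nrow = n_rows, ncol = 4L * k)
  colnames(x) <- as.vector(vapply(window - center, function(off) {
    paste0("pos", ifelse(off >= 0, paste0("+", off), off), "_", feat_names)
  }, character(4)))
  vals <- cbind(sub$mean, sub$median, sub$std, sub$dwell_val)
  for (j in seq_len(k)) {
    x[, (j - 1L) * 4L + 1:4] <- vals[seq(j, nrow(sub), by = k), , drop = FALSE]
  }
  parts <- do.call(rbind, strsplit(complete, "\r", fixed = TRUE))
  group <- factor(parts[, 1L], levels = c("native", "control"))
  counts <- table(group)
  if (any(counts < min_reads)) {
    stop("insufficient coverage at position ", center, ": ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         " complete reads (minimum ", min_reads, " per group)")
  }
  structure(list(x = x, group = group, read_id = parts[, 2L],
                 center = center, k = k),
            class = "kmer_feature_matrix")
}

#' Principal-component projection of a feature matrix
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns dropped), then decomposed; scores are centered and components
#' ordered by decreasing explained variance.
#'
#' @param x Numeric matrix or a `kmer_feature_matrix`.
#' @param n_components Number of score columns to return.
#' @return List with `scores` (rows x n_components),
#'   `explained_variance_ratio`, and `dropped_columns`.
#' @export
pca_project <- function(x, n_components = 2) {
  if (inherits(x, "kmer_feature_matrix")) x <- x$x
  stopifnot(is.matrix(x), nrow(x) >= n_components + 1)
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("degenerate matrix: every column has zero variance")
  xs <- scale(x[, keep, drop = FALSE])
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance_ratio = evr,
       dropped_columns = colnames(x)[!keep])
}

#' Two-group MANOVA on PC scores
#'
#' Pillai's trace with the group as the single factor, p-value from the
#' standard F approximation. If the within-group covariance is singular, the
#' p-value falls back to a label-permutation test of the same statistic
#' (flagged in the output). P-values are floored at 1e-300 before any log
#' transform.
#'
#' @param scores Numeric matrix of per-read scores (usually 2 columns).
#' @param groups Factor or character vector of group labels (2 levels used).
#' @param n_perm Permutations for the fallback test.
#' @param seed Seed for the fallback's label shuffles.
#' @return List with `statistic` (Pillai's trace), `p_value`, `method`
#'   (`"manova_pillai"` or `"permutation"`).
#' @export
manova_test <- function(scores, groups, n_perm = 2000, seed = 42) {
  scores <- as.matrix(scores)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop("manova_test needs exactly two groups")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 rows")
  stat <- pillai_trace(scores, groups)
  res <- tryCatch({
    if (ncol(scores) == 1L) {
      # one response: Pillai's trace reduces to SSB/SST and the F test is
      # the ordinary one-way ANOVA
      an <- stats::anova(stats::lm(scores[, 1L] ~ groups))
      list(statistic = stat, p_value = an[["Pr(>F)"]][1L],
           method = "manova_pillai")
    } else {
      fit <- stats::manova(scores ~ groups)
      st <- summary(fit, test = "Pillai")$stats
      list(statistic = unname(st[1L, "Pillai"]),
           p_value = unname(st[1L, "Pr(>F)"]), method = "manova_pillai")
    }
  }, error = function(e) NULL)
  if (is.null(res) || !is.finite(res$p_value)) {
    res <- list(statistic = stat,
                p_value = permutation_p(scores, groups, stat, n_perm, seed),
                method = "permutation")
  }
  res$p_value <- max(res$p_value, 1e-300)
  res
}

# Pillai's trace computed directly from between/total SSCP matrices;
# independent of summary.manova and reused by the permutation fallback.
pillai_trace <- function(scores, groups) {
  scores <- as.matrix(scores)
  gm <- colMeans(scores)
  centered <- sweep(scores, 2L, gm)
  total <- crossprod(centered)
  within <- matrix(0, ncol(scores), ncol(scores))
  for (lv in levels(groups)) {
    xg <- scores[groups == lv, , drop = FALSE]
    cg <- sweep(xg, 2L, colMeans(xg))
    within <- within + crossprod(cg)
  }
  between <- total - within
  inv_total <- tryCatch(solve(total), error = function(e) {
    # singular total SSCP (e.g. collinear responses): generalized inverse
    # keeps the statistic defined and rank-preserving for permutation use
    MASS::ginv(total)
  })
  sum(diag(between %*% inv_total))
}

permutation_p <- function(scores, groups, observed, n_perm, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(groups)
    if (pillai_trace(scores, perm) >= observed - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Per-position significance profile over a region
#'
#' For every region position with sufficient coverage: assemble the k-mer
#' feature matrix, project to `n_components` principal components, and test
#' group separation by MANOVA. Positions whose -log10 p exceeds `cutoff`
#' (default 3, i.e. p < 1e-3) are flagged. Because k-mer features smear the
#' signal over neighbours, the truly modified base is expected near the
#' middle of a flagged cluster; no single site is auto-called.
#'
#' @param features Feature table from [build_feature_table()].
#' @param region List with `contig`, `start`, `end`.
#' @param k Window width (odd).
#' @param cutoff Flagging threshold on -log10 p.
#' @param min_reads Minimum complete reads per group per site.
#' @param n_components PCs passed to MANOVA.
#' @param use_pca Test PC scores (default) or the raw 4k features.
#' @param seed Seed for any permutation fallback.
#' @return List of class `significance_profile`: `results` (data.frame, one
#'   row per testable position), `scores` (per-position list of PCA output
#'   plus groups), `flagged` (0-based positions above the cutoff), `cutoff`.
#' @export
significance_profile <- function(features, region, k = 3, cutoff = 3,
                                 min_reads = 10, n_components = 2,
                                 use_pca = TRUE, seed = 42) {
  positions <- region$start:(region$end - 1L)
  rows <- list(); scores <- list()
  for (pos in positions) {
    km <- tryCatch(assemble_kmer_matrix(features, pos, k = k,
                                        min_reads = min_reads),
                   error = function(e) NULL)
    if (is.null(km)) next
    test_input <- if (use_pca) {
      pc <- pca_project(km, n_components = n_components)
      scores[[as.character(pos)]] <- list(
        scores = pc$scores, group = km$group, read_id = km$read_id,
        explained_variance_ratio = pc$explained_variance_ratio)
      pc$scores
    } else {
      km$x
    }
    mt <- manova_test(test_input, km$group, seed = seed)
    ref_b <- features$ref_base[match(pos, features$ref_position)]
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, ref_base = ref_b,
      n_native = sum(km$group == "native"),
      n_control = sum(km$group == "control"),
      statistic = mt$statistic, p_value = mt$p_value,
      neg_log10_p = -log10(mt$p_value), method = mt$method)
  }
  if (length(rows) == 0L) {
    stop("no testable positions in ", region$contig, ":[", region$start,
         ", ", region$end, ")")
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results$p_bonferroni <- pmin(1, results$p_value * nrow(results))
  results$flagged <- results$neg_log10_p > cutoff
  structure(list(results = results, scores = scores,
                 flagged = results$position[results$flagged],
                 cutoff = cutoff, k = k),
            class = "significance_profile")
}

#' Write the per-position test table and center-site PC scores
#'
#' @param profile A `significance_profile`.
#' @param path Output TSV path for the per-position table.
#' @param scores_path Optional TSV path for per-read PC scores at `center`.
#' @param center 0-based position whose scores to export (default: the most
#'   significant position).
#' @param rna Display T as U in `ref_base`.
#' @return The per-position data.frame, invisibly.
#' @export
write_test_tsv <- function(profile, path, scores_path = NULL, center = NULL,
                           rna = FALSE) {
  df <- profile$results
  df$position_1based <- df$position + 1L
  if (rna) df$ref_base[df$ref_base == "T"] <- "U"
  out <- df[, c("position_1based", "ref_base", "n_native", "n_control",
                "statistic", "p_value", "neg_log10_p", "p_bonferroni",
                "flagged", "method")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scores_path)) {
    if (is.null(center)) {
      center <- df$position[which.max(df$neg_log10_p)]
    }
    sc <- profile$scores[[as.character(center)]]
    if (!is.null(sc)) {
      sdf <- data.frame(read_id = sc$read_id, group = as.character(sc$group),
                        PC1 = sc$scores[, 1L],
                        PC2 = if (ncol(sc$scores) >= 2L) sc$scores[, 2L]
                              else NA_real_)
      utils::write.table(sdf, scores_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  invisible(out)
}

#' Export the machine-learning-ready k-mer feature matrix for one site
#'
#' The k x 4 feature table (one row per read, with its group label) that
#' downstream classifier training consumes.
#'
#' @param features Feature table from [build_feature_table()].
#' @param center 0-based site.
#' @param path Output TSV path.
#' @param k Window width.
#' @param min_reads Minimum rows per group.
#' @return The exported data.frame, invisibly.
#' @export
write_kmer_matrix_tsv <- function(features, center, path, k = 3,
                                  min_reads = 10) {
  km <- assemble_kmer_matrix(features, center, k = k, min_reads = min_reads)
  df <- data.frame(read_id = km$read_id, group = as.character(km$group),
                   km$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
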