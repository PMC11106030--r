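# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; nothing binary is checked in.

# Write a SAM (and convert to BAM) from a data.frame of alignment rows.
# rows: qname, flag, pos (1-based), cigar, seq; optional tags column of
# pre-formatted tag strings.
write_test_bam <- function(rows, contigs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", unname(contigs)))
  rows <- rows[order(rows$pos), , drop = FALSE]
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    line <- paste(r$qname, r$flag, r$rname, r$pos, 60L, r$cigar, "*", 0L,
                  0L, r$seq, "*", sep = "\t")
    if (!is.null(r$tags) && !is.na(r$tags) && nzchar(r$tags)) {
      line <- paste(line, r$tags, sep = "\t")
    }
    line
  }, character(1))
  writeLines(c(hdr, body), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}

write_test_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  Rsamtools::indexFa(path)
  path
}

# --- Oracle: per-base CIGAR expansion -------------------------------------
# Expands a CIGAR one base at a time into (query index -> reference
# position) alignment columns; deliberately loop-based and independent of
# the package's vectorized walk.
oracle_query_ref_columns <- function(cigar, ref_start) {
  ops <- strsplit(gsub("([0-9]+)([A-Z=])", "\\1,\\2;", cigar), ";")[[1]]
  q <- 0L; r <- ref_start
  qidx <- integer(); ridx <- integer()
  for (tok in ops) {
    parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
    n <- as.integer(parts[1]); op <- parts[2]
    for (i in seq_len(n)) {
      if (op %in% c("M", "=", "X")) {
        qidx <- c(qidx, q); ridx <- c(ridx, r); q <- q + 1L; r <- r + 1L
      } else if (op %in% c("I", "S")) {
        qidx <- c(qidx, q); ridx <- c(ridx, NA_integer_); q <- q + 1L
      } else if (op %in% c("D", "N")) {
        r <- r + 1L
      }
    }
  }
  list(qidx = qidx, ref = ridx, qlen = q)
}

# Random valid CIGAR over match/insertion/deletion with optional soft clips.
random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- character(); prev <- ""
  for (i in seq_len(n_ops)) {
    op <- sample(setdiff(c("M", "I", "D"), prev), 1)
    # never start or end on I/D, never repeat an op
    if (i == 1L || i == n_ops) op <- "M"
    if (op == prev) op <- "M"
    ops <- c(ops, op); prev <- op
  }
  lens <- sample(1:8, length(ops), replace = TRUE)
  body <- paste0(lens, ops, collapse = "")
  pre <- if (stats::runif(1) < 0.4) paste0(sample(1:5, 1), "S") else ""
  post <- if (stats::runif(1) < 0.4) paste0(sample(1:5, 1), "S") else ""
  paste0(pre, body, post)
}

# --- Oracle: brute-force pileup from CIGAR + sequence ---------------------
# Counts aligned read bases per reference position by walking each read's
# CIGAR and sequence explicitly.
oracle_pileup_counts <- function(rows, start, end) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = end - start, ncol = 4,
                   dimnames = list(NULL, bases))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (bitwAnd(r$flag, 256L) != 0L || bitwAnd(r$flag, 2048L) != 0L) next
    cols <- oracle_query_ref_columns(r$cigar, r$pos - 1L)
    seq_chars <- strsplit(r$seq, "")[[1]]
    for (j in seq_along(cols$qidx)) {
      rp <- cols$ref[j]
      if (!is.na(rp) && rp >= start && rp < end) {
        b <- seq_chars[cols$qidx[j] + 1L]
        if (b %in% bases) counts[rp - start + 1L, b] <-
            counts[rp - start + 1L, b] + 1L
      }
    }
  }
  counts
}

# --- Oracle: PCA via eigendecomposition of the covariance -----------------
oracle_pca_scores <- function(x, n_components = 2) {
  sds <- apply(x, 2, stats::sd)
  xs <- scale(x[, sds > 0, drop = FALSE])
  ev <- eigen(stats::cov(xs), symmetric = TRUE)
  scores <- xs %*% ev$vectors
  list(scores = scores[, seq_len(n_components), drop = FALSE],
       evr = ev$values / sum(ev$values))
}

# --- Oracle: label-permutation p for a two-group multivariate shift -------
oracle_permutation_p <- function(scores, groups, n_perm, seed) {
  stat_fun <- function(g) {
    # squared Euclidean distance between group centroids (rank-preserving
    # alternative statistic, independent of the package's Pillai code)
    ms <- rowsum(scores, g) / as.vector(table(g))
    sum((ms[1, ] - ms[2, ])^2)
  }
  obs <- stat_fun(groups)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (stat_fun(sample(groups)) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Small simulated fixture + pipeline run used by several files.
quick_pipeline_run <- function(seed = 3, n_reads = 14, effect_delta = 1.5,
                               flank = 4, min_reads = 5, dir = NULL,
                               render = FALSE, ...) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulation_config(seed = seed, n_reads = n_reads,
                           effect_delta = effect_delta, ...)
  run_simulate(sim, file.path(dir, "fix"))
  cfg <- fixture_run_config(file.path(dir, "fix"), sim,
                            file.path(dir, "out"), flank = flank,
                            min_reads = min_reads)
  res <- run_current_events_magnifier(cfg, render_figures = render)
  list(sim = sim, cfg = cfg, res = res, dir = dir)
}
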