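#' Summary features of one current event
#'
#' Mean, median, standard deviation and dwell time of the raw samples
#' attributed to one nucleotide. The standard deviation is the population
#' form (divisor n), so single-sample events give 0 rather than NaN.
#'
#' @param normalized_samples Numeric vector the event indexes into.
#' @param start 0-based start index of the event.
#' @param length Number of samples (>= 1).
#' @return Named numeric vector `c(mean, median, std, dwell)`.
#' @export
event_features <- function(normalized_samples, start, length) {
  if (length < 1L) stop("empty event")
  if (start < 0L || start + length > base::length(normalized_samples)) {
    stop("event [", start, ", ", start + length,
         ") outside the sample vector")
  }
  x <- normalized_samples[(start + 1L):(start + length)]
  m <- mean(x)
  c(mean = m, median = stats::median(x),
    std = sqrt(sum((x - m)^2) / length), dwell = length)
}

#' Per-read, per-position feature table for two sample groups
#'
#' For each read: the mapped section (the raw-sample span covered by its
#' projected events) is normalized with [normalize_read()], then the four
#' event features are computed at every reference position the read covers
#' inside the region. Positions a read does not cover (e.g. deletions) are
#' simply absent, not zero-filled.
#'
#' @param native,control Lists with elements `reads` (named list of
#'   [raw_read()]) and `events` (named list of [projected_event_table()]).
#' @param region List with `contig`, `start`, `end` (0-based half-open).
#' @param clip Normalization clipping threshold.
#' @param ref_bases Optional character vector naming the reference base per
#'   region position (length `end - start`).
#' @param max_reads_per_group Optional cap on reads per group (first reads by
#'   ID order kept); default unlimited.
#' @return data.frame with columns read_id, contig, ref_position (0-based),
#'   ref_base, group, mean, median, std, dwell.
#' @export
build_feature_table <- function(native, control, region, clip = 5,
                                ref_bases = NULL,
                                max_reads_per_group = Inf) {
  groups <- list(native = native, control = control)
  out <- list()
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (is.null(grp)) next
    ids <- intersect(names(grp$events), names(grp$reads))
    ids <- sort(ids)
    if (length(ids) > max_reads_per_group) {
      ids <- ids[seq_len(max_reads_per_group)]
    }
    n_rec <- 0L
    for (id in ids) {
      rec <- read_position_features(grp$reads[[id]], grp$events[[id]],
                                    region, clip)
      if (!is.null(rec) && nrow(rec) > 0L) {
        rec$group <- g
        out[[length(out) + 1L]] <- rec
        n_rec <- n_rec + nrow(rec)
      }
    }
    if (n_rec == 0L) {
      warning("no events inside ", region$contig, ":[", region$start, ", ",
              region$end, ") for the ", g, " group")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(), contig = character(),
                      ref_position = integer(), ref_base = character(),
                      group = character(), mean = numeric(),
                      median = numeric(), std = numeric(),
                      dwell = integer()))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(ref_bases)) {
    df$ref_base <- ref_bases[df$ref_position - region$start + 1L]
  }
  df[, c("read_id", "contig", "ref_position", "ref_base", "group",
         "mean", "median", "std", "dwell")]
}

# One read's features at every region position it covers.
read_position_features <- function(read, proj, region, clip) {
  ev <- proj$events
  if (!is.null(proj$contig) && !is.na(proj$contig) &&
      proj$contig != region$contig) {
    return(NULL)
  }
  inside <- ev$ref_position >= region$start & ev$ref_position < region$end
  ev <- ev[inside, , drop = FALSE]
  if (nrow(ev) == 0L) return(NULL)
  span <- c(min(proj$events$start),
            max(proj$events$start + proj$events$length))
  norm <- normalize_read(read, mapped_span = span, clip = clip)
  feats <- t(vapply(seq_len(nrow(ev)), function(i) {
    event_features(norm$samples, ev$start[i] - span[1L], ev$length[i])
  }, numeric(4)))
  data.frame(read_id = read$read_id, contig = region$contig,
             ref_position = ev$ref_position, ref_base = NA_character_,
             mean = feats[, "mean"], median = feats[, "median"],
             std = feats[, "std"], dwell = as.integer(feats[, "dwell"]))
}

#' Write the feature table as TSV
#'
#' Columns: read_id, contig, position_1based, ref_base, group, mean, median,
#' std, dwell. RNA display mode writes U for reference-base T.
#'
#' @param features data.frame from [build_feature_table()].
#' @param path Output path.
#' @param rna Display T as U.
#' @return The exported data.frame, invisibly.
#' @export
write_feature_tsv <- function(features, path, rna = FALSE) {
  df <- features
  df$position_1based <- df$ref_position + 1L
  if (rna) df$ref_base[df$ref_base == "T"] <- "U"
  df <- df[, c("read_id", "contig", "position_1based", "ref_base", "group",
               "mean", "median", "std", "dwell")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
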