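#' Per-position nucleotide composition over a target region
#'
#' The "alignment magnifier": counts A/C/G/T from aligned read bases at every
#' reference position of `[start, end)`. Deletions and reference skips
#' contribute to neither the counts nor the coverage; mapping and base
#' quality filters default to off. Coverage at a position is the sum of the
#' four base counts.
#'
#' @param bam Path to a BAM (or text SAM) file.
#' @param reference Path to the reference FASTA (indexed on demand).
#' @param contig Reference sequence name.
#' @param start,end 0-based half-open region.
#' @param strand `"+"`, `"-"` or `"both"`: restrict to reads on one strand
#'   or pool both.
#' @param min_mapq,min_baseq Quality filters (default 0 = off).
#' @return A `pileup_profile`: list with `contig`, `positions` (0-based),
#'   `ref_base`, `counts` (matrix positions x ACGT), `coverage`.
#' @export
pileup_region <- function(bam, reference, contig, start, end,
                          strand = c("both", "+", "-"),
                          min_mapq = 0, min_baseq = 0) {
  strand <- match.arg(strand)
  if (end <= start) stop("empty region: [", start, ", ", end, ")")
  bam_path <- as_bam(bam)
  fa <- Rsamtools::FaFile(reference)
  if (!file.exists(paste0(reference, ".fai"))) Rsamtools::indexFa(reference)
  fa_info <- Rsamtools::seqinfo(fa)
  if (!contig %in% GenomeInfoDb::seqnames(fa_info)) {
    stop("contig '", contig, "' absent from FASTA ", reference)
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!contig %in% names(hdr)) {
    stop("contig '", contig, "' absent from BAM ", bam)
  }
  clen <- GenomeInfoDb::seqlengths(fa_info)[[contig]]
  if (start < 0 || end > clen) {
    stop("region [", start, ", ", end, ") outside contig bounds (length ",
         clen, ")")
  }

  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start + 1L, end))
  ref_seq <- as.character(Rsamtools::getSeq(fa, gr)[[1]])
  ref_base <- strsplit(ref_seq, "")[[1]]

  flags <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isUnmappedQuery = FALSE,
    isMinusStrand = switch(strand, both = NA, `+` = FALSE, `-` = TRUE))
  sbp <- Rsamtools::ScanBamParam(which = gr, flag = flags)
  pp <- Rsamtools::PileupParam(
    max_depth = 1e6L, min_base_quality = as.integer(min_baseq),
    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE, include_deletions = FALSE,
    include_insertions = FALSE)
  res <- Rsamtools::pileup(bam_path, scanBamParam = sbp, pileupParam = pp)

  positions <- start:(end - 1L)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = length(positions), ncol = 4L,
                   dimnames = list(NULL, bases))
  if (nrow(res) > 0L) {
    res <- res[res$nucleotide %in% bases, , drop = FALSE]
    i <- match(res$pos - 1L, positions)
    j <- match(as.character(res$nucleotide), bases)
    ok <- !is.na(i)
    counts[cbind(i[ok], j[ok])] <- res$count[ok]
  }
  structure(list(contig = contig, positions = positions,
                 ref_base = ref_base, counts = counts,
                 coverage = as.integer(rowSums(counts))),
            class = "pileup_profile")
}

#' Per-position mismatch fraction of a pileup profile
#'
#' `1 - count[ref_base] / coverage` per position; positions with zero
#' coverage yield `NA` rather than 0 so that uncovered sites are not mistaken
#' for perfect matches.
#'
#' @param profile A `pileup_profile` from [pileup_region()].
#' @return Numeric vector in `[0, 1]` (or `NA`), one per position.
#' @export
mismatch_fractions <- function(profile) {
  stopifnot(inherits(profile, "pileup_profile"))
  n <- length(profile$positions)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cov <- profile$coverage[i]
    if (cov > 0L) {
      rb <- profile$ref_base[i]
      ref_count <- if (rb %in% colnames(profile$counts)) {
        profile$counts[i, rb]
      } else 0L
      out[i] <- 1 - ref_count / cov
    }
  }
  out
}

#' Read IDs of primary alignments overlapping a region
#'
#' Mirrors the usual "extract reads for a locus" helper: returns exactly the
#' primary-alignment read IDs overlapping `[start, end)`; secondary and
#' supplementary records are excluded.
#'
#' @inheritParams pileup_region
#' @return Character vector of unique read IDs (possibly empty).
#' @export
extract_region_read_ids <- function(bam, contig, start, end) {
  if (end <= start) stop("empty region: [", start, ", ", end, ")")
  bam_path <- as_bam(bam)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!contig %in% names(hdr)) {
    stop("contig '", contig, "' absent from BAM ", bam)
  }
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(what = "qname", which = gr, flag = flags)
  sort(unique(Rsamtools::scanBam(bam_path, param = p)[[1]]$qname))
}

#' Primary alignment records for a region, as projection-ready lists
#'
#' @inheritParams extract_region_read_ids
#' @return Named list (by read ID) of lists with `contig`, `ref_start`
#'   (0-based), `cigar`, `strand`.
#' @export
read_alignments <- function(bam, contig, start, end) {
  bam_path <- as_bam(bam)
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "cigar"),
                               which = gr, flag = flags)
  res <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  out <- list()
  for (i in seq_along(res$qname)) {
    out[[res$qname[i]]] <- list(
      contig = contig, ref_start = res$pos[i] - 1L, cigar = res$cigar[i],
      strand = if (bitwAnd(res$flag[i], 16L) != 0L) "-" else "+")
  }
  out
}

#' Export a pileup profile as a TSV table
#'
#' Columns: contig, pos_1based, ref_base, A, C, G, T, coverage,
#' mismatch_fraction. In RNA display mode the reference base T is written as
#' U (counts remain keyed by T internally).
#'
#' @param profile A `pileup_profile`.
#' @param path Output path.
#' @param rna Display T as U.
#' @return The exported data.frame, invisibly.
#' @export
write_pileup_tsv <- function(profile, path, rna = FALSE) {
  rb <- profile$ref_base
  if (rna) rb[rb == "T"] <- "U"
  df <- data.frame(contig = profile$contig,
                   pos_1based = profile$positions + 1L,
                   ref_base = rb,
                   profile$counts,
                   coverage = profile$coverage,
                   mismatch_fraction = mismatch_fractions(profile),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
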