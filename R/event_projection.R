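#' Normalize a read's signal by median shift and MAD scale
#'
#' Over the mapped section of the read, computes `shift` = median and
#' `scale` = median absolute deviation (plain MAD, no consistency factor),
#' then returns `clamp((x - shift) / scale, -clip, +clip)`. Clipping caps the
#' influence of current noise spikes; the default threshold of 5 normalized
#' units matches the usual nanopore practice.
#'
#' @param read A [raw_read()].
#' @param mapped_span Integer pair `c(start, end)`, 0-based half-open raw
#'   sample interval covered by the alignment. Defaults to the whole read.
#' @param clip Positive clipping threshold in normalized units.
#' @return List with `samples` (normalized values over the span), `span`
#'   (the interval used), and `params` (list `shift`, `scale`, `clip`).
#' @export
normalize_read <- function(read, mapped_span = NULL, clip = 5) {
  stopifnot(inherits(read, "raw_read"), clip > 0)
  n <- length(read$samples)
  if (is.null(mapped_span)) mapped_span <- c(0L, n)
  s0 <- mapped_span[1L]; s1 <- mapped_span[2L]
  if (s1 <= s0 || s0 < 0L || s1 > n) {
    stop("read '", read$read_id, "': mapped_span [", s0, ", ", s1,
         ") is empty or outside the read (", n, " samples)")
  }
  x <- read$samples[(s0 + 1L):s1]
  shift <- stats::median(x)
  scale <- stats::median(abs(x - shift))
  if (scale == 0) {
    stop("degenerate signal for read '", read$read_id,
         "': MAD of the mapped section is 0")
  }
  z <- (x - shift) / scale
  list(samples = pmin(pmax(z, -clip), clip),
       span = c(s0, s1),
       params = list(shift = shift, scale = scale, clip = clip))
}

#' Resolve and apply a base shift to a basecall-space event table
#'
#' Preprocessors disagree about which base of the pore's k-mer an event is
#' attributed to: for the RNA002 5-mer CUAAG, f5c assigns the event to the
#' first base (C) where Tombo assigns it to the second (U). Shifting f5c
#' positions by +1 reconciles the two conventions. `shift = "auto"` looks the
#' offset up in a configurable table keyed by (dialect, molecule, pore);
#' unknown combinations are a configuration error rather than a guess.
#'
#' @param table A `BASECALL`-space [event_table()].
#' @param shift Integer offset, or `"auto"`.
#' @param dialect,molecule,pore Context for `"auto"` resolution.
#' @param n_positions Number of basecalled positions in the read; events
#'   shifted outside `[0, n_positions)` are dropped. `NULL` disables the
#'   bound check (only valid with non-positive shifts of known safety).
#' @param shift_table Override table as returned by [read_base_shift_table()].
#' @return The shifted [event_table()].
#' @export
apply_base_shift <- function(table, shift = "auto", dialect = NULL,
                             molecule = NULL, pore = NULL,
                             n_positions = NULL, shift_table = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (table$coordinate_space != "BASECALL") {
    stop("apply_base_shift requires a BASECALL-space event table")
  }
  if (identical(shift, "auto")) {
    shift <- resolve_base_shift(dialect, molecule, pore, shift_table)
  }
  shift <- as.integer(shift)
  if (shift == 0L) return(table)
  ev <- table$events
  ev$position <- ev$position + shift
  keep <- ev$position >= 0L
  if (!is.null(n_positions)) keep <- keep & ev$position < n_positions
  event_table(table$read_id, "BASECALL", ev[keep, , drop = FALSE],
              contig = table$contig)
}

#' Look up a base shift for a (dialect, molecule, pore) combination
#'
#' @param dialect,molecule,pore Keys into the shift table.
#' @param shift_table Optional table from [read_base_shift_table()]; defaults
#'   to the packaged configuration.
#' @return Integer shift.
#' @export
resolve_base_shift <- function(dialect, molecule, pore, shift_table = NULL) {
  if (is.null(dialect) || is.null(molecule) || is.null(pore)) {
    stop("configuration error: shift 'auto' needs dialect, molecule and pore")
  }
  if (is.null(shift_table)) shift_table <- read_base_shift_table()
  hit <- shift_table$dialect == dialect &
    shift_table$molecule == molecule & shift_table$pore == pore
  if (sum(hit) != 1L) {
    stop("configuration error: no base shift configured for (", dialect,
         ", ", molecule, ", ", pore, "); pass an explicit integer shift ",
         "or extend the shift table")
  }
  as.integer(shift_table$shift[hit])
}

#' Read a base-shift configuration table
#'
#' Tab-separated with columns `dialect`, `molecule`, `pore`, `shift`. The
#' packaged default covers the f5c dialects on R9/R10 chemistries; move-table
#' and Tombo-style indices need no shift.
#'
#' @param path Path to a shift table; defaults to the packaged file.
#' @return data.frame with the four columns.
#' @export
read_base_shift_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "base_shift_table.tsv",
                        package = "squigglescope", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dialect", "molecule", "pore", "shift")
  if (!all(need %in% names(tab))) {
    stop("shift table '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  tab
}

#' Reverse a direct-RNA read's signal and event indices
#'
#' Direct-RNA reads are sequenced and stored 3'->5', while the basecalled
#' sequence is written 5'->3'. Before projecting onto the reference, the raw
#' samples and the event intervals must be flipped so that signal and
#' sequence share an orientation: sample order is reversed and each event's
#' start becomes `n_samples - start - length`. The operation is an
#' involution.
#'
#' @param read An RNA [raw_read()].
#' @param table The read's `BASECALL`-space [event_table()].
#' @return List with reversed `read` and `table`.
#' @export
reverse_rna_events <- function(read, table) {
  stopifnot(inherits(read, "raw_read"), inherits(table, "event_table"))
  if (read$molecule != "RNA") {
    stop("reverse_rna_events applies to RNA reads only (read '",
         read$read_id, "' is DNA)")
  }
  if (table$coordinate_space != "BASECALL") {
    stop("reverse_rna_events requires a BASECALL-space event table")
  }
  n <- length(read$samples)
  rev_read <- raw_read(read$read_id, rev(read$samples),
                       sampling_rate = read$sampling_rate, molecule = "RNA")
  ev <- table$events
  ev$start <- n - ev$start - ev$length
  ev <- ev[order(ev$position, ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  list(read = rev_read,
       table = event_table(table$read_id, "BASECALL", ev,
                           contig = table$contig))
}

# Map 0-based query indices (BAM orientation, soft clips included) to
# 0-based reference positions via the CIGAR; NA for soft clips/insertions.
# Hard clips consume nothing. Vectorized over CIGAR operations.
query_to_ref_map <- function(cigar, ref_start) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qmap <- vector("list", length(ops))
  ref <- ref_start
  for (i in seq_along(ops)) {
    op <- ops[i]; L <- lens[i]
    if (op %in% c("M", "=", "X")) {
      qmap[[i]] <- ref + seq_len(L) - 1L
      ref <- ref + L
    } else if (op %in% c("I", "S")) {
      qmap[[i]] <- rep(NA_integer_, L)
    } else if (op %in% c("D", "N")) {
      ref <- ref + L
    } else if (op != "H") {
      stop("unsupported CIGAR operation '", op, "'")
    }
  }
  unlist(qmap)
}

#' Project basecall-space events onto reference coordinates
#'
#' Walks the alignment CIGAR: aligned columns map basecall positions to
#' reference positions, events on inserted or soft-clipped bases are dropped,
#' and deleted reference positions simply receive no event. For
#' reverse-strand alignments the BAM stores the reverse complement, so
#' basecall position `i` (read orientation, 5'->3') corresponds to query
#' index `query_length - 1 - i`; event order in the raw signal is preserved.
#'
#' @param table A `BASECALL`-space [event_table()].
#' @param alignment List describing the read's primary alignment: `contig`,
#'   `ref_start` (0-based), `cigar`, `strand` (`"+"`/`"-"`).
#' @return A [projected_event_table()].
#' @export
project_to_reference <- function(table, alignment) {
  stopifnot(inherits(table, "event_table"))
  if (table$coordinate_space != "BASECALL") {
    stop("project_to_reference requires a BASECALL-space event table")
  }
  qmap <- query_to_ref_map(alignment$cigar, alignment$ref_start)
  qlen <- length(qmap)
  pos <- table$events$position
  if (any(pos >= qlen)) {
    stop("inconsistency for read '", table$read_id, "': event position ",
         max(pos), " beyond query length ", qlen)
  }
  qidx <- if (identical(alignment$strand, "-")) qlen - 1L - pos else pos
  ref_pos <- qmap[qidx + 1L]
  keep <- !is.na(ref_pos)
  projected_event_table(
    table$read_id, alignment$contig, alignment$strand,
    data.frame(ref_position = ref_pos[keep],
               start = table$events$start[keep],
               length = table$events$length[keep]))
}

#' Treat a reference-space event table as projected
#'
#' Eventalign- and Tombo-style tables already carry reference positions; this
#' wraps them in the projected representation used by feature extraction.
#'
#' @param table A `REFERENCE`-space [event_table()].
#' @param contig,strand Alignment identity (contig defaults to the table's).
#' @return A [projected_event_table()].
#' @export
as_projected <- function(table, contig = NULL, strand = "+") {
  stopifnot(inherits(table, "event_table"))
  if (table$coordinate_space != "REFERENCE") {
    stop("as_projected requires a REFERENCE-space event table")
  }
  if (is.null(contig)) contig <- table$contig
  ev <- table$events
  projected_event_table(table$read_id, contig, strand,
                        data.frame(ref_position = ev$position,
                                   start = ev$start, length = ev$length))
}
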