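#' Raw nanopore read
#'
#' Container for one read's raw current trace plus the metadata the pipeline
#' needs downstream. Samples are stored in picoamperes (or any already-scaled
#' unit); conversion from ADC units happens in [read_slow5()].
#'
#' @param read_id Character scalar, unique within a sample.
#' @param samples Numeric vector of current measurements; must be non-empty.
#' @param sampling_rate Sampling frequency in Hz, or `NA` when unknown.
#' @param molecule `"DNA"` or `"RNA"`. Direct-RNA reads are sequenced (and
#'   stored) 3'->5'; see [reverse_rna_events()].
#' @return An object of class `raw_read`.
#' @export
raw_read <- function(read_id, samples, sampling_rate = NA_real_,
                     molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  stopifnot(is.character(read_id), length(read_id) == 1L, nzchar(read_id))
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples)) {
    stop("raw_read '", read_id, "': samples must be non-empty and free of NA")
  }
  if (!is.na(sampling_rate) && sampling_rate <= 0) {
    stop("raw_read '", read_id, "': sampling_rate must be > 0")
  }
  structure(
    list(read_id = read_id, samples = samples,
         sampling_rate = as.numeric(sampling_rate), molecule = molecule),
    class = "raw_read"
  )
}

#' @export
print.raw_read <- function(x, ...) {
  cat(sprintf("<raw_read %s: %d samples, %s, %s Hz>\n", x$read_id,
              length(x$samples), x$molecule,
              ifelse(is.na(x$sampling_rate), "?", format(x$sampling_rate))))
  invisible(x)
}

#' Per-read event table
#'
#' Maps sequence positions to contiguous raw-sample intervals ("current
#' events"). Positions index either the basecalled read (`BASECALL`, as from
#' f5c resquiggle or a basecaller move table) or the reference (`REFERENCE`,
#' as from eventalign or a Tombo-style export). Raw-sample intervals are
#' 0-based half-open `[start, start + length)`.
#'
#' @param read_id Character scalar.
#' @param coordinate_space `"BASECALL"` or `"REFERENCE"`.
#' @param events data.frame with integer columns `position`, `start`,
#'   `length`; rows sorted by `position` (non-decreasing), raw-sample
#'   intervals non-overlapping, `length >= 1`. For DNA (and RNA after
#'   [reverse_rna_events()]) starts increase with position; for direct-RNA
#'   tables indexing the stored 3'->5' signal they decrease.
#' @param contig Optional contig name (reference-space dialects carry one).
#' @return An object of class `event_table`.
#' @export
event_table <- function(read_id, coordinate_space = c("BASECALL", "REFERENCE"),
                        events, contig = NA_character_) {
  coordinate_space <- match.arg(coordinate_space)
  stopifnot(is.data.frame(events),
            all(c("position", "start", "length") %in% names(events)))
  events <- data.frame(position = as.integer(events$position),
                       start = as.integer(events$start),
                       length = as.integer(events$length))
  validate_events(events, read_id)
  structure(
    list(read_id = read_id, coordinate_space = coordinate_space,
         events = events, contig = contig),
    class = "event_table"
  )
}

validate_events <- function(events, read_id) {
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$length < 1L)) {
    stop("event_table '", read_id, "': every event length must be >= 1")
  }
  if (any(events$start < 0L) || any(events$position < 0L)) {
    stop("event_table '", read_id, "': negative start or position")
  }
  if (is.unsorted(events$position)) {
    stop("event_table '", read_id, "': positions must be non-decreasing")
  }
  if (nrow(events) > 1L) {
    ord <- order(events$start)
    starts <- events$start[ord]
    ends <- starts + events$length[ord]
    if (any(starts[-1L] < ends[-length(ends)])) {
      stop("event_table '", read_id, "': overlapping raw-sample intervals")
    }
  }
  invisible(events)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table %s: %d events, %s space>\n", x$read_id,
              nrow(x$events), x$coordinate_space))
  invisible(x)
}

#' Reference-projected event table
#'
#' Like [event_table()] but positions are 0-based reference coordinates on a
#' named contig/strand, produced by [project_to_reference()]. At most one
#' event per reference position.
#'
#' @param read_id,contig,strand Read and alignment identity.
#' @param events data.frame with columns `ref_position`, `start`, `length`.
#' @return An object of class `projected_event_table`.
#' @export
projected_event_table <- function(read_id, contig, strand, events) {
  stopifnot(all(c("ref_position", "start", "length") %in% names(events)))
  events <- data.frame(ref_position = as.integer(events$ref_position),
                       start = as.integer(events$start),
                       length = as.integer(events$length))
  if (anyDuplicated(events$ref_position)) {
    stop("projected_event_table '", read_id,
         "': more than one event for a reference position")
  }
  structure(list(read_id = read_id, contig = contig, strand = strand,
                 events = events),
            class = "projected_event_table")
}
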