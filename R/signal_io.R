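#' Read an ASCII SLOW5 file
#'
#' Parses the tab-separated ASCII SLOW5 dialect: `@key\tvalue` metadata
#' lines, `#`-prefixed header lines (the last of which, starting with
#' `#read_id`, names the record columns), then one record per line. The raw
#' ADC signal (comma-separated integers) is converted to picoamperes as
#' `(raw + offset) * range / digitisation`.
#'
#' @param path Path to an ASCII SLOW5 file.
#' @param molecule `"DNA"` or `"RNA"`; SLOW5 does not record chemistry, so
#'   the caller states it.
#' @return Named list of [raw_read()] objects (names = read ids).
#' @export
read_slow5 <- function(path, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("SLOW5 file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("SLOW5 parse error at line 1: empty file")

  is_meta <- startsWith(lines, "@")
  is_hdr <- startsWith(lines, "#")
  hdr_idx <- which(is_hdr)
  if (length(hdr_idx) == 0L) {
    stop("SLOW5 parse error at line 1: no '#' header line found")
  }
  col_line <- max(hdr_idx)
  cols <- strsplit(sub("^#", "", lines[col_line]), "\t", fixed = TRUE)[[1]]
  required <- c("read_id", "digitisation", "offset", "range",
                "sampling_rate", "len_raw_signal", "raw_signal")
  missing <- setdiff(required, cols)
  if (length(missing) > 0L) {
    stop("SLOW5 parse error at line ", col_line,
         ": missing column(s) ", paste(missing, collapse = ", "))
  }

  data_idx <- setdiff(seq_along(lines), which(is_meta | is_hdr))
  data_idx <- data_idx[nzchar(trimws(lines[data_idx]))]
  reads <- vector("list", length(data_idx))
  ids <- character(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(cols)) {
      stop("SLOW5 parse error at line ", i, ": expected ", length(cols),
           " fields, found ", length(fields))
    }
    names(fields) <- cols
    digitisation <- as.numeric(fields[["digitisation"]])
    offset <- as.numeric(fields[["offset"]])
    rng <- as.numeric(fields[["range"]])
    rate <- as.numeric(fields[["sampling_rate"]])
    n_sig <- as.integer(fields[["len_raw_signal"]])
    if (anyNA(c(digitisation, offset, rng, rate)) || digitisation <= 0) {
      stop("SLOW5 parse error at line ", i, ": bad numeric field")
    }
    sig_str <- fields[["raw_signal"]]
    if (!nzchar(sig_str)) {
      stop("SLOW5 parse error at line ", i, ": empty raw signal")
    }
    raw <- as.numeric(strsplit(sig_str, ",", fixed = TRUE)[[1]])
    if (anyNA(raw)) {
      stop("SLOW5 parse error at line ", i, ": non-numeric raw signal")
    }
    if (!is.na(n_sig) && n_sig != length(raw)) {
      stop("SLOW5 parse error at line ", i, ": len_raw_signal=", n_sig,
           " but ", length(raw), " samples present")
    }
    pa <- (raw + offset) * rng / digitisation
    ids[k] <- fields[["read_id"]]
    reads[[k]] <- raw_read(fields[["read_id"]], pa,
                           sampling_rate = rate, molecule = molecule)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate read_id in SLOW5 file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(reads) <- ids
  reads
}

#' Write an ASCII SLOW5 file
#'
#' Inverse of [read_slow5()] for identity-scaled records: samples are written
#' as the raw signal with `digitisation = range` and `offset = 0` unless a
#' `scaling` list overrides them, in which case raw values are recovered as
#' `samples * digitisation / range - offset` and rounded to integers.
#'
#' @param reads List of [raw_read()] objects.
#' @param path Output path.
#' @param scaling Optional list with `digitisation`, `range`, `offset`.
#' @return `path`, invisibly.
#' @export
write_slow5 <- function(reads, path, scaling = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#slow5_version\t0.2.0", "#num_read_groups\t1"), con)
  writeLines(paste("#read_id", "read_group", "digitisation", "offset",
                   "range", "sampling_rate", "len_raw_signal", "raw_signal",
                   sep = "\t"), con)
  for (rd in reads) {
    if (is.null(scaling)) {
      dig <- 1; rng <- 1; off <- 0
      raw <- rd$samples
    } else {
      dig <- scaling$digitisation; rng <- scaling$range; off <- scaling$offset
      raw <- round(rd$samples * dig / rng - off)
    }
    writeLines(paste(rd$read_id, "0",
                     format(dig, scientific = FALSE),
                     format(off, scientific = FALSE),
                     format(rng, scientific = FALSE),
                     ifelse(is.na(rd$sampling_rate), "0",
                            format(rd$sampling_rate, scientific = FALSE)),
                     length(rd$samples),
                     paste(format(raw, scientific = FALSE, trim = TRUE),
                           collapse = ","),
                     sep = "\t"), con)
  }
  invisible(path)
}

# Merge adjacent rows sharing a position: start = min, length = sum.
# Idempotent; used by every dialect reader. Preserves position order.
merge_adjacent_events <- function(events) {
  if (nrow(events) <= 1L) return(events)
  grp <- cumsum(c(TRUE, events$position[-1L] != events$position[-nrow(events)]))
  if (max(grp) == nrow(events)) return(events)
  merged <- data.frame(
    position = as.integer(tapply(events$position, grp, `[`, 1L)),
    start = as.integer(tapply(events$start, grp, min)),
    length = as.integer(tapply(events$length, grp, sum))
  )
  rownames(merged) <- NULL
  merged
}

#' Read per-read event indices in one of four dialects
#'
#' Presents f5c-resquiggle-style TSV, eventalign-style TSV, Tombo-style TSV
#' exports, and basecaller move tables (BAM auxiliary tags) as one uniform
#' collection of [event_table()] objects. f5c resquiggle and move tables
#' index the basecalled read (`BASECALL` space); eventalign and Tombo index
#' the reference (`REFERENCE` space). Adjacent rows for the same position are
#' merged into a single event (start = min start, length = summed length).
#'
#' Expected columns:
#' \describe{
#'   \item{f5c_resquiggle}{`read_id`, `basecall_position`, `start`, `length`}
#'   \item{eventalign}{`contig`, `position`, `read_name` (or `read_index`),
#'     `start_idx`, `end_idx` (half-open raw-sample interval)}
#'   \item{tombo_tsv}{`read_id`, `ref_position`, `start`, `length`}
#'   \item{move_table}{taken from `bam`: per-read `mv:B:c` tag whose first
#'     element is the stride, followed by the move flags; optional `ts:i` tag
#'     giving the number of leading raw samples trimmed before the first
#'     stride block}
#' }
#'
#' @param path Path to the dialect TSV (ignored for `move_table`).
#' @param dialect One of `"f5c_resquiggle"`, `"eventalign"`, `"move_table"`,
#'   `"tombo_tsv"`.
#' @param bam For `move_table`: path to the BAM/SAM carrying `mv`/`ts` tags.
#' @return Named list of [event_table()] objects.
#' @export
read_event_dialect <- function(path = NULL,
                               dialect = c("f5c_resquiggle", "eventalign",
                                           "move_table", "tombo_tsv"),
                               bam = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "move_table") {
    if (is.null(bam)) stop("move_table dialect requires a BAM/SAM file")
    return(read_move_table_bam(bam))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  spec <- switch(dialect,
    f5c_resquiggle = list(cols = c("read_id", "basecall_position", "start",
                                   "length"),
                          space = "BASECALL"),
    eventalign = list(cols = c("contig", "position", "start_idx", "end_idx"),
                      space = "REFERENCE"),
    tombo_tsv = list(cols = c("read_id", "ref_position", "start", "length"),
                     space = "REFERENCE"))
  missing <- setdiff(spec$cols, names(tab))
  if (dialect == "eventalign") {
    if (!any(c("read_name", "read_index") %in% names(tab))) {
      missing <- c(missing, "read_name/read_index")
    }
  }
  if (length(missing) > 0L) {
    stop("schema error in ", dialect, " file '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }

  std <- switch(dialect,
    f5c_resquiggle = data.frame(read_id = tab$read_id,
                                position = tab$basecall_position,
                                start = tab$start, length = tab$length,
                                contig = NA_character_),
    eventalign = data.frame(
      read_id = if ("read_name" %in% names(tab)) tab$read_name
                else as.character(tab$read_index),
      position = tab$position, start = tab$start_idx,
      length = tab$end_idx - tab$start_idx, contig = tab$contig),
    tombo_tsv = data.frame(read_id = tab$read_id,
                           position = tab$ref_position,
                           start = tab$start, length = tab$length,
                           contig = NA_character_))

  out <- lapply(split(std, std$read_id), function(df) {
    df <- df[order(df$position, df$start), , drop = FALSE]
    ev <- merge_adjacent_events(df[, c("position", "start", "length")])
    tryCatch(
      event_table(df$read_id[1L], spec$space, ev, contig = df$contig[1L]),
      error = function(e) stop(dialect, " dialect error: ",
                               conditionMessage(e), call. = FALSE))
  })
  out[order(names(out))]
}

# Decode mv/ts tags: stride is mv[1]; each subsequent element is a move flag
# per stride block. Flag 1 opens a new basecall position's event; flag 0
# extends the current one. The final event runs to the end of the move array.
read_move_table_bam <- function(bam) {
  bam_path <- as_bam(bam)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag"),
                               tag = c("mv", "ts"))
  res <- Rsamtools::scanBam(bam_path, param = p)[[1]]
  keep <- bitwAnd(res$flag, 256L) == 0L & bitwAnd(res$flag, 2048L) == 0L
  out <- list()
  for (i in which(keep)) {
    mv <- res$tag$mv[[i]]
    if (is.null(mv) || length(mv) < 2L) {
      stop("schema error: read '", res$qname[i],
           "' lacks a usable mv move-table tag")
    }
    ts <- res$tag$ts[[i]]
    ts <- if (is.null(ts) || is.na(ts)) 0L else as.integer(ts)
    stride <- as.integer(mv[1L])
    moves <- as.integer(mv[-1L])
    if (stride < 1L || !all(moves %in% c(0L, 1L)) || moves[1L] != 1L) {
      stop("move_table dialect error: read '", res$qname[i],
           "' has an invalid stride or move array")
    }
    starts_idx <- which(moves == 1L)
    ends_idx <- c(starts_idx[-1L] - 1L, length(moves))
    ev <- data.frame(position = seq_along(starts_idx) - 1L,
                     start = ts + (starts_idx - 1L) * stride,
                     length = (ends_idx - starts_idx + 1L) * stride)
    out[[res$qname[i]]] <- event_table(res$qname[i], "BASECALL", ev)
  }
  out[order(names(out))]
}

#' Write event tables to a TSV dialect
#'
#' Supports the two four-column dialects (`tombo_tsv` for reference-space
#' tables, `f5c_resquiggle` for basecall-space tables). Re-reading the file
#' with [read_event_dialect()] reproduces the collection exactly.
#'
#' @param tables List of [event_table()] objects.
#' @param path Output path.
#' @param dialect `"tombo_tsv"` or `"f5c_resquiggle"`.
#' @return `path`, invisibly.
#' @export
write_event_tsv <- function(tables, path,
                            dialect = c("tombo_tsv", "f5c_resquiggle")) {
  dialect <- match.arg(dialect)
  want_space <- if (dialect == "tombo_tsv") "REFERENCE" else "BASECALL"
  pos_col <- if (dialect == "tombo_tsv") "ref_position" else "basecall_position"
  rows <- lapply(tables, function(tb) {
    if (tb$coordinate_space != want_space) {
      stop("cannot write a ", tb$coordinate_space, "-space table to the ",
           dialect, " dialect")
    }
    cbind(read_id = tb$read_id, tb$events)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "position"] <- pos_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accept .sam transparently where a BAM is expected (fixtures are text SAM).
as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- sub("\\.sam$", "", path, ignore.case = TRUE)
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
  } else {
    if (!file.exists(paste0(path, ".bai"))) {
      try(Rsamtools::indexBam(path), silent = TRUE)
    }
    path
  }
}
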