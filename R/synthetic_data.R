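#' Configuration for the synthetic sample-pair generator
#'
#' Describes a native-vs-control contrast: per-base current levels in pA,
#' Gaussian measurement noise, geometric dwell times, and a localized
#' modification effect. The native group's current at `modified_position` is
#' shifted by `effect_delta` (in normalized-current units, i.e. multiples of
#' the robust scale of the level track; flanking positions get
#' `neighbor_deltas`), and its emitted base at that site is corrupted with
#' probability `basecall_error_rate`, mimicking the elevated mismatch rate
#' basecallers show over modified bases. `effect_delta = 0` yields two
#' statistically exchangeable groups.
#'
#' Defaults describe an R9.4.1-like DNA run: 4 kHz sampling, per-base levels
#' A=85, C=95, T=100, G=110 pA, noise sd 2.5 pA, dwell ~ 1 + Geometric(1/9)
#' (mean 9 samples per base), 50 reads per group.
#'
#' @param seed Integer RNG seed (determinism: fixed seed => identical files).
#' @param reference_length Bases in the synthetic reference.
#' @param modified_position 0-based modified site (default: middle).
#' @param effect_delta Normalized-current shift at the modified site.
#' @param neighbor_deltas Shifts at the immediate flanks (offset -1, +1).
#' @param per_base_levels Named numeric, mean pA level per base.
#' @param noise_sd Gaussian noise sd in pA.
#' @param dwell_geometric_p Geometric success probability; dwell = 1 + G(p).
#' @param n_reads Reads per group.
#' @param molecule `"DNA"` or `"RNA"` (RNA stores the signal 3'->5').
#' @param basecall_error_rate Substitution probability at the modified site
#'   in the native group's emitted sequences.
#' @param sampling_rate Hz.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              reference_length = 60L,
                              modified_position = NULL,
                              effect_delta = 1.5,
                              neighbor_deltas = c(0.75, 0.75),
                              per_base_levels = c(A = 85, C = 95,
                                                  T = 100, G = 110),
                              noise_sd = 2.5,
                              dwell_geometric_p = 1 / 9,
                              n_reads = 50L,
                              molecule = c("DNA", "RNA"),
                              basecall_error_rate = 0.15,
                              sampling_rate = 4000) {
  molecule <- match.arg(molecule)
  if (is.null(modified_position)) {
    modified_position <- as.integer(reference_length %/% 2L)
  }
  if (modified_position < 0L || modified_position >= reference_length) {
    stop("modified_position ", modified_position,
         " outside the reference [0, ", reference_length, ")")
  }
  stopifnot(dwell_geometric_p > 0, dwell_geometric_p < 1,
            noise_sd >= 0, n_reads >= 1,
            all(c("A", "C", "G", "T") %in% names(per_base_levels)))
  structure(list(seed = as.integer(seed),
                 reference_length = as.integer(reference_length),
                 modified_position = as.integer(modified_position),
                 effect_delta = effect_delta,
                 neighbor_deltas = neighbor_deltas,
                 per_base_levels = per_base_levels,
                 noise_sd = noise_sd,
                 dwell_geometric_p = dwell_geometric_p,
                 n_reads = as.integer(n_reads),
                 molecule = molecule,
                 basecall_error_rate = basecall_error_rate,
                 sampling_rate = sampling_rate),
            class = "simulation_config")
}

# pA shift applied at each reference position for the native group.
# effect_delta is given in normalized units; the conversion factor is the
# plain MAD of the per-position level track, the same robust scale the
# normalization step divides by.
native_delta_track <- function(config, ref_bases) {
  levels_track <- config$per_base_levels[ref_bases]
  scale <- stats::median(abs(levels_track - stats::median(levels_track)))
  if (scale == 0) scale <- 1
  track <- numeric(config$reference_length)
  mp <- config$modified_position
  track[mp + 1L] <- config$effect_delta * scale
  nd <- config$neighbor_deltas
  if (length(nd) >= 1L && mp - 1L >= 0L) track[mp] <- nd[1L] * scale
  if (length(nd) >= 2L && mp + 1L < config$reference_length) {
    track[mp + 2L] <- nd[2L] * scale
  }
  track
}

#' Generate a complete synthetic native/control fixture set
#'
#' Emits mutually consistent files for both groups under `out_dir`:
#' `reference.fasta` (+ .fai), `<group>.slow5` (ASCII SLOW5),
#' `<group>.f5c_resquiggle.tsv` (basecall-space events),
#' `<group>.tombo.tsv` (reference-space events), and `<group>.bam` (+ .bai).
#' Every read spans the whole reference; alignments are perfect-match CIGARs
#' except for the substitutions injected at the modified site. For RNA the
#' SLOW5 signal and the basecall-space event starts are stored 3'->5', so
#' the fixtures exercise [reverse_rna_events()].
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created).
#' @return List with the file paths per group, the reference string, and the
#'   ground truth (`modified_position`, `delta_track_pA`).
#' @export
simulate_sample_pair <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  bases <- c("A", "C", "G", "T")
  ref_bases <- sample(bases, config$reference_length, replace = TRUE)
  ref_seq <- paste(ref_bases, collapse = "")
  fasta <- file.path(out_dir, "reference.fasta")
  writeLines(c(">synthetic_ref", ref_seq), fasta)
  Rsamtools::indexFa(fasta)

  delta_track <- native_delta_track(config, ref_bases)
  files <- list(reference = fasta)
  for (g in c("native", "control")) {
    files[[g]] <- simulate_group(config, g, ref_bases,
                                 if (g == "native") delta_track
                                 else numeric(config$reference_length),
                                 out_dir)
  }
  files$truth <- list(modified_position = config$modified_position,
                      delta_track_pA = delta_track,
                      reference = ref_seq)
  files
}

simulate_group <- function(config, group, ref_bases, delta_track, out_dir) {
  n_pos <- config$reference_length
  levels_track <- config$per_base_levels[ref_bases] + delta_track
  reads <- list(); f5c_rows <- list(); tombo_rows <- list(); sam_rows <- list()
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(config$n_reads)) {
    id <- sprintf("%s_read_%03d", group, r)
    dwell <- 1L + stats::rgeom(n_pos, config$dwell_geometric_p)
    starts <- c(0L, cumsum(dwell)[-n_pos])
    n_samp <- sum(dwell)
    signal <- stats::rnorm(n_samp,
                           mean = rep(levels_track, dwell),
                           sd = config$noise_sd)
    # emitted sequence: reference, with a possible substitution at the
    # modified site (native group only)
    seq_bases <- ref_bases
    if (group == "native" && config$basecall_error_rate > 0 &&
        stats::runif(1) < config$basecall_error_rate) {
      mp <- config$modified_position
      seq_bases[mp + 1L] <- sample(setdiff(bases, ref_bases[mp + 1L]), 1L)
    }
    ev_start <- starts
    if (config$molecule == "RNA") {
      signal <- rev(signal)
      ev_start <- n_samp - starts - dwell
    }
    reads[[id]] <- raw_read(id, signal, sampling_rate = config$sampling_rate,
                            molecule = config$molecule)
    f5c_rows[[id]] <- data.frame(read_id = id,
                                 basecall_position = seq_len(n_pos) - 1L,
                                 start = ev_start, length = dwell)
    # reference-space export: indices into the 5'->3'-oriented signal
    tombo_rows[[id]] <- data.frame(read_id = id,
                                   ref_position = seq_len(n_pos) - 1L,
                                   start = starts, length = dwell)
    sam_rows[[id]] <- paste(id, 0L, "synthetic_ref", 1L, 60L,
                            paste0(n_pos, "M"), "*", 0L, 0L,
                            paste(seq_bases, collapse = ""), "*",
                            sep = "\t")
  }

  slow5 <- file.path(out_dir, paste0(group, ".slow5"))
  write_slow5(reads, slow5,
              scaling = list(digitisation = 10000, range = 1000, offset = 0))
  f5c <- file.path(out_dir, paste0(group, ".f5c_resquiggle.tsv"))
  df <- do.call(rbind, f5c_rows)
  df <- df[order(df$read_id, df$start), ]
  utils::write.table(df, f5c, sep = "\t", quote = FALSE, row.names = FALSE)
  tombo <- file.path(out_dir, paste0(group, ".tombo.tsv"))
  utils::write.table(do.call(rbind, tombo_rows), tombo, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sam <- file.path(out_dir, paste0(group, ".sam"))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:synthetic_ref\tLN:", n_pos),
               unlist(sam_rows)), sam)
  bam <- Rsamtools::asBam(sam, file.path(out_dir, group),
                          overwrite = TRUE, indexDestination = TRUE)
  list(slow5 = slow5, f5c_resquiggle = f5c, tombo = tombo, bam = bam,
       sam = sam)
}
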