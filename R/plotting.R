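#' Assemble figure-ready data for the four panels
#'
#' All numeric computation for the figures happens here — quartiles, 1.5 x
#' IQR whiskers and outliers per (position, group, feature), mismatch
#' fractions, PC scores at the center site, and the -log10 p profile with
#' its cutoff line — so rendering is pure drawing. Quartiles use linear
#' interpolation (R quantile type 7); whiskers extend to the most extreme
#' observation within 1.5 x IQR of the box.
#'
#' @param profiles Named list of `pileup_profile` objects (`native`,
#'   `control`), or `NULL` to omit the alignment panel.
#' @param features Feature table from [build_feature_table()], or `NULL`.
#' @param test_results A `significance_profile`, or `NULL`.
#' @param options List: `rna` (display U for T), `cutoff` (significance
#'   line), `center` (0-based site for the PCA panel; default = most
#'   significant).
#' @return List of class `plot_bundle` with `region`, `alignment`,
#'   `feature_boxes`, `pca`, `significance`, `options`.
#' @export
build_plot_bundle <- function(profiles = NULL, features = NULL,
                              test_results = NULL, options = list()) {
  opts <- utils::modifyList(list(rna = FALSE, cutoff = 3, center = NULL),
                            options)
  ranges <- list()

  alignment <- NULL
  if (!is.null(profiles)) {
    alignment <- do.call(rbind, lapply(names(profiles), function(g) {
      pr <- profiles[[g]]
      data.frame(group = g, contig = pr$contig, position = pr$positions,
                 ref_base = pr$ref_base, pr$counts,
                 coverage = pr$coverage,
                 mismatch_fraction = mismatch_fractions(pr),
                 check.names = FALSE)
    }))
    ranges$alignment <- range(alignment$position)
  }

  feature_boxes <- NULL
  if (!is.null(features) && nrow(features) > 0L) {
    long <- stats::reshape(
      features[, c("ref_position", "ref_base", "group",
                   "mean", "median", "std", "dwell")],
      varying = c("mean", "median", "std", "dwell"), v.names = "value",
      timevar = "feature", times = c("mean", "median", "std", "dwell"),
      direction = "long")
    grp <- interaction(long$ref_position, long$group, long$feature,
                       drop = TRUE)
    feature_boxes <- do.call(rbind, lapply(split(long, grp), function(d) {
      q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3L] - q[1L]
      lo <- min(d$value[d$value >= q[1L] - 1.5 * iqr])
      hi <- max(d$value[d$value <= q[3L] + 1.5 * iqr])
      data.frame(position = d$ref_position[1L], ref_base = d$ref_base[1L],
                 group = d$group[1L], feature = d$feature[1L],
                 q1 = q[1L], median = q[2L], q3 = q[3L],
                 whisker_lo = lo, whisker_hi = hi,
                 n_outliers = sum(d$value < lo | d$value > hi),
                 n = nrow(d))
    }))
    rownames(feature_boxes) <- NULL
    ranges$features <- range(feature_boxes$position)
  }

  pca <- NULL; significance <- NULL
  if (!is.null(test_results)) {
    res <- test_results$results
    significance <- data.frame(position = res$position,
                               ref_base = res$ref_base,
                               neg_log10_p = res$neg_log10_p,
                               flagged = res$flagged)
    center <- opts$center
    if (is.null(center)) center <- res$position[which.max(res$neg_log10_p)]
    sc <- test_results$scores[[as.character(center)]]
    if (!is.null(sc)) {
      pca <- list(center = center,
                  scores = data.frame(read_id = sc$read_id,
                                      group = as.character(sc$group),
                                      PC1 = sc$scores[, 1L],
                                      PC2 = if (ncol(sc$scores) >= 2L)
                                        sc$scores[, 2L] else NA_real_),
                  explained_variance_ratio = sc$explained_variance_ratio)
    }
    ranges$significance <- range(significance$position)
  }

  if (length(ranges) > 1L) {
    spans <- do.call(rbind, ranges)
    if (stats::var(spans[, 1L]) > 0 || stats::var(spans[, 2L]) > 0) {
      # panels may legitimately differ by the k-mer margin; anything larger
      # indicates mismatched inputs
      if (max(spans[, 1L]) - min(spans[, 1L]) > 5 ||
          max(spans[, 2L]) - min(spans[, 2L]) > 5) {
        stop("region mismatch between panel inputs: ",
             paste(rownames(spans), apply(spans, 1L, paste, collapse = "-"),
                   collapse = "; "))
      }
    }
  }

  if (opts$rna) {
    if (!is.null(alignment)) {
      alignment$ref_base[alignment$ref_base == "T"] <- "U"
    }
    if (!is.null(feature_boxes)) {
      feature_boxes$ref_base[feature_boxes$ref_base == "T"] <- "U"
    }
    if (!is.null(significance)) {
      significance$ref_base[significance$ref_base == "T"] <- "U"
    }
  }

  structure(list(region = ranges, alignment = alignment,
                 feature_boxes = feature_boxes, pca = pca,
                 significance = significance, options = opts),
            class = "plot_bundle")
}

axis_labels <- function(positions, ref_base) {
  paste0(ref_base, "\n", positions + 1L)
}

group_palette <- c(native = "#d62728", control = "#1a1a1a")

panel_alignment <- function(bundle) {
  d <- bundle$alignment
  long <- stats::reshape(d[, c("group", "position", "ref_base",
                               "A", "C", "G", "T")],
                         varying = c("A", "C", "G", "T"), v.names = "count",
                         timevar = "base", times = c("A", "C", "G", "T"),
                         direction = "long")
  disp_base <- long$base
  if (bundle$options$rna) disp_base[disp_base == "T"] <- "U"
  long$match <- disp_base == long$ref_base
  long$fill <- ifelse(long$match, "match", disp_base)
  pal <- c(match = "grey70", A = "#2ca02c", C = "#1f77b4",
           G = "#ff7f0e", T = "#d62728", U = "#d62728")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position + 1L,
                                     y = .data$count,
                                     fill = .data$fill)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~group, ncol = 1L) +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::scale_x_continuous(
      breaks = unique(d$position) + 1L,
      labels = axis_labels(unique(d$position),
                           d$ref_base[!duplicated(d$position)])) +
    ggplot2::labs(x = "reference position", y = "base count",
                  title = "Alignment profile") +
    ggplot2::theme_bw(base_size = 9)
}

panel_features <- function(bundle) {
  d <- bundle$feature_boxes
  d$feature <- factor(d$feature, levels = c("dwell", "mean", "median", "std"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position + 1L,
                                  fill = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_lo,
                                        ymax = .data$whisker_hi,
                                        group = interaction(.data$position,
                                                            .data$group)),
                           position = ggplot2::position_dodge(width = 0.7),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$position + 1L - 0.3, xmax = .data$position + 1L + 0.3,
      ymin = .data$q1, ymax = .data$q3,
      group = interaction(.data$position, .data$group)),
      position = ggplot2::position_dodge(width = 0.7), colour = "black",
      linewidth = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median,
                                     group = interaction(.data$position,
                                                         .data$group)),
                        position = ggplot2::position_dodge(width = 0.7),
                        size = 0.6) +
    ggplot2::facet_wrap(~feature, ncol = 1L, scales = "free_y") +
    ggplot2::scale_fill_manual(values = group_palette, name = NULL) +
    ggplot2::labs(x = "reference position", y = "normalized value",
                  title = "Current-event features") +
    ggplot2::theme_bw(base_size = 9)
}

panel_pca <- function(bundle) {
  p <- bundle$pca
  evr <- p$explained_variance_ratio
  ggplot2::ggplot(p$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = .data$group)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = group_palette, name = NULL) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * evr[min(2L, length(evr))]),
      title = sprintf("PCA at position %d", p$center + 1L)) +
    ggplot2::theme_bw(base_size = 9)
}

panel_significance <- function(bundle) {
  d <- bundle$significance
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position + 1L,
                                  y = .data$neg_log10_p,
                                  fill = .data$flagged)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = bundle$options$cutoff,
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d62728",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = d$position + 1L,
      labels = axis_labels(d$position, d$ref_base)) +
    ggplot2::labs(x = "reference position",
                  y = expression(-log[10] ~ italic(P)),
                  title = "MANOVA significance") +
    ggplot2::theme_bw(base_size = 9)
}

#' Render a plot bundle to image files
#'
#' Writes one collective figure plus one file per available panel.
#' Rendering draws only; every number shown was computed by
#' [build_plot_bundle()]. SVG output (the default) is byte-deterministic for
#' a given bundle.
#'
#' @param bundle A `plot_bundle`.
#' @param output_path Directory for the figures (created if needed).
#' @param format `"svg"`, `"pdf"` or `"png"`.
#' @param width,height Collective figure size in inches.
#' @return Character vector of files written, invisibly.
#' @export
render <- function(bundle, output_path, format = c("svg", "pdf", "png"),
                   width = 8, height = 10) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "plot_bundle"))
  dir.create(output_path, recursive = TRUE, showWarnings = FALSE)
  panels <- list()
  if (!is.null(bundle$alignment)) {
    panels$alignment <- panel_alignment(bundle)
  }
  if (!is.null(bundle$feature_boxes)) {
    panels$current_features <- panel_features(bundle)
  }
  if (!is.null(bundle$pca)) panels$pca <- panel_pca(bundle)
  if (is.null(bundle$significance) || nrow(bundle$significance) == 0L) {
    message("significance panel empty; omitted from the figure")
  } else {
    panels$significance <- panel_significance(bundle)
  }
  if (length(panels) == 0L) stop("plot bundle has no renderable panel")

  files <- character()
  dev_fun <- switch(format,
    svg = function(f, w, h) grDevices::svg(f, width = w, height = h),
    pdf = function(f, w, h) grDevices::pdf(f, width = w, height = h,
                                           useDingbats = FALSE),
    png = function(f, w, h) grDevices::png(f, width = w, height = h,
                                           units = "in", res = 150))
  for (nm in names(panels)) {
    f <- file.path(output_path, paste0(nm, ".", format))
    dev_fun(f, width, height / 2)
    print(panels[[nm]])
    grDevices::dev.off()
    files <- c(files, f)
  }
  f <- file.path(output_path, paste0("overview.", format))
  dev_fun(f, width, height)
  print(patchwork::wrap_plots(panels, ncol = 1L))
  grDevices::dev.off()
  files <- c(files, f)
  invisible(files)
}

#' Serialize a plot bundle to JSON
#'
#' @param bundle A `plot_bundle`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plot_bundle_json <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}
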