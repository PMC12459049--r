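# Cumulative plot data: the four plot kinds are built as plain layer tables
# (points, segment lines, rectangles, frequency bars, gene labels) on a
# concatenated genome axis; rendering is a thin ggplot2 step on top.

#' Concatenated genome axis coordinates
#'
#' Chromosomes are laid end to end; returns per-bin absolute x positions and
#' the chromosome boundaries for axis decoration.
#'
#' @param bin_map A [build_bin_map] result.
#' @return List with `bin_x` (bin midpoints on the genome axis), `bin_width`,
#'   `offsets` (named per-chromosome bp offsets), and `boundaries` (data frame
#'   of chromosome start/end/label positions).
#' @export
genome_axis <- function(bin_map) {
  chroms <- unique(as.character(bin_map$chrom))
  lens <- vapply(chroms, function(ch) {
    max(bin_map$end[as.character(bin_map$chrom) == ch])
  }, 0)
  offsets <- c(0, cumsum(lens))[seq_along(chroms)]
  names(offsets) <- chroms
  off_of_bin <- offsets[as.character(bin_map$chrom)]
  list(
    bin_x = off_of_bin + (bin_map$start + bin_map$end) / 2,
    bin_width = bin_map$end - bin_map$start + 1,
    offsets = offsets,
    boundaries = data.frame(
      chrom = chroms,
      start = unname(offsets),
      end = unname(offsets + lens),
      mid = unname(offsets + lens / 2)
    )
  )
}

new_plot_data <- function(kind, layers, bin_map) {
  structure(
    c(list(kind = kind, axis = genome_axis(bin_map)), layers),
    class = "cnv_plot_data"
  )
}

#' @export
print.cnv_plot_data <- function(x, ...) {
  cat(sprintf("cnv_plot_data (%s)\n", x$kind))
  invisible(x)
}

#' Combined-segmentation intensity plot data
#'
#' Point layer: per-bin cross-sample mean log2 ratio, with a seeded
#' horizontal jitter within the bin width. Line layer: per segment, the
#' cross-sample mean of the per-sample segment means. Optional gene labels
#' per [annotate_genes].
#'
#' @param bm A [bin_matrix].
#' @param shared_seg A `shared_segmentation` on the same bins.
#' @param gene_list Optional character vector of gene symbols to annotate.
#' @param probes Probe table (required when `gene_list` is given).
#' @param jitter_seed Seed for the jitter offsets (default 1).
#' @return A `cnv_plot_data` of kind `"cs_intensity"` with layers `points`,
#'   `segments`, `labels`.
#' @export
cs_intensity_data <- function(bm, shared_seg, gene_list = NULL, probes = NULL,
                              jitter_seed = 1L) {
  ax <- genome_axis(bm$bin_map)
  set.seed(jitter_seed)
  jitter <- (stats::runif(nrow(bm$values)) - 0.5) * ax$bin_width
  points <- data.frame(
    bin_id = bm$bin_map$bin_id,
    chrom = as.character(bm$bin_map$chrom),
    x = ax$bin_x + jitter,
    value = rowMeans(bm$values)
  )
  seg <- shared_seg$segments
  off <- ax$offsets[as.character(seg$chrom)]
  segments <- data.frame(
    chrom = as.character(seg$chrom),
    x_start = off + bm$bin_map$start[seg$start_bin],
    x_end = off + bm$bin_map$end[seg$end_bin],
    value = rowMeans(shared_seg$means)
  )
  labels <- if (!is.null(gene_list)) {
    annotate_genes(gene_list, probes, bm$bin_map, rowMeans(bm$values))
  } else {
    data.frame(gene = character(0), bin_id = integer(0), value = numeric(0))
  }
  if (nrow(labels)) labels$x <- ax$bin_x[labels$bin_id]
  new_plot_data(
    "cs_intensity",
    list(points = points, segments = segments, labels = labels),
    bm$bin_map
  )
}

#' Gene labels for the intensity plot
#'
#' Each gene is marked at the bin containing the most of its probes
#' (ties go to the leftmost bin), and only labelled when that bin's intensity
#' satisfies `|value| >= 0.15`.
#'
#' @param gene_list Character vector of gene symbols.
#' @param probes A [probe_table] with a `gene` column.
#' @param bin_map A [build_bin_map] result.
#' @param bin_means Per-bin mean intensities (cross-sample).
#' @param min_abs Label threshold (default 0.15, inclusive).
#' @return Data frame `gene`, `bin_id`, `value` for the labelled genes.
#' @export
annotate_genes <- function(gene_list, probes, bin_map, bin_means,
                           min_abs = 0.15) {
  probe_bin <- rep(NA_integer_, nrow(probes))
  names(probe_bin) <- probes$probe_id
  for (b in seq_len(nrow(bin_map))) {
    probe_bin[bin_map$probe_ids[[b]]] <- bin_map$bin_id[b]
  }
  rows <- list()
  for (g in gene_list) {
    bins <- probe_bin[probes$probe_id[!is.na(probes$gene) & probes$gene == g]]
    bins <- bins[!is.na(bins)]
    if (!length(bins)) {
      warn_fmt("gene %s not found in the probe annotation; skipped", g)
      next
    }
    counts <- table(bins)
    best <- as.integer(names(counts)[which.max(counts)]) # ties: leftmost
    if (abs(bin_means[best]) >= min_abs) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, bin_id = best, value = bin_means[best]
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), bin_id = integer(0), value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

frequency_layers <- function(abmat, bin_map) {
  reg <- abmat$regions
  ax <- genome_axis(bin_map)
  off <- ax$offsets[as.character(reg$chrom)]
  out <- data.frame(
    chrom = as.character(reg$chrom),
    x_start = unname(off) + reg$start,
    x_end = unname(off) + reg$end,
    gain = unname(abmat$gain_freq),
    loss = -unname(abmat$loss_freq)
  )
  rownames(out) <- NULL
  out
}

#' Combined-segmentation frequency plot data
#'
#' Per segment: gain frequency drawn upward, loss frequency downward, both
#' in `[0, 1]`.
#'
#' @param abmat An [aberration_matrix] from the combined segmentation.
#' @param bm The underlying [bin_matrix] (genome axis source).
#' @return A `cnv_plot_data` of kind `"cs_frequency"` with layer `bars`.
#' @export
cs_frequency_data <- function(abmat, bm) {
  new_plot_data(
    "cs_frequency",
    list(bars = frequency_layers(abmat, bm$bin_map)),
    bm$bin_map
  )
}

#' Sample-wise intensity plot data
#'
#' One rectangle per sample-segment at height equal to the segment mean;
#' every rectangle has opacity `1 / n_samples`, so recurrent segments darken.
#'
#' @param seg_list A `sample_segmentation_list`.
#' @param bm The underlying [bin_matrix].
#' @return A `cnv_plot_data` of kind `"sw_intensity"` with layer `rects`
#'   (including an `opacity` column) .
#' @export
sw_intensity_data <- function(seg_list, bm) {
  ax <- genome_axis(bm$bin_map)
  rects <- do.call(rbind, lapply(names(seg_list), function(s) {
    seg <- seg_list[[s]]
    off <- ax$offsets[as.character(seg$chrom)]
    data.frame(
      sample = s,
      chrom = seg$chrom,
      x_start = unname(off) + bm$bin_map$start[seg$start_bin],
      x_end = unname(off) + bm$bin_map$end[seg$end_bin],
      value = seg$mean
    )
  }))
  rects$opacity <- 1 / length(seg_list)
  rownames(rects) <- NULL
  new_plot_data("sw_intensity", list(rects = rects), bm$bin_map)
}

#' Sample-wise frequency plot data
#'
#' Frequency bars on the atomic intervals produced by re-segmenting
#' overlapping per-sample segments ([disjoint_intervals]), thresholded like
#' the combined-segmentation frequencies.
#'
#' @param abmat An [aberration_matrix] built from a
#'   `sample_segmentation_list` (its rows are the atoms).
#' @param bm The underlying [bin_matrix].
#' @return A `cnv_plot_data` of kind `"sw_frequency"` with layer `bars`.
#' @export
sw_frequency_data <- function(abmat, bm) {
  new_plot_data(
    "sw_frequency",
    list(bars = frequency_layers(abmat, bm$bin_map)),
    bm$bin_map
  )
}

#' Serialise plot-data layers to TSV
#'
#' Writes one TSV per layer as `<prefix>_<layer>.tsv`; these tables are the
#' regression surface of the plots.
#'
#' @param pd A `cnv_plot_data`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_plot_data <- function(pd, prefix) {
  layers <- setdiff(names(pd), c("kind", "axis"))
  paths <- character(0)
  for (layer in layers) {
    path <- sprintf("%s_%s.tsv", prefix, layer)
    utils::write.table(
      pd[[layer]], path, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}
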