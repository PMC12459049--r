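# Interchange formats: IGV SEG export, breakpoint BED, bin-matrix TSV
# (the toolkit's main entry point for users bringing their own
# normalisation), and the aberration-matrix TSV.

seg_rows <- function(seg_tab, bin_map, sample) {
  data.frame(
    ID = sample,
    chrom = as.character(seg_tab$chrom),
    loc.start = bin_map$start[seg_tab$start_bin],
    loc.end = bin_map$end[seg_tab$end_bin],
    num.mark = seg_tab$end_bin - seg_tab$start_bin + 1L,
    seg.mean = seg_tab$mean
  )
}

#' Write a segmentation as an IGV SEG file
#'
#' One row per sample x segment: `ID`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark` (bins), `seg.mean`.
#'
#' @param segmentation A `shared_segmentation` or `sample_segmentation_list`.
#' @param bm The underlying [bin_matrix] (bp coordinates).
#' @param path Output path.
#' @export
write_seg <- function(segmentation, bm, path) {
  if (inherits(segmentation, "shared_segmentation")) {
    tabs <- lapply(seq_along(segmentation$samples), function(s) {
      d <- segmentation$segments
      d$mean <- segmentation$means[, s]
      seg_rows(d, bm$bin_map, segmentation$samples[s])
    })
  } else {
    tabs <- lapply(names(segmentation), function(s) {
      seg_rows(segmentation[[s]], bm$bin_map, s)
    })
  }
  utils::write.table(
    do.call(rbind, tabs), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write shared breakpoints as BED
#'
#' Each interior breakpoint is emitted as the 1-bp boundary between its
#' segment-end bin and the next (0-based half-open BED).
#'
#' @param shared_seg A `shared_segmentation`.
#' @param bm The underlying [bin_matrix].
#' @param path Output path.
#' @export
write_breakpoint_bed <- function(shared_seg, bm, path) {
  rows <- do.call(rbind, lapply(names(shared_seg$breakpoints), function(ch) {
    b <- shared_seg$breakpoints[[ch]]
    if (!length(b)) return(NULL)
    data.frame(
      chrom = ch,
      start = bm$bin_map$end[b],
      end = bm$bin_map$end[b] + 1
    )
  }))
  if (is.null(rows)) rows <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  utils::write.table(
    rows, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write a bin matrix as TSV
#'
#' Columns `bin_id`, `chrom`, `start`, `end`, `n_probes`, then one column per
#' sample. Per-bin probe variances are written alongside as
#' `<path>.var.tsv` when present.
#'
#' @param bm A [bin_matrix].
#' @param path Output path.
#' @export
write_bin_matrix <- function(bm, path) {
  head <- data.frame(
    bin_id = bm$bin_map$bin_id,
    chrom = as.character(bm$bin_map$chrom),
    start = bm$bin_map$start,
    end = bm$bin_map$end,
    n_probes = bm$bin_map$n_probes
  )
  utils::write.table(
    cbind(head, as.data.frame(bm$values)), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(bm$var)) {
    utils::write.table(
      cbind(head, as.data.frame(bm$var)), paste0(path, ".var.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Read a bin matrix TSV
#'
#' Inverse of [write_bin_matrix]; probe membership is not preserved by the
#' TSV (the `probe_ids` column comes back empty).
#'
#' @param path TSV path.
#' @param genome_layout Chromosome ordering (defaults to order of
#'   appearance).
#' @return A [bin_matrix].
#' @export
read_bin_matrix <- function(path, genome_layout = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("bin_id", "chrom", "start", "end", "n_probes")
  if (!all(meta %in% names(df))) {
    stop_fmt(
      "bin matrix TSV needs columns: %s", paste(meta, collapse = ", ")
    )
  }
  layout <- genome_layout %||% unique(df$chrom)
  bmap <- df[meta]
  bmap$chrom <- factor(bmap$chrom, levels = layout)
  bmap$probe_ids <- I(replicate(nrow(bmap), character(0), simplify = FALSE))
  class(bmap) <- c("bin_map", "data.frame")
  values <- as.matrix(df[setdiff(names(df), meta)])
  var <- NULL
  var_path <- paste0(path, ".var.tsv")
  if (file.exists(var_path)) {
    vdf <- utils::read.delim(var_path, stringsAsFactors = FALSE, check.names = FALSE)
    var <- as.matrix(vdf[setdiff(names(vdf), meta)])
  }
  bin_matrix(values, bmap, var = var)
}

#' Write an aberration matrix as TSV
#'
#' Rows are labelled regions (`chrom:start-end` or `1p`-style arms), columns
#' the samples in similarity order, followed by the gain and loss frequency
#' columns.
#'
#' @param abmat An [aberration_matrix].
#' @param path Output path.
#' @param order Optional sample order (defaults to
#'   [order_by_similarity]).
#' @export
write_aberration_matrix <- function(abmat, path, order = NULL) {
  ord <- order %||% order_by_similarity(abmat)
  out <- data.frame(
    region = abmat$regions$label,
    abmat$calls[, ord, drop = FALSE],
    gain_freq = abmat$gain_freq,
    loss_freq = abmat$loss_freq,
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
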