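# Genomic binning: fixed-size windows merged left-to-right until each bin
# holds at least min_probes probes; bin values are per-bin probe medians.

#' Build the genomic bin map
#'
#' Each chromosome is tiled with `bin_size` windows from position 1; windows
#' are accumulated left to right and a bin is emitted as soon as the running
#' probe count reaches `min_probes`. A trailing accumulation holding fewer
#' probes is merged back into the previously emitted bin (or forms the only
#' bin when none exists), so every bin holds at least `min_probes` probes
#' whenever the chromosome does. Empty windows never form bins on their own.
#'
#' @param probes A [probe_table].
#' @param bin_size Window size in bp (default 50000).
#' @param min_probes Minimum probes per emitted bin (default 15).
#' @return A `bin_map`: data frame with `bin_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_probes`, and a `probe_ids` list column holding
#'   the member probe IDs.
#' @export
build_bin_map <- function(probes, bin_size = 50000, min_probes = 15) {
  stopifnot(bin_size > 0, min_probes >= 1)
  rows <- list()
  for (ch in levels(probes$chrom)) {
    p <- probes[probes$chrom == ch, ]
    if (!nrow(p)) next
    n_win <- ceiling(max(p$pos) / bin_size)
    win_of <- pmin((p$pos - 1L) %/% bin_size + 1L, n_win)
    counts <- tabulate(win_of, nbins = n_win)
    bins <- list()
    acc_start <- 1L
    acc_n <- 0L
    for (k in seq_len(n_win)) {
      acc_n <- acc_n + counts[k]
      if (acc_n >= min_probes) {
        bins[[length(bins) + 1L]] <- c(acc_start, k, acc_n)
        acc_start <- k + 1L
        acc_n <- 0L
      }
    }
    if (acc_n > 0L) {
      if (length(bins)) {
        last <- bins[[length(bins)]]
        bins[[length(bins)]] <- c(last[1], n_win, last[3] + acc_n)
      } else {
        bins[[1L]] <- c(acc_start, n_win, acc_n)
      }
    }
    for (b in bins) {
      sel <- win_of >= b[1] & win_of <= b[2]
      rows[[length(rows) + 1L]] <- list(
        chrom = ch,
        start = (b[1] - 1L) * bin_size + 1L,
        end = b[2] * bin_size,
        n_probes = b[3],
        probe_ids = p$probe_id[sel]
      )
    }
  }
  if (!length(rows)) {
    warn_fmt("no probes on any chromosome; empty bin map")
  }
  out <- data.frame(
    bin_id = seq_along(rows),
    chrom = factor(
      vapply(rows, `[[`, "", "chrom"), levels = levels(probes$chrom)
    ),
    start = vapply(rows, function(r) as.numeric(r$start), 0),
    end = vapply(rows, function(r) as.numeric(r$end), 0),
    n_probes = vapply(rows, function(r) as.integer(r$n_probes), 0L)
  )
  out$probe_ids <- I(lapply(rows, `[[`, "probe_ids"))
  class(out) <- c("bin_map", "data.frame")
  out
}

#' Aggregate probe log2 ratios into bins
#'
#' Per bin per sample: the median of the member probes' log2 ratios, plus the
#' population variance of those probes (the weight denominator of weighted
#' CBS).
#'
#' @param log_ratios Probes x samples log2-ratio matrix with probe IDs as row
#'   names.
#' @param bin_map A [build_bin_map] result.
#' @return A `bin_matrix`: list with `values` (bins x samples), `var`
#'   (bins x samples probe variances), `bin_map`, `samples`.
#' @export
aggregate_probes <- function(log_ratios, bin_map) {
  idx <- lapply(bin_map$probe_ids, function(ids) {
    j <- match(ids, rownames(log_ratios))
    j[!is.na(j)]
  })
  if (any(lengths(idx) == 0L)) {
    stop_fmt("bin with no member probes present in the log2-ratio matrix")
  }
  nb <- nrow(bin_map)
  ns <- ncol(log_ratios)
  values <- matrix(NA_real_, nb, ns)
  vars <- matrix(NA_real_, nb, ns)
  for (b in seq_len(nb)) {
    sub <- log_ratios[idx[[b]], , drop = FALSE]
    values[b, ] <- apply(sub, 2, stats::median)
    vars[b, ] <- apply(sub, 2, pop_var)
  }
  bin_matrix(values, bin_map, var = vars, samples = colnames(log_ratios))
}

#' Construct a bin matrix container
#'
#' @param values Bins x samples numeric matrix of bin log2 ratios.
#' @param bin_map Matching [build_bin_map] result.
#' @param var Optional bins x samples matrix of per-bin probe variances.
#' @param samples Sample IDs (defaults to `colnames(values)`).
#' @return A `bin_matrix` object.
#' @export
bin_matrix <- function(values, bin_map, var = NULL, samples = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(bin_map)) stop_fmt("row count must equal bin count")
  if (any(!is.finite(values))) stop_fmt("bin values must be finite")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
  dimnames(values) <- list(bin_map$bin_id, samples)
  if (!is.null(var)) dimnames(var) <- dimnames(values)
  structure(
    list(values = values, var = var, bin_map = bin_map, samples = samples),
    class = "bin_matrix"
  )
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf(
    "bin_matrix: %d bins x %d samples over chromosome(s) %s\n",
    nrow(x$values), ncol(x$values),
    paste(unique(as.character(x$bin_map$chrom)), collapse = ", ")
  ))
  invisible(x)
}

chrom_bin_index <- function(bin_map) {
  split(seq_len(nrow(bin_map)), droplevels(bin_map$chrom))
}
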