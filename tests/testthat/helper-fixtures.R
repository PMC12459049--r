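# Small in-code fixtures shared across the suite.

tiny_probe_df <- function() {
  data.frame(
    probe_id = sprintf("cg%03d", 1:9),
    chrom = c("1", "1", "1", "1", "1", "2", "2", "2", "2"),
    pos = c(100, 50, 200, 60000, 70000, 100, 200, 300, 400),
    gene = c("GENE1", "GENE1", NA, "GENE2", NA, NA, NA, NA, NA)
  )
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Regularly spaced probe table: `per_win` probes in each bin-size window.
spaced_probes <- function(n_windows, per_win, chrom = "1", bin_size = 50000) {
  pos <- as.vector(vapply(seq_len(n_windows), function(k) {
    round((k - 1) * bin_size + bin_size * (seq_len(per_win) - 0.5) / per_win)
  }, numeric(per_win)))
  probe_table(
    data.frame(
      probe_id = sprintf("p%04d", seq_along(pos)),
      chrom = chrom, pos = pos
    ),
    genome_layout = unique(chrom)
  )
}

# Bin matrix from a plain values matrix on a synthetic one-or-more-chromosome
# genome (equal bins per chromosome unless bins_per_chrom given).
quick_bin_matrix <- function(values, chroms = "1", bins_per_chrom = NULL) {
  values <- as.matrix(values)
  nb <- nrow(values)
  bins_per_chrom <- bins_per_chrom %||% rep(nb / length(chroms), length(chroms))
  cb <- stats::setNames(as.integer(bins_per_chrom), chroms)
  bin_matrix(values, synth_bin_map(cb), samples = colnames(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive minimiser of the penalised multi-sample SSE over all breakpoint
# subsets: the independent oracle for the dynamic program.
brute_force_pcf <- function(values, penalty, noise = NULL) {
  values <- as.matrix(values)
  if (!is.null(noise)) values <- sweep(values, 2, noise, "/")
  n <- nrow(values)
  sse <- function(i, j) {
    sub <- values[i:j, , drop = FALSE]
    sum(colSums(sub^2) - colSums(sub)^2 / (j - i + 1))
  }
  best <- list(cost = Inf, ends = NULL)
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    ends <- c(cuts, n)
    starts <- c(1, head(ends, -1) + 1)
    cost <- sum(mapply(sse, starts, ends)) + penalty * length(cuts)
    if (cost < best$cost - 1e-12) best <- list(cost = cost, ends = ends)
  }
  best
}
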