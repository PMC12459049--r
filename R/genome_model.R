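#' Default chromosome layout
#'
#' Canonical ordered autosome + sex chromosome set used as the genome axis.
#' Mitochondrial and unplaced contigs are intentionally absent: probes mapping
#' outside this layout are dropped on load.
#'
#' @return Character vector `"1"`..`"22"`, `"X"`, `"Y"`.
#' @export
default_chromosomes <- function() c(as.character(1:22), "X", "Y")

norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Construct a validated probe annotation table
#'
#' @param df Data frame with columns `probe_id`, `chrom`, `pos` and optionally
#'   `gene`.
#' @param genome_layout Ordered chromosome names admitted to the coordinate
#'   system; probes elsewhere are dropped with a warning.
#' @return A `probe_table`: data frame sorted by (chrom, pos), `chrom` a factor
#'   with the layout's level order, positions 1-based.
#' @export
probe_table <- function(df, genome_layout = default_chromosomes()) {
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_fmt("probe annotation lacks column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) {
    stop_fmt("duplicate probe_id: %s", paste(unique(dup), collapse = ", "))
  }
  df$chrom <- norm_chrom(df$chrom)
  off <- !(df$chrom %in% genome_layout)
  if (any(off)) {
    warn_fmt("dropping %d probe(s) outside the genome layout", sum(off))
    df <- df[!off, , drop = FALSE]
  }
  if (nrow(df) && any(df$pos < 1)) stop_fmt("probe positions must be >= 1")
  df$chrom <- factor(df$chrom, levels = genome_layout)
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  df <- df[order(df$chrom, df$pos), c("probe_id", "chrom", "pos", "gene")]
  rownames(df) <- NULL
  class(df) <- c("probe_table", "data.frame")
  df
}

#' Load a probe annotation TSV
#'
#' Expects a header with columns `probe_id`, `chrom`, `pos` and optionally
#' `gene`. `chr` prefixes are stripped; the result is sorted by (chrom, pos).
#'
#' @inheritParams probe_table
#' @param path Path to the TSV file.
#' @return A [probe_table].
#' @export
load_probe_table <- function(path, genome_layout = default_chromosomes()) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_table(df, genome_layout)
}

#' Write a probe annotation TSV
#'
#' @param probes A [probe_table].
#' @param path Output path.
#' @export
write_probe_table <- function(probes, path) {
  out <- as.data.frame(probes)
  out$chrom <- as.character(out$chrom)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load chromosome-arm definitions from BED4
#'
#' The 4th BED column carries the arm label (e.g. `"1p"`). BED's 0-based
#' half-open intervals are converted to the internal 1-based inclusive
#' convention.
#'
#' @param path BED4 file path (no header).
#' @param genome_layout Admitted chromosome names.
#' @return An `arm_table`: data frame with `chrom`, `arm` (`"p"`/`"q"`),
#'   `start`, `end` (1-based inclusive), sorted with p before q.
#' @export
load_arm_table <- function(path, genome_layout = default_chromosomes()) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_fmt("arm BED needs 4 columns (chrom start end label)")
  names(df)[1:4] <- c("chrom", "start", "end", "label")
  arm_table(data.frame(
    chrom = norm_chrom(df$chrom),
    arm = substr(df$label, nchar(df$label), nchar(df$label)),
    start = df$start + 1L,
    end = df$end,
    stringsAsFactors = FALSE
  ), genome_layout)
}

#' Construct a validated arm table
#'
#' @param df Data frame with columns `chrom`, `arm`, `start`, `end` (1-based
#'   inclusive).
#' @param genome_layout Admitted chromosome names.
#' @return An `arm_table` (see [load_arm_table]).
#' @export
arm_table <- function(df, genome_layout = default_chromosomes()) {
  if (!all(df$arm %in% c("p", "q"))) stop_fmt("arm labels must end in 'p' or 'q'")
  if (any(df$start >= df$end)) stop_fmt("arm start must precede arm end")
  df$chrom <- factor(norm_chrom(df$chrom), levels = genome_layout)
  df <- df[order(df$chrom, df$start), c("chrom", "arm", "start", "end")]
  for (ch in levels(droplevels(df$chrom))) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop_fmt("overlapping arms on chromosome %s", ch)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("arm_table", "data.frame")
  df
}

#' Load a sample manifest TSV
#'
#' @param path TSV with header `sample_id`, `path`, `array_type`.
#' @return Validated data frame; `array_type` one of 450k, EPIC, EPICv2,
#'   mouse, matrix.
#' @export
load_sample_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "array_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_fmt("duplicate sample_id in manifest")
  ok <- c("450k", "EPIC", "EPICv2", "mouse", "matrix")
  bad <- setdiff(df$array_type, ok)
  if (length(bad)) stop_fmt("unrecognised array_type: %s", paste(bad, collapse = ", "))
  df
}

#' Harmonise probe sets across array types by intersection
#'
#' Mixed-array cohorts are projected onto the probes shared by every array:
#' the probe-ID intersection, with coordinates taken from the first table.
#'
#' @param tables List of [probe_table] objects (>= 1).
#' @return A [probe_table] restricted to the common probes.
#' @export
harmonize_probe_sets <- function(tables) {
  if (!length(tables)) stop_fmt("need at least one probe table")
  common <- Reduce(intersect, lapply(tables, function(t) t$probe_id))
  if (!length(common)) {
    stop_fmt(paste(
      "probe-set intersection is empty;",
      "analyse the array types separately"
    ))
  }
  first <- tables[[1]]
  out <- first[first$probe_id %in% common, , drop = FALSE]
  message(sprintf("harmonized to %d shared probe(s)", nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("probe_table", "data.frame")
  out
}
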