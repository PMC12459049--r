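# Aberration calling: threshold segment means into {-1, 0, +1}, with an
# optional per-segment noise adjustment of the threshold for CBS-derived
# segments, arm-level condensation, and similarity ordering of samples.

#' Configuration for aberration calling
#'
#' @param theta Calling threshold on segment means (> 0, default 0.2).
#' @param min_bins Segments with fewer bins are removed from the aberration
#'   matrix entirely (default 2).
#' @param noise_adjust Multiply the threshold by the per-segment noise factor
#'   (`theta_eff = theta * noise_seg`). `NA` (default) resolves to TRUE for
#'   sample-wise (CBS) segmentations and FALSE for the combined fit.
#' @param strict Require `|mean| > threshold` (default) rather than `>=`.
#' @return A `calling_config` list.
#' @export
calling_config <- function(theta = 0.2, min_bins = 2L, noise_adjust = NA,
                           strict = TRUE) {
  if (!is.numeric(theta) || theta <= 0) stop_fmt("theta must be > 0")
  stopifnot(min_bins >= 1)
  structure(
    list(
      theta = theta, min_bins = as.integer(min_bins),
      noise_adjust = noise_adjust, strict = strict
    ),
    class = "calling_config"
  )
}

#' Per-segment noise factor
#'
#' `noise_seg = max(1, sd(residuals about the segment mean) / reference)`,
#' where the reference is the cohort-wide median of such residual SDs. The
#' floor at 1 means the adjustment only ever raises the calling threshold.
#' Single-bin segments (SD undefined) get factor 1.
#'
#' @param values The sample's bin values within the segment.
#' @param reference_noise Cohort reference residual SD (> 0).
#' @return The noise factor `noise_seg >= 1`.
#' @export
segment_noise_factor <- function(values, reference_noise) {
  if (length(values) < 2 || reference_noise <= 0) return(1)
  max(1, stats::sd(values - mean(values)) / reference_noise)
}

threshold_calls <- function(means, theta_eff, strict) {
  cmp <- if (strict) {
    function(a, b) a > b
  } else {
    function(a, b) a >= b
  }
  calls <- matrix(0L, nrow(means), ncol(means), dimnames = dimnames(means))
  calls[cmp(means, theta_eff)] <- 1L
  calls[cmp(-means, theta_eff)] <- -1L
  calls
}

# Rows (regions) and per-sample means for either segmentation flavour.
calling_rows <- function(segmentation, bm) {
  if (inherits(segmentation, "shared_segmentation")) {
    list(
      rows = segmentation$segments,
      means = segmentation$means,
      sw = FALSE
    )
  } else {
    d <- disjoint_intervals(segmentation)
    list(rows = d$atoms, means = d$means, sw = TRUE)
  }
}

#' Call aberrations from a segmentation
#'
#' Per region per sample: `+1` when the mean exceeds the effective threshold,
#' `-1` when it falls below its negative, else `0`. With noise adjustment the
#' threshold is `theta * noise_seg` per (region, sample); regions with fewer
#' than `min_bins` bins are removed entirely. For sample-wise segmentations
#' the regions are the atomic intervals of [disjoint_intervals].
#'
#' @param segmentation A `shared_segmentation` or `sample_segmentation_list`.
#' @param bm The [bin_matrix] the segmentation was computed on.
#' @param config A [calling_config].
#' @return An `aberration_matrix`: `regions` (chrom, bp start/end, bin span,
#'   label), `calls` in `{-1, 0, 1}` (regions x samples), `gain_freq`,
#'   `loss_freq`, plus the effective threshold matrix `theta_eff`.
#' @export
call_aberrations <- function(segmentation, bm, config = calling_config()) {
  cr <- calling_rows(segmentation, bm)
  noise_adjust <- config$noise_adjust
  if (is.na(noise_adjust)) noise_adjust <- cr$sw
  rows <- cr$rows
  means <- cr$means
  if (is.null(rows) || nrow(rows) == 0L) {
    return(empty_aberration_matrix(bm$samples))
  }
  theta_eff <- matrix(config$theta, nrow(rows), ncol(means))
  if (noise_adjust) {
    resid_sd <- matrix(NA_real_, nrow(rows), ncol(means))
    for (k in seq_len(nrow(rows))) {
      r <- rows$start_bin[k]:rows$end_bin[k]
      if (length(r) >= 2) {
        resid_sd[k, ] <- apply(
          bm$values[r, , drop = FALSE], 2,
          function(v) stats::sd(v - mean(v))
        )
      }
    }
    ref <- stats::median(resid_sd, na.rm = TRUE)
    factor <- resid_sd / ref
    factor[is.na(factor) | factor < 1] <- 1 # floor: never lower the threshold
    theta_eff <- config$theta * factor
  }
  calls <- threshold_calls(means, theta_eff, config$strict)
  keep <- rows$end_bin - rows$start_bin + 1L >= config$min_bins
  rows <- rows[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  theta_eff <- theta_eff[keep, , drop = FALSE]
  regions <- data.frame(
    chrom = rows$chrom,
    start = bm$bin_map$start[rows$start_bin],
    end = bm$bin_map$end[rows$end_bin],
    start_bin = rows$start_bin,
    end_bin = rows$end_bin,
    n_bins = rows$end_bin - rows$start_bin + 1L
  )
  regions$label <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  aberration_matrix(regions, calls, theta_eff = theta_eff)
}

empty_aberration_matrix <- function(samples) {
  aberration_matrix(
    data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      start_bin = integer(0), end_bin = integer(0), n_bins = integer(0),
      label = character(0)
    ),
    matrix(0L, 0, length(samples), dimnames = list(NULL, samples))
  )
}

#' Construct an aberration matrix container
#'
#' @param regions Data frame describing the rows (must carry a `label`
#'   column).
#' @param calls Integer matrix in `{-1, 0, 1}`, regions x samples.
#' @param theta_eff Optional effective-threshold matrix of the same shape.
#' @return An `aberration_matrix` with per-row gain and loss frequencies.
#' @export
aberration_matrix <- function(regions, calls, theta_eff = NULL) {
  stopifnot(nrow(regions) == nrow(calls))
  if (length(calls) && !all(calls %in% c(-1L, 0L, 1L))) {
    stop_fmt("calls must be in {-1, 0, 1}")
  }
  rownames(calls) <- regions$label
  structure(
    list(
      regions = regions,
      calls = calls,
      gain_freq = rowMeans(calls == 1L),
      loss_freq = rowMeans(calls == -1L),
      theta_eff = theta_eff
    ),
    class = "aberration_matrix"
  )
}

#' @export
print.aberration_matrix <- function(x, ...) {
  cat(sprintf(
    "aberration_matrix: %d region(s) x %d sample(s); %d gained, %d lost\n",
    nrow(x$calls), ncol(x$calls),
    sum(x$gain_freq > 0), sum(x$loss_freq > 0)
  ))
  invisible(x)
}

#' Atomic intervals of a sample-wise segmentation
#'
#' The atoms are the intervals between consecutive elements of the union of
#' all samples' breakpoints per chromosome; each sample's value on an atom is
#' its covering segment's mean. Atoms partition the genome.
#'
#' @param seg_list A `sample_segmentation_list`.
#' @return List with `atoms` (data frame `chrom`, `start_bin`, `end_bin`,
#'   `n_bins`) and `means` (atoms x samples).
#' @export
disjoint_intervals <- function(seg_list) {
  all_seg <- do.call(rbind, lapply(names(seg_list), function(s) {
    d <- seg_list[[s]]
    d$sample <- s
    d
  }))
  atoms <- list()
  for (ch in unique(all_seg$chrom)) {
    sub <- all_seg[all_seg$chrom == ch, ]
    cuts <- sort(unique(c(min(sub$start_bin) - 1L, sub$end_bin)))
    starts <- cuts[-length(cuts)] + 1L
    ends <- cuts[-1]
    atoms[[ch]] <- data.frame(
      chrom = ch, start_bin = starts, end_bin = ends,
      n_bins = ends - starts + 1L
    )
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  means <- matrix(
    NA_real_, nrow(atoms), length(seg_list),
    dimnames = list(NULL, names(seg_list))
  )
  for (s in seq_along(seg_list)) {
    seg <- seg_list[[s]]
    for (k in seq_len(nrow(seg))) {
      cover <- atoms$chrom == seg$chrom[k] &
        atoms$start_bin >= seg$start_bin[k] &
        atoms$end_bin <= seg$end_bin[k]
      means[cover, s] <- seg$mean[k]
    }
  }
  list(atoms = atoms, means = means)
}

# Map each bin to an arm label by its midpoint; NA when outside every arm.
bin_arms <- function(bin_map, arms) {
  mid <- (bin_map$start + bin_map$end) / 2
  lab <- rep(NA_character_, nrow(bin_map))
  for (k in seq_len(nrow(arms))) {
    sel <- as.character(bin_map$chrom) == as.character(arms$chrom[k]) &
      mid >= arms$start[k] & mid <= arms$end[k]
    lab[sel] <- paste0(arms$chrom[k], arms$arm[k])
  }
  lab
}

#' Length-weighted arm-level means
#'
#' Condenses a segmentation to chromosome arms: per sample per arm, the mean
#' of segment means weighted by the number of member bins falling in the arm.
#' Arms containing no bins are reported as `NA`.
#'
#' @param segmentation A `shared_segmentation` or `sample_segmentation_list`.
#' @param arms An [arm_table].
#' @param bm The [bin_matrix] the segmentation refers to.
#' @return Arms x samples numeric matrix with `"1p"`-style row names.
#' @export
arm_weighted_mean <- function(segmentation, arms, bm) {
  labels <- paste0(arms$chrom, arms$arm)
  arm_of_bin <- bin_arms(bm$bin_map, arms)
  if (inherits(segmentation, "shared_segmentation")) {
    seg_tab <- lapply(seq_along(segmentation$samples), function(s) {
      d <- segmentation$segments
      d$mean <- segmentation$means[, s]
      d
    })
    names(seg_tab) <- segmentation$samples
  } else {
    seg_tab <- segmentation
  }
  out <- matrix(
    NA_real_, length(labels), length(seg_tab),
    dimnames = list(labels, names(seg_tab))
  )
  for (s in seq_along(seg_tab)) {
    seg <- seg_tab[[s]]
    for (a in seq_along(labels)) {
      in_arm <- which(arm_of_bin == labels[a])
      if (!length(in_arm)) next
      num <- 0
      den <- 0
      for (k in seq_len(nrow(seg))) {
        len <- sum(in_arm >= seg$start_bin[k] & in_arm <= seg$end_bin[k])
        if (len) {
          num <- num + len * seg$mean[k]
          den <- den + len
        }
      }
      if (den > 0) out[a, s] <- num / den
    }
  }
  out
}

#' Threshold arm-level means into gain/loss calls
#'
#' Same threshold rule as [call_aberrations] but without the bin-count
#' filter and without noise adjustment; `NA` arms call 0.
#'
#' @param arm_means Arms x samples matrix from [arm_weighted_mean].
#' @param config A [calling_config].
#' @return An `aberration_matrix` whose regions are the arms.
#' @export
classify_arms <- function(arm_means, config = calling_config()) {
  m <- arm_means
  m[is.na(m)] <- 0
  calls <- threshold_calls(m, config$theta, config$strict)
  regions <- data.frame(
    chrom = sub("[pq]$", "", rownames(arm_means)),
    label = rownames(arm_means)
  )
  aberration_matrix(regions, calls)
}

#' Order samples by CNV-profile similarity
#'
#' Average-linkage agglomerative clustering on pairwise Hamming distance
#' (count of differing `{-1, 0, 1}` entries) between sample columns; the
#' dendrogram leaf order is returned. Columns are pre-sorted by sample ID so
#' ties resolve deterministically; an all-identical cohort keeps its input
#' order.
#'
#' @param abmat An [aberration_matrix].
#' @return Character vector of sample IDs in similarity order.
#' @export
order_by_similarity <- function(abmat) {
  calls <- abmat$calls
  ids <- colnames(calls)
  if (length(ids) <= 2L || nrow(calls) == 0L) return(ids)
  ord <- order(ids)
  calls <- calls[, ord, drop = FALSE]
  d <- matrix(0, ncol(calls), ncol(calls))
  for (a in seq_len(ncol(calls) - 1L)) {
    for (b in (a + 1L):ncol(calls)) {
      d[a, b] <- d[b, a] <- sum(calls[, a] != calls[, b])
    }
  }
  if (all(d == 0)) return(ids)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  colnames(calls)[hc$order]
}
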