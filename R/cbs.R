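# Sample-wise segmentation (SW mode): circular binary segmentation with a
# permutation significance test, plain or with inverse-variance bin weights.
# This is a self-contained CBS: no hybrid p-value approximation and no
# undo/prune passes.

#' Configuration for circular binary segmentation
#'
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Number of within-interval permutations (default 1000,
#'   minimum 100).
#' @param weighted Use inverse-variance bin weights (default FALSE).
#' @param seed Integer RNG seed recorded in the output; permutations are
#'   deterministic given the seed.
#' @param min_seg_bins Minimum bins per emitted segment (default 2).
#' @return A `cbs_config` list.
#' @export
cbs_config <- function(alpha = 0.01, n_perm = 1000, weighted = FALSE,
                       seed = 1L, min_seg_bins = 2L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100, min_seg_bins >= 1)
  structure(
    list(
      alpha = alpha, n_perm = as.integer(n_perm), weighted = weighted,
      seed = as.integer(seed), min_seg_bins = as.integer(min_seg_bins)
    ),
    class = "cbs_config"
  )
}

#' Arc-versus-complement test statistic
#'
#' The two-sample t-like statistic
#' `|mean_arc - mean_complement| / pooled SE` for the circular arc `i..j`
#' against the rest of the chromosome. With weights, group means are
#' weighted means and the residual sums of squares are weight-multiplied.
#' The pooled variance is floored at `eps` so noiseless steps yield a large
#' finite statistic.
#'
#' @param values Bin vector.
#' @param i,j Arc limits, `1 <= i <= j <= length(values)`.
#' @param weights Optional positive bin weights (unit weights when NULL).
#' @param eps Pooled-variance floor (default 1e-12).
#' @return The statistic; 0 when either side of the partition is empty.
#' @export
cbs_statistic <- function(values, i, j, weights = NULL, eps = 1e-12) {
  n <- length(values)
  stopifnot(i >= 1, j >= i, j <= n)
  arc <- seq(i, j)
  if (length(arc) == 0L || length(arc) == n) return(0)
  w <- weights %||% rep(1, n)
  m1 <- sum(w[arc] * values[arc]) / sum(w[arc])
  m2 <- sum(w[-arc] * values[-arc]) / sum(w[-arc])
  ss1 <- sum(w[arc] * (values[arc] - m1)^2)
  ss2 <- sum(w[-arc] * (values[-arc] - m2)^2)
  pooled <- max((ss1 + ss2) / max(n - 2, 1), eps)
  abs(m1 - m2) / sqrt(pooled * (1 / length(arc) + 1 / (n - length(arc))))
}

# Maximum arc statistic over all circular partitions of a (sub)interval.
# Contiguous arcs cover all circular partitions because arc and complement
# give the same statistic. Each partition piece must hold >= min_seg bins.
# Returns list(stat, i, j); stat = -Inf when no admissible arc exists.
max_arc_stat <- function(x, w, min_seg, eps = 1e-12) {
  n <- length(x)
  best <- list(stat = -Inf, i = NA_integer_, j = NA_integer_)
  if (n < 2 * min_seg) return(best)
  Pw <- psum(w)
  Pwv <- psum(w * x)
  Pwv2 <- psum(w * x^2)
  tw <- Pw[n + 1L]
  tv <- Pwv[n + 1L]
  tv2 <- Pwv2[n + 1L]
  for (k in min_seg:(n - min_seg)) {
    i <- seq_len(n - k + 1L)
    # arcs interior or flush with an end; pieces outside the arc are
    # [1..i-1] and [j+1..n]; each must be empty or >= min_seg
    left <- i - 1L
    right <- n - (i + k - 1L)
    ok <- (left == 0L | left >= min_seg) & (right == 0L | right >= min_seg)
    if (!any(ok)) next
    i <- i[ok]
    sw <- Pw[i + k] - Pw[i]
    sv <- Pwv[i + k] - Pwv[i]
    sv2 <- Pwv2[i + k] - Pwv2[i]
    m1 <- sv / sw
    m2 <- (tv - sv) / (tw - sw)
    ss1 <- sv2 - sv^2 / sw
    ss2 <- (tv2 - sv2) - (tv - sv)^2 / (tw - sw)
    pooled <- pmax((ss1 + ss2) / max(n - 2, 1), eps)
    stat <- abs(m1 - m2) / sqrt(pooled * (1 / k + 1 / (n - k)))
    top <- which.max(stat)
    if (stat[top] > best$stat) {
      best <- list(stat = stat[top], i = i[top], j = i[top] + k - 1L)
    }
  }
  best
}

# Permutation p-value with early stopping: once the exceedance count forces
# p > alpha the remaining permutations cannot change the split decision.
perm_significant <- function(x, w, obs, config) {
  limit <- floor(config$alpha * (config$n_perm + 1)) - 1 # max exceedances
  exceed <- 0L
  for (p in seq_len(config$n_perm)) {
    ord <- sample.int(length(x))
    mx <- max_arc_stat(x[ord], w[ord], config$min_seg_bins)
    if (mx$stat >= obs) {
      exceed <- exceed + 1L
      if (exceed > limit) return(FALSE)
    }
  }
  (1 + exceed) / (config$n_perm + 1) <= config$alpha
}

# Recursive CBS on one interval; returns segment end indices (relative).
cbs_recurse <- function(x, w, config) {
  n <- length(x)
  if (n < 2 * config$min_seg_bins) return(n)
  mx <- max_arc_stat(x, w, config$min_seg_bins)
  if (!is.finite(mx$stat) || mx$stat <= 0) return(n)
  if (!perm_significant(x, w, mx$stat, config)) return(n)
  cuts <- integer(0)
  pieces <- list()
  if (mx$i > 1L) pieces[[length(pieces) + 1L]] <- c(1L, mx$i - 1L)
  pieces[[length(pieces) + 1L]] <- c(mx$i, mx$j)
  if (mx$j < n) pieces[[length(pieces) + 1L]] <- c(mx$j + 1L, n)
  for (p in pieces) {
    sub <- cbs_recurse(x[p[1]:p[2]], w[p[1]:p[2]], config)
    cuts <- c(cuts, sub + p[1] - 1L)
  }
  sort(unique(cuts))
}

#' Segment one sample's chromosome by circular binary segmentation
#'
#' Finds the arc maximising [cbs_statistic], assesses it by permutation
#' (p-value `(1 + exceedances) / (n_perm + 1)`), and recurses on the arc and
#' its linearised complement pieces while splits stay significant at
#' `alpha`. Deterministic given `config$seed`.
#'
#' @param values Bin vector of one chromosome.
#' @param weights Optional positive bin weights (inverse-variance, see
#'   [weighted_bin_weights]).
#' @param config A [cbs_config].
#' @return Data frame of segments: `start_bin`, `end_bin`, `n_bins`, `mean`
#'   (weighted mean when weights are supplied).
#' @export
cbs_segment_sample <- function(values, weights = NULL, config = cbs_config()) {
  stopifnot(length(values) >= 1)
  w <- weights %||% rep(1, length(values))
  set.seed(config$seed)
  ends <- cbs_recurse(values, w, config)
  starts <- c(1L, ends[-length(ends)] + 1L)
  data.frame(
    start_bin = starts,
    end_bin = ends,
    n_bins = ends - starts + 1L,
    mean = vapply(seq_along(ends), function(k) {
      r <- starts[k]:ends[k]
      sum(w[r] * values[r]) / sum(w[r])
    }, 0)
  )
}

#' Inverse-variance bin weights
#'
#' `weight = 1 / (probe variance + eps)`, normalised to mean 1 per sample so
#' weighted and unweighted segmentation coincide when all variances are
#' equal.
#'
#' @param bm A [bin_matrix] carrying per-bin probe variances.
#' @param eps Variance floor guarding zero-variance bins (default 1e-8).
#' @return Bins x samples weight matrix.
#' @export
weighted_bin_weights <- function(bm, eps = 1e-8) {
  if (is.null(bm$var)) stop_fmt("bin matrix has no per-bin probe variances")
  w <- 1 / (bm$var + eps)
  sweep(w, 2, colMeans(w), "/")
}

#' Sample-wise segmentation of a whole cohort (SW mode)
#'
#' Applies [cbs_segment_sample] per sample per chromosome; every sample gets
#' independent boundaries. Per-call RNG seeds are derived deterministically
#' from `config$seed`.
#'
#' @param bm A [bin_matrix].
#' @param config A [cbs_config]; with `weighted = TRUE` the bin matrix must
#'   carry probe variances.
#' @return Named list (one per sample) of segment data frames with `chrom`,
#'   global `start_bin`/`end_bin`, `n_bins`, `mean`; class
#'   `sample_segmentation_list`.
#' @export
segment_cohort_sw <- function(bm, config = cbs_config()) {
  idx <- chrom_bin_index(bm$bin_map)
  weights <- if (config$weighted) weighted_bin_weights(bm) else NULL
  out <- vector("list", length(bm$samples))
  names(out) <- bm$samples
  for (s in seq_along(bm$samples)) {
    per_chrom <- list()
    for (ci in seq_along(idx)) {
      rows <- idx[[ci]]
      if (!length(rows)) next
      cfg <- config
      cfg$seed <- (config$seed + 7919L * s + ci) %% .Machine$integer.max
      seg <- cbs_segment_sample(
        bm$values[rows, s],
        if (is.null(weights)) NULL else weights[rows, s],
        cfg
      )
      seg$chrom <- names(idx)[ci]
      seg$start_bin <- seg$start_bin + rows[1] - 1L
      seg$end_bin <- seg$end_bin + rows[1] - 1L
      per_chrom[[ci]] <- seg[, c("chrom", "start_bin", "end_bin", "n_bins", "mean")]
    }
    out[[s]] <- do.call(rbind, per_chrom)
    rownames(out[[s]]) <- NULL
  }
  structure(out, class = "sample_segmentation_list", seed = config$seed)
}
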