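# Combined segmentation (CS mode): multi-sample penalised least-squares
# piecewise-constant fit with breakpoints shared across samples. An exact
# dynamic program provides the global optimum; two moving-difference
# high-pass filters supply a sparse candidate set for long chromosomes.

#' Configuration for the multi-sample piecewise-constant fit
#'
#' @param gamma Breakpoint penalty (> 0). Larger values give fewer, more
#'   conservative segments.
#' @param penalty_scale `"per_sample"` (default): effective penalty
#'   `gamma * n_samples * log(n_bins)` per breakpoint, a BIC-flavoured
#'   scaling that keeps `gamma` meaningful across cohort and chromosome
#'   sizes once residuals are standardised. `"per_cohort"`: the raw `gamma`
#'   per breakpoint, for direct control of the penalty.
#' @param standardize Divide each sample's residuals by its noise estimate
#'   `sigma_s` before costing, making `gamma` noise-scale free (default TRUE).
#' @param half_widths Half-widths of the two high-pass candidate filters
#'   (default `c(1, 5)`: sharp and low-amplitude steps).
#' @param candidate_threshold Minimum filter score for an interior boundary to
#'   become a candidate (default 1).
#' @param exact_threshold Chromosomes with at most this many bins skip the
#'   candidate heuristic and run the exact dynamic program (default 400).
#' @return A `pcf_config` list.
#' @export
pcf_config <- function(gamma = 1, penalty_scale = c("per_sample", "per_cohort"),
                       standardize = TRUE, half_widths = c(1, 5),
                       candidate_threshold = 1, exact_threshold = 400) {
  stopifnot(gamma > 0, all(half_widths >= 1))
  structure(
    list(
      gamma = gamma,
      penalty_scale = match.arg(penalty_scale),
      standardize = standardize,
      half_widths = as.integer(half_widths),
      candidate_threshold = candidate_threshold,
      exact_threshold = as.integer(exact_threshold)
    ),
    class = "pcf_config"
  )
}

#' Estimate per-sample bin-level noise
#'
#' The successive-difference median-absolute-deviation estimator
#' `median(|v[i+1] - v[i]|) / (0.6745 * sqrt(2))`, robust to piecewise-constant
#' signal because only the few bins at breakpoints contribute outlying
#' differences.
#'
#' @param values Numeric vector of one sample's bin log2 ratios (>= 2 bins).
#' @param eps Lower floor for the estimate (default 1e-8).
#' @return Noise standard deviation estimate `sigma_s`.
#' @export
per_sample_noise <- function(values, eps = 1e-8) {
  if (length(values) < 2) stop_fmt("need at least 2 bins to estimate noise")
  max(stats::median(abs(diff(values))) / (0.6745 * sqrt(2)), eps)
}

# Genome-wide sigma_s per sample: successive differences pooled within
# chromosomes (never across a chromosome boundary).
cohort_noise <- function(bm, eps = 1e-8) {
  idx <- chrom_bin_index(bm$bin_map)
  vapply(seq_along(bm$samples), function(s) {
    d <- unlist(lapply(idx, function(i) {
      if (length(i) >= 2) abs(diff(bm$values[i, s])) else numeric(0)
    }), use.names = FALSE)
    if (!length(d)) return(eps)
    max(stats::median(d) / (0.6745 * sqrt(2)), eps)
  }, 0)
}

#' Pooled within-segment cost of a bin range
#'
#' Sum over samples of the residual sum of squares about the per-sample
#' segment mean for bins `i..j`, with each sample's contribution divided by
#' `noise^2` when noise estimates are supplied.
#'
#' @param values Bins x samples matrix.
#' @param i,j First and last bin of the segment (`i <= j`).
#' @param noise Optional per-sample noise standard deviations for
#'   standardisation.
#' @return The pooled (standardised) SSE.
#' @export
segment_cost <- function(values, i, j, noise = NULL) {
  if (i > j) stop_fmt("segment_cost requires i <= j")
  values <- as.matrix(values)
  sub <- values[i:j, , drop = FALSE]
  sse <- colSums(sub^2) - colSums(sub)^2 / (j - i + 1)
  if (!is.null(noise)) sse <- sse / noise^2
  sum(sse)
}

# Dynamic program over an allowed set of segment-end boundaries.
# x: standardised bins x samples matrix; bounds: sorted candidate segment
# ends, always containing n; penalty: effective per-breakpoint penalty.
# Ties within 1e-12 break toward the earlier previous boundary, i.e. the
# fewer-breakpoint solution.
pcf_dp <- function(x, bounds, penalty) {
  n <- nrow(x)
  P <- psum_mat(x)
  Q <- psum_mat(x^2)
  b <- c(0L, bounds) # b[1] = 0 sentinel
  m <- length(bounds)
  C <- c(-penalty, rep(NA_real_, m))
  back <- integer(m)
  for (j in seq_len(m)) {
    ends <- b[j + 1L]
    prevs <- b[seq_len(j)] # candidate previous boundaries (0 .. b_j-1)
    len <- ends - prevs
    A <- matrix(P[ends + 1L, ], j, ncol(x), byrow = TRUE) -
      P[prevs + 1L, , drop = FALSE]
    B <- matrix(Q[ends + 1L, ], j, ncol(x), byrow = TRUE) -
      Q[prevs + 1L, , drop = FALSE]
    sse <- rowSums(B) - rowSums(A^2) / len
    tot <- C[seq_len(j)] + sse + penalty
    best <- min(tot)
    k <- which(tot <= best + 1e-12)[1L]
    C[j + 1L] <- tot[k]
    back[j] <- k
  }
  # backtrack
  ends <- integer(0)
  j <- m
  while (j > 0L) {
    ends <- c(b[j + 1L], ends)
    j <- back[j] - 1L
  }
  starts <- c(1L, ends[-length(ends)] + 1L)
  means <- t(vapply(
    seq_along(ends),
    function(k) (P[ends[k] + 1L, ] - P[starts[k], ]) / (ends[k] - starts[k] + 1L),
    numeric(ncol(x))
  ))
  list(
    starts = starts, ends = ends, means = means,
    cost = C[m + 1L], breakpoints = ends[-length(ends)]
  )
}

prep_pcf <- function(values, config, noise) {
  values <- as.matrix(values)
  S <- ncol(values)
  if (config$standardize) {
    if (is.null(noise)) {
      noise <- if (nrow(values) >= 2) {
        apply(values, 2, per_sample_noise)
      } else {
        rep(1, S)
      }
    }
    values <- sweep(values, 2, noise, "/")
  }
  # Per-sample scaling: gamma * S * log(n). Splitting pure standardised
  # noise at any fixed position reduces the cost by chi-square(1) per sample
  # (mean S in total), so a penalty proportional to S alone sits at the
  # noise floor; the log(n) factor (BIC-flavoured, n = bins tested) lifts
  # the penalty above the max over candidate positions and keeps gamma in
  # the 0.5-5 range meaningful from sensitive to conservative.
  penalty <- if (config$penalty_scale == "per_sample") {
    config$gamma * S * log(max(nrow(values), 2))
  } else {
    config$gamma
  }
  list(x = values, penalty = penalty, noise = noise)
}

finish_pcf <- function(values, dp, config) {
  structure(
    list(
      segments = data.frame(
        start_bin = dp$starts, end_bin = dp$ends,
        n_bins = dp$ends - dp$starts + 1L
      ),
      # means reported on the original (unstandardised) scale
      means = t(vapply(
        seq_along(dp$starts),
        function(k) colMeans(values[dp$starts[k]:dp$ends[k], , drop = FALSE]),
        numeric(ncol(values))
      )),
      breakpoints = dp$breakpoints,
      cost = dp$cost,
      gamma = config$gamma
    ),
    class = "pcf_fit"
  )
}

#' Exact multi-sample piecewise-constant fit of one chromosome
#'
#' Minimises `sum_s SSE_s / sigma_s^2 + penalty * n_breakpoints` over all
#' breakpoint sets by dynamic programming; the first segment carries no
#' penalty. Cost ties within 1e-12 are broken toward fewer breakpoints.
#'
#' @param values Bins x samples matrix for one chromosome.
#' @param config A [pcf_config].
#' @param noise Optional per-sample noise SDs (estimated from `values`
#'   when omitted and standardisation is on).
#' @return A `pcf_fit`: segments (`start_bin`, `end_bin`, `n_bins`),
#'   per-sample segment `means`, interior `breakpoints` (segment-end bin
#'   indices), and the penalised `cost` in standardised units.
#' @export
pcf_exact <- function(values, config = pcf_config(), noise = NULL) {
  p <- prep_pcf(values, config, noise)
  dp <- pcf_dp(p$x, seq_len(nrow(p$x)), p$penalty)
  finish_pcf(as.matrix(values), dp, config)
}

#' High-pass-filter breakpoint candidates
#'
#' For each half-width `w` the score of interior boundary `b` is
#' `sum_s |mean(bins b-w+1..b) - mean(bins b+1..b+w)| / sigma_s` (windows
#' truncated at chromosome ends). A boundary is a candidate when it is a local
#' maximum of the score for either filter and its score exceeds the
#' configured threshold.
#'
#' @inheritParams pcf_exact
#' @return Sorted integer vector of candidate interior boundaries (bin index
#'   of the last bin left of the cut).
#' @export
candidate_breakpoints <- function(values, config = pcf_config(), noise = NULL) {
  p <- prep_pcf(values, config, noise)
  x <- p$x
  n <- nrow(x)
  if (n < 2) return(integer(0))
  P <- psum_mat(x)
  cand <- logical(n - 1L)
  for (w in config$half_widths) {
    b <- seq_len(n - 1L)
    lo <- pmax(b - w + 1L, 1L)
    hi <- pmin(b + w, n)
    lmean <- (P[b + 1L, , drop = FALSE] - P[lo, , drop = FALSE]) / (b - lo + 1L)
    rmean <- (P[hi + 1L, , drop = FALSE] - P[b + 1L, , drop = FALSE]) / (hi - b)
    score <- rowSums(abs(lmean - rmean))
    up <- c(TRUE, diff(score) >= 0)
    down <- c(diff(score) <= 0, TRUE)
    cand <- cand | (up & down & score > config$candidate_threshold)
  }
  which(cand)
}

#' Fast multi-sample piecewise-constant fit of one chromosome
#'
#' Runs the exact dynamic program restricted to the high-pass-filter candidate
#' boundaries. Chromosomes with at most `exact_threshold` bins bypass the
#' heuristic entirely, so small inputs are always solved exactly; on larger
#' inputs the returned cost is an upper bound on the exact optimum.
#'
#' @inheritParams pcf_exact
#' @return A `pcf_fit` (see [pcf_exact]).
#' @export
pcf_fast <- function(values, config = pcf_config(), noise = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n <= config$exact_threshold) {
    return(pcf_exact(values, config, noise))
  }
  p <- prep_pcf(values, config, noise)
  cand <- candidate_breakpoints(values, config, noise)
  bounds <- sort(unique(c(cand, n)))
  dp <- pcf_dp(p$x, bounds, p$penalty)
  finish_pcf(values, dp, config)
}

#' Combined segmentation of a whole cohort (CS mode)
#'
#' Applies the shared-breakpoint piecewise-constant fit chromosome by
#' chromosome, so no segment ever crosses a chromosome boundary. Per-sample
#' noise is estimated genome-wide (successive differences pooled within
#' chromosomes) and reused for every chromosome.
#'
#' @param bm A [bin_matrix].
#' @param config A [pcf_config].
#' @return A `shared_segmentation`: `segments` data frame (`chrom`,
#'   `start_bin`, `end_bin` as global bin indices, `n_bins`), per-sample
#'   segment `means` (segments x samples), per-chromosome `breakpoints`,
#'   total penalised `cost`, `samples`, and the `config` used.
#' @export
segment_genome_cs <- function(bm, config = pcf_config()) {
  idx <- chrom_bin_index(bm$bin_map)
  noise <- if (config$standardize) cohort_noise(bm) else NULL
  seg_rows <- list()
  means <- list()
  bkpts <- list()
  total_cost <- 0
  for (ch in names(idx)) {
    rows <- idx[[ch]]
    if (!length(rows)) {
      warn_fmt("chromosome %s has no bins; skipped", ch)
      next
    }
    fit <- pcf_fast(bm$values[rows, , drop = FALSE], config, noise)
    off <- rows[1] - 1L
    seg_rows[[ch]] <- data.frame(
      chrom = ch,
      start_bin = fit$segments$start_bin + off,
      end_bin = fit$segments$end_bin + off,
      n_bins = fit$segments$n_bins
    )
    means[[ch]] <- fit$means
    bkpts[[ch]] <- fit$breakpoints + off
    total_cost <- total_cost + fit$cost
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  structure(
    list(
      segments = segments,
      means = do.call(rbind, means),
      breakpoints = bkpts,
      cost = total_cost,
      samples = bm$samples,
      config = config,
      noise = noise
    ),
    class = "shared_segmentation"
  )
}

#' @export
print.shared_segmentation <- function(x, ...) {
  cat(sprintf(
    "shared_segmentation: %d segment(s) x %d sample(s), gamma = %g\n",
    nrow(x$segments), length(x$samples), x$config$gamma
  ))
  invisible(x)
}
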