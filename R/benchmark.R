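# Monte Carlo focal-aberration benchmark: draw a focal event (location,
# frequency, strength), inject it into a cohort, segment, and score whether
# the injected span is recovered; plus CS-vs-SW arm-level concordance.

#' Draw a focal aberration specification
#'
#' Uniformly samples an anchor region (a gene's probes when the annotation
#' carries genes, otherwise a single bin), a frequency from
#' `{0.2, 0.4, 0.6, 0.8, 1}` and a strength from `{0.5, 1, 1.5, 2}`, pads
#' the region by `pad_bins` on each side, and widens it to at least
#' `min_bins` bins (shifted inward when it would overrun the chromosome).
#' The affected samples are a uniform subset of size
#' `round(frequency * n_samples)`.
#'
#' @param bin_map A [build_bin_map] / [synth_bin_map] result.
#' @param n_samples Cohort size.
#' @param seed Optional RNG seed (uses the current RNG stream when NULL).
#' @param frequencies,strengths The candidate sets.
#' @param pad_bins Padding per side (default 3).
#' @param min_bins Minimum padded span (default 7).
#' @param probes Optional [probe_table] with gene annotation for gene-anchored
#'   draws.
#' @return A `focal_sim_spec`: `chrom`, global `start_bin`/`end_bin`,
#'   `frequency`, `strength`, `affected` (sample indices).
#' @export
draw_focal_spec <- function(bin_map, n_samples, seed = NULL,
                            frequencies = c(0.2, 0.4, 0.6, 0.8, 1),
                            strengths = c(0.5, 1, 1.5, 2),
                            pad_bins = 3L, min_bins = 7L, probes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- if (!is.null(probes)) unique(probes$gene[!is.na(probes$gene)]) else NULL
  if (length(genes)) {
    g <- sample(genes, 1)
    probe_bin <- rep(NA_integer_, nrow(probes))
    names(probe_bin) <- probes$probe_id
    for (b in seq_len(nrow(bin_map))) {
      probe_bin[bin_map$probe_ids[[b]]] <- bin_map$bin_id[b]
    }
    bins <- probe_bin[probes$probe_id[probes$gene %in% g]]
    bins <- bins[!is.na(bins)]
    anchor <- c(min(bins), max(bins))
  } else {
    b <- sample.int(nrow(bin_map), 1)
    anchor <- c(b, b)
  }
  chrom <- as.character(bin_map$chrom[anchor[1]])
  rows <- which(as.character(bin_map$chrom) == chrom)
  lo <- anchor[1] - pad_bins
  hi <- anchor[2] + pad_bins
  short <- min_bins - (hi - lo + 1L)
  if (short > 0L) {
    lo <- lo - ceiling(short / 2)
    hi <- hi + floor(short / 2)
  }
  if (hi - lo + 1L > length(rows)) {
    stop_fmt("padded region longer than chromosome %s", chrom)
  }
  if (lo < rows[1]) {
    hi <- hi + (rows[1] - lo)
    lo <- rows[1]
  }
  if (hi > rows[length(rows)]) {
    lo <- lo - (hi - rows[length(rows)])
    hi <- rows[length(rows)]
  }
  frequency <- frequencies[sample.int(length(frequencies), 1)]
  strength <- strengths[sample.int(length(strengths), 1)]
  n_aff <- round(frequency * n_samples)
  affected <- if (n_aff >= n_samples) seq_len(n_samples) else sample.int(n_samples, n_aff)
  structure(
    list(
      chrom = chrom, start_bin = as.integer(lo), end_bin = as.integer(hi),
      frequency = frequency, strength = strength,
      affected = sort(affected)
    ),
    class = "focal_sim_spec"
  )
}

#' Inject a focal aberration into a bin matrix
#'
#' Adds the spec's strength to the spec's bin span for the affected samples;
#' all other entries are untouched.
#'
#' @param bm A [bin_matrix].
#' @param spec A `focal_sim_spec`.
#' @return The modified [bin_matrix].
#' @export
inject_aberration <- function(bm, spec) {
  rows <- spec$start_bin:spec$end_bin
  if (length(unique(as.character(bm$bin_map$chrom[rows]))) != 1L) {
    stop_fmt("injected span crosses a chromosome boundary")
  }
  bm$values[rows, spec$affected] <- bm$values[rows, spec$affected] + spec$strength
  bm
}

#' Score detection of an injected aberration
#'
#' The aberration counts as found when the segmentation contains a segment
#' whose start and end both match the injected span within `boundary_tol`
#' bins, regardless of how many samples exceed the calling threshold on it.
#' The observed frequency is the fraction of samples whose mean on the
#' matched segment exceeds `theta` (NA when not found). False positives are
#' the called aberration rows (already min-bin filtered) disjoint from the
#' injected span, with their maximum gain/loss exceedance frequency.
#'
#' @param segmentation A `shared_segmentation` of the injected matrix.
#' @param calls The [call_aberrations] result on the same segmentation, or
#'   NULL to skip the false-positive audit.
#' @param spec The injected `focal_sim_spec`.
#' @param theta Calling threshold for the observed frequency (default 0.2).
#' @param boundary_tol Allowed boundary slack in bins (default 0: exact).
#' @return A `sim_result`: `found`, `observed_frequency`, `false_positives`
#'   data frame (`label`, `frequency`), and the `spec`.
#' @export
score_detection <- function(segmentation, calls, spec, theta = 0.2,
                            boundary_tol = 0L) {
  seg <- segmentation$segments
  hit <- which(
    abs(seg$start_bin - spec$start_bin) <= boundary_tol &
      abs(seg$end_bin - spec$end_bin) <= boundary_tol
  )
  found <- length(hit) > 0L
  observed <- NA_real_
  if (found) {
    observed <- mean(segmentation$means[hit[1], ] > theta)
  }
  fp <- data.frame(label = character(0), frequency = numeric(0))
  if (!is.null(calls) && nrow(calls$regions)) {
    disjoint <- calls$regions$end_bin < spec$start_bin |
      calls$regions$start_bin > spec$end_bin
    freq <- pmax(calls$gain_freq, calls$loss_freq)
    sel <- disjoint & freq > 0
    fp <- data.frame(
      label = calls$regions$label[sel], frequency = freq[sel]
    )
  }
  structure(
    list(
      found = found, observed_frequency = observed,
      false_positives = fp, spec = spec
    ),
    class = "sim_result"
  )
}

#' Monte Carlo focal-aberration benchmark
#'
#' Per iteration: generate a cohort, draw a focal spec, inject it, run the
#' combined segmentation at each `gamma`, call aberrations, and score
#' detection. Fully reproducible given `seed`.
#'
#' @param n_iter Number of iterations.
#' @param cohort_fn Function `(seed) -> list(bin_matrix = ...)` producing a
#'   cohort (e.g. a [synth_bin_cohort] wrapper).
#' @param gammas Penalty values to test.
#' @param pcf_cfg Template [pcf_config]; its `gamma` is overridden per run.
#' @param calling_cfg A [calling_config] (noise adjustment off for the
#'   combined fit unless set explicitly).
#' @param seed Top-level seed; per-iteration seeds are derived from it.
#' @param boundary_tol Passed to [score_detection].
#' @return List with `results` (one row per iteration x gamma: `gamma`,
#'   `iter`, `frequency`, `strength`, `found`, `observed_frequency`,
#'   `n_false_positive`), `summary` (per gamma: `n`, `detected`,
#'   `detection_rate`, `false_positive_count`), and `by_stratum`
#'   (gamma x strength x frequency detection rates).
#' @export
run_monte_carlo <- function(n_iter, cohort_fn, gammas = c(0.5, 1),
                            pcf_cfg = pcf_config(),
                            calling_cfg = calling_config(noise_adjust = FALSE),
                            seed = 1L, boundary_tol = 0L) {
  rows <- vector("list", n_iter * length(gammas))
  k <- 0L
  for (it in seq_len(n_iter)) {
    iter_seed <- (seed + 104729L * it) %% .Machine$integer.max
    cohort <- cohort_fn(iter_seed)
    bm <- cohort$bin_matrix
    spec <- draw_focal_spec(bm$bin_map, length(bm$samples),
      seed = iter_seed + 1L
    )
    injected <- inject_aberration(bm, spec)
    for (g in gammas) {
      cfg <- pcf_cfg
      cfg$gamma <- g
      segm <- segment_genome_cs(injected, cfg)
      calls <- call_aberrations(segm, injected, calling_cfg)
      res <- score_detection(segm, calls, spec,
        theta = calling_cfg$theta, boundary_tol = boundary_tol
      )
      k <- k + 1L
      rows[[k]] <- data.frame(
        gamma = g, iter = it,
        frequency = spec$frequency, strength = spec$strength,
        found = res$found,
        observed_frequency = res$observed_frequency,
        n_false_positive = nrow(res$false_positives)
      )
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$gamma), function(d) {
    data.frame(
      gamma = d$gamma[1], n = nrow(d), detected = sum(d$found),
      detection_rate = mean(d$found),
      false_positive_count = sum(d$n_false_positive)
    )
  }))
  rownames(summary) <- NULL
  by_stratum <- stats::aggregate(
    found ~ gamma + strength + frequency, results,
    function(f) mean(f)
  )
  names(by_stratum)[names(by_stratum) == "found"] <- "detection_rate"
  list(results = results, summary = summary, by_stratum = by_stratum)
}

#' CS-versus-SW arm-level concordance
#'
#' Per sample: the Pearson correlation between the arm-level length-weighted
#' means of the combined and the sample-wise segmentation. Samples whose arm
#' vector has zero variance in either mode are reported NA.
#'
#' @param cs A `shared_segmentation`.
#' @param sw A `sample_segmentation_list` on the same cohort.
#' @param arms An [arm_table].
#' @param bm The shared [bin_matrix].
#' @return Named numeric vector of per-sample correlations.
#' @export
mode_concordance <- function(cs, sw, arms, bm) {
  a_cs <- arm_weighted_mean(cs, arms, bm)
  a_sw <- arm_weighted_mean(sw, arms, bm)
  r <- vapply(seq_len(ncol(a_cs)), function(s) {
    x <- a_cs[, s]
    y <- a_sw[, s]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])
  }, 0, USE.NAMES = FALSE)
  names(r) <- colnames(a_cs)
  r
}
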