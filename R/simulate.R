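# Synthetic cohorts with known ground truth: bin-level Gaussian cohorts with
# injected broad and focal events, and probe-level lognormal cohorts whose
# normalisation + binning chain recovers the bin-level truth.

#' Specify a synthetic cohort
#'
#' @param n_samples Number of query samples (default 60).
#' @param chrom_bins Named integer vector: bins per chromosome
#'   (default 4 chromosomes of 500 bins).
#' @param bin_size Bin width in bp (default 50000).
#' @param noise_sd Bin-level Gaussian noise SD (default 0.1, a typical
#'   bin-level log2-ratio dispersion for good-quality arrays).
#' @param sample_noise_mult Optional per-sample noise multipliers.
#' @param broad_events List of broad events, each
#'   `list(chrom, start_bin, end_bin, strength, fraction)` with bin indices
#'   relative to the chromosome (`start_bin`/`end_bin` NULL for the whole
#'   chromosome).
#' @param focal_events List of `focal_sim_spec` objects (see
#'   [draw_focal_spec]).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 60,
                        chrom_bins = c("1" = 500, "2" = 500, "3" = 500, "4" = 500),
                        bin_size = 50000, noise_sd = 0.1,
                        sample_noise_mult = NULL,
                        broad_events = list(), focal_events = list(),
                        seed = 1L) {
  stopifnot(noise_sd > 0, n_samples >= 1, all(chrom_bins >= 1))
  structure(
    list(
      n_samples = as.integer(n_samples), chrom_bins = chrom_bins,
      bin_size = bin_size, noise_sd = noise_sd,
      sample_noise_mult = sample_noise_mult,
      broad_events = broad_events, focal_events = focal_events,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Bin map for a synthetic genome
#'
#' @param chrom_bins Named integer vector of bins per chromosome.
#' @param bin_size Bin width in bp.
#' @param n_probes Nominal probes per bin recorded in the map (default 15).
#' @return A `bin_map` with contiguous `bin_size` bins per chromosome.
#' @export
synth_bin_map <- function(chrom_bins, bin_size = 50000, n_probes = 15L) {
  chroms <- names(chrom_bins)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    k <- seq_len(chrom_bins[[ch]])
    data.frame(
      chrom = ch,
      start = (k - 1) * bin_size + 1,
      end = k * bin_size,
      n_probes = n_probes
    )
  }))
  out <- data.frame(bin_id = seq_len(nrow(out)), out)
  out$chrom <- factor(out$chrom, levels = chroms)
  out$probe_ids <- I(replicate(nrow(out), character(0), simplify = FALSE))
  class(out) <- c("bin_map", "data.frame")
  out
}

#' Arm table splitting each synthetic chromosome in half
#'
#' @param bin_map A [synth_bin_map] result.
#' @param split Fraction of the chromosome assigned to the p arm
#'   (default 0.5).
#' @return An [arm_table].
#' @export
synth_arm_table <- function(bin_map, split = 0.5) {
  chroms <- unique(as.character(bin_map$chrom))
  rows <- do.call(rbind, lapply(chroms, function(ch) {
    len <- max(bin_map$end[as.character(bin_map$chrom) == ch])
    cut <- round(len * split)
    data.frame(
      chrom = ch, arm = c("p", "q"),
      start = c(1, cut + 1), end = c(cut, len)
    )
  }))
  arm_table(rows, genome_layout = chroms)
}

# Global bin index range of an event given relative coordinates.
event_bins <- function(bin_map, chrom, start_bin, end_bin) {
  rows <- which(as.character(bin_map$chrom) == as.character(chrom))
  if (!length(rows)) stop_fmt("event on unknown chromosome %s", chrom)
  s <- if (is.null(start_bin)) 1L else start_bin
  e <- if (is.null(end_bin)) length(rows) else end_bin
  if (s < 1 || e > length(rows)) stop_fmt("event span outside chromosome %s", chrom)
  rows[s]:rows[e]
}

#' Simulate a bin-level cohort with known ground truth
#'
#' Values are i.i.d. Gaussian noise (`noise_sd`, optionally scaled per
#' sample) plus the strengths of the injected broad and focal events for
#' their affected samples. The truth table lists every event's global bin
#' span, strength, and affected sample IDs.
#'
#' @param spec A [cohort_spec].
#' @return List with `bin_matrix` (a [bin_matrix]; `var` set to the constant
#'   noise variance) and `truth` (data frame `chrom`, `start_bin`, `end_bin`,
#'   `strength`, `n_affected`, `affected` (comma-joined IDs)).
#' @export
synth_bin_cohort <- function(spec) {
  set.seed(spec$seed)
  bm_map <- synth_bin_map(spec$chrom_bins, spec$bin_size)
  nb <- nrow(bm_map)
  S <- spec$n_samples
  mult <- spec$sample_noise_mult %||% rep(1, S)
  values <- matrix(stats::rnorm(nb * S, 0, spec$noise_sd), nb, S)
  values <- sweep(values, 2, mult, "*")
  samples <- sprintf("S%03d", seq_len(S))
  colnames(values) <- samples
  truth <- list()
  add_event <- function(rows, strength, affected) {
    values[rows, affected] <<- values[rows, affected] + strength
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = as.character(bm_map$chrom[rows[1]]),
      start_bin = rows[1], end_bin = rows[length(rows)],
      strength = strength, n_affected = length(affected),
      affected = paste(samples[affected], collapse = ",")
    )
  }
  for (ev in spec$broad_events) {
    rows <- event_bins(bm_map, ev$chrom, ev$start_bin %||% NULL, ev$end_bin %||% NULL)
    n_aff <- round((ev$fraction %||% 1) * S)
    affected <- if (n_aff >= S) seq_len(S) else sample.int(S, n_aff)
    add_event(rows, ev$strength, affected)
  }
  for (ev in spec$focal_events) {
    add_event(ev$start_bin:ev$end_bin, ev$strength, ev$affected)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    chrom = character(0), start_bin = integer(0), end_bin = integer(0),
    strength = numeric(0), n_affected = integer(0), affected = character(0)
  )
  vars <- matrix(spec$noise_sd^2, nb, S)
  list(
    bin_matrix = bin_matrix(values, bm_map, var = vars, samples = samples),
    truth = truth
  )
}

#' Simulate a probe-level intensity cohort
#'
#' Per-probe baseline intensities are lognormal and shared between query and
#' control samples; query samples multiply the baseline by `2^signal`, where
#' the signal is the bin-level event profile of the spec, plus multiplicative
#' lognormal measurement noise. Running normalisation and binning on the
#' output recovers the bin-level ground truth within tolerance.
#'
#' @param spec A [cohort_spec].
#' @param probes_per_bin Probes per 50-kb window (default 15).
#' @param n_controls Number of control samples (default 8).
#' @param probe_noise_sd SD of the multiplicative log-intensity noise
#'   (default 0.15; bin medians then carry noise well below `noise_sd`).
#' @return List with `query` and `controls` intensity matrices, `probes`
#'   (a [probe_table]), and `truth` as in [synth_bin_cohort].
#' @export
synth_probe_cohort <- function(spec, probes_per_bin = 15L, n_controls = 8L,
                               probe_noise_sd = 0.15) {
  set.seed(spec$seed)
  bm_map <- synth_bin_map(spec$chrom_bins, spec$bin_size)
  chroms <- names(spec$chrom_bins)
  probes <- do.call(rbind, lapply(chroms, function(ch) {
    nb <- spec$chrom_bins[[ch]]
    pos <- as.vector(vapply(seq_len(nb), function(k) {
      lo <- (k - 1) * spec$bin_size
      round(lo + spec$bin_size * (seq_len(probes_per_bin) - 0.5) / probes_per_bin)
    }, numeric(probes_per_bin)))
    data.frame(chrom = ch, pos = pos)
  }))
  probes$probe_id <- sprintf("cg%07d", seq_len(nrow(probes)))
  probes <- probe_table(probes, genome_layout = chroms)
  np <- nrow(probes)
  # bin-level signal per query sample, reusing the bin-cohort event logic
  signal_spec <- spec
  signal_spec$noise_sd <- 1e-6
  sim <- synth_bin_cohort(signal_spec)
  signal_bins <- sim$bin_matrix$values
  signal_bins[abs(signal_bins) < 1e-3] <- 0 # keep only injected strengths
  probe_bin <- rep(seq_len(nrow(bm_map)), each = probes_per_bin)
  base <- stats::rlnorm(np, meanlog = log(2000), sdlog = 0.4)
  noise <- function(n) exp(stats::rnorm(n, 0, probe_noise_sd))
  S <- spec$n_samples
  query <- vapply(seq_len(S), function(s) {
    base * 2^signal_bins[probe_bin, s] * noise(np)
  }, numeric(np))
  controls <- vapply(seq_len(n_controls), function(s) base * noise(np),
    numeric(np)
  )
  rownames(query) <- rownames(controls) <- probes$probe_id
  colnames(query) <- sprintf("S%03d", seq_len(S))
  colnames(controls) <- sprintf("C%03d", seq_len(n_controls))
  list(query = query, controls = controls, probes = probes, truth = sim$truth)
}
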