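test_that("focal specs are reproducible, padded, and sample the declared sets", {
  bmap <- synth_bin_map(c("1" = 100, "2" = 100))
  a <- draw_focal_spec(bmap, n_samples = 60, seed = 71)
  b <- draw_focal_spec(bmap, n_samples = 60, seed = 71)
  expect_identical(a, b)
  for (s in 1:30) {
    sp <- draw_focal_spec(bmap, n_samples = 60, seed = 100 + s)
    # single-bin anchor + 3-bin padding, floored at 7 bins
    expect_equal(sp$end_bin - sp$start_bin + 1L, 7L)
    expect_in(sp$frequency, c(0.2, 0.4, 0.6, 0.8, 1))
    expect_in(sp$strength, c(0.5, 1, 1.5, 2))
    expect_equal(length(sp$affected), round(sp$frequency * 60))
    # span stays within one chromosome
    rows <- which(as.character(bmap$chrom) == sp$chrom)
    expect_gte(sp$start_bin, rows[1])
    expect_lte(sp$end_bin, rows[length(rows)])
  }
  full <- draw_focal_spec(bmap, n_samples = 10, seed = 5, frequencies = 1)
  expect_equal(full$affected, 1:10)
})

test_that("gene-anchored spans widen by the 3-bin padding rule", {
  probes <- spaced_probes(12, 15)
  probes$gene[probes$pos > 150000 & probes$pos <= 400000] <- "BIGGENE" # 5 bins
  bmap <- build_bin_map(probes)
  sp <- draw_focal_spec(bmap, n_samples = 10, seed = 3, probes = probes)
  expect_equal(sp$end_bin - sp$start_bin + 1L, 5L + 2L * 3L)
})

test_that("injection adds the strength exactly where specified", {
  sim <- synth_bin_cohort(cohort_spec(n_samples = 6, chrom_bins = c("1" = 50), seed = 72))
  bm <- sim$bin_matrix
  sp <- structure(
    list(
      chrom = "1", start_bin = 10L, end_bin = 16L,
      frequency = 0.5, strength = 1.5, affected = c(1L, 3L, 5L)
    ),
    class = "focal_sim_spec"
  )
  inj <- inject_aberration(bm, sp)
  delta <- inj$values - bm$values
  expect_equal(sum(delta != 0), 7 * 3)
  expect_equal(unique(as.vector(delta[10:16, c(1, 3, 5)])), 1.5)
  # zero strength is the identity
  sp0 <- sp
  sp0$strength <- 0
  expect_equal(inject_aberration(bm, sp0)$values, bm$values)
})

test_that("detection scoring requires matching boundaries, not frequency", {
  sim <- synth_bin_cohort(cohort_spec(n_samples = 10, chrom_bins = c("1" = 80), seed = 73))
  bm <- sim$bin_matrix
  sp <- draw_focal_spec(bm$bin_map, 10, seed = 74, frequencies = 0.2, strengths = 2)
  inj <- inject_aberration(bm, sp)
  cs <- segment_genome_cs(inj, pcf_config(gamma = 1))
  calls <- call_aberrations(cs, inj, calling_config(noise_adjust = FALSE))
  res <- score_detection(cs, calls, sp)
  expect_true(res$found)
  # only the 2 affected samples exceed theta on the matched segment
  expect_equal(res$observed_frequency, 0.2)
  # no-breakpoint segmentation: not found
  flat <- segment_genome_cs(inj, pcf_config(gamma = 1e6))
  res0 <- score_detection(flat, NULL, sp)
  expect_false(res0$found)
  expect_true(is.na(res0$observed_frequency))
})

test_that("false-positive audit excludes the injected span and short calls", {
  bm <- quick_bin_matrix(matrix(0, 30, 2))
  regions <- data.frame(
    chrom = "1", start = c(1, 501), end = c(100, 700),
    start_bin = c(1L, 20L), end_bin = c(1L, 24L), n_bins = c(1L, 5L),
    label = c("one-bin", "far")
  )
  calls <- aberration_matrix(regions[2, ], rbind(c(1L, 0L)))
  sp <- structure(
    list(chrom = "1", start_bin = 5L, end_bin = 11L, strength = 1,
         frequency = 0.5, affected = 1L),
    class = "focal_sim_spec"
  )
  seg <- segment_genome_cs(bm, pcf_config(gamma = 1))
  res <- score_detection(seg, calls, sp)
  expect_equal(res$false_positives$label, "far")
  expect_equal(res$false_positives$frequency, 0.5)
})

test_that("a small Monte Carlo run is deterministic and monotone in gamma", {
  gen <- function(seed) {
    synth_bin_cohort(cohort_spec(
      n_samples = 12, chrom_bins = c("1" = 120, "2" = 120), seed = seed
    ))
  }
  mc1 <- run_monte_carlo(6, gen, gammas = c(0.5, 1, 1e5), seed = 8)
  mc2 <- run_monte_carlo(6, gen, gammas = c(0.5, 1, 1e5), seed = 8)
  expect_identical(mc1$results, mc2$results)
  rates <- mc1$summary$detection_rate[order(mc1$summary$gamma)]
  expect_true(all(diff(rates) <= 0)) # non-increasing in gamma
  expect_equal(rates[3], 0) # penalty dominance: no breakpoints at huge gamma
  expect_gte(rates[1], 5 / 6)
})

test_that("noiseless staircase cohorts are found below penalty dominance, missed above", {
  vals <- matrix(0, 60, 4)
  vals[21:27, ] <- 2
  bm <- quick_bin_matrix(vals)
  sp <- structure(
    list(chrom = "1", start_bin = 21L, end_bin = 27L, strength = 2,
         frequency = 1, affected = 1:4),
    class = "focal_sim_spec"
  )
  low <- segment_genome_cs(bm, pcf_config(gamma = 1, standardize = FALSE,
    penalty_scale = "per_cohort"
  ))
  expect_true(score_detection(low, NULL, sp)$found)
  # analytic bound: one-segment SSE vs 2 breakpoints
  sse1 <- segment_cost(vals, 1, 60)
  high <- segment_genome_cs(bm, pcf_config(gamma = sse1, standardize = FALSE,
    penalty_scale = "per_cohort"
  ))
  expect_false(score_detection(high, NULL, sp)$found)
})

test_that("mode concordance is 1 for identical segmentations and -1 when negated", {
  sim <- synth_bin_cohort(cohort_spec(
    n_samples = 3, chrom_bins = c("1" = 60), noise_sd = 0.05,
    broad_events = list(
      list(chrom = "1", start_bin = 1, end_bin = 30, strength = 0.8, fraction = 1)
    ),
    seed = 75
  ))
  bm <- sim$bin_matrix
  arms <- synth_arm_table(bm$bin_map)
  cs <- segment_genome_cs(bm, pcf_config(gamma = 1))
  sw_same <- lapply(seq_along(bm$samples), function(s) {
    d <- cs$segments
    d$mean <- cs$means[, s]
    d[, c("chrom", "start_bin", "end_bin", "n_bins", "mean")]
  })
  names(sw_same) <- bm$samples
  class(sw_same) <- "sample_segmentation_list"
  expect_equal(unname(mode_concordance(cs, sw_same, arms, bm)), rep(1, 3))
  sw_neg <- lapply(sw_same, function(d) {
    d$mean <- -d$mean
    d
  })
  class(sw_neg) <- "sample_segmentation_list"
  expect_equal(unname(mode_concordance(cs, sw_neg, arms, bm)), rep(-1, 3))
  # hand-computed 3-arm example via the direct Pearson formula
  a_cs <- rbind(c(0.4), c(0), c(-0.2))
  a_sw <- rbind(c(0.5), c(0.1), c(-0.1))
  r <- sum((a_cs - mean(a_cs)) * (a_sw - mean(a_sw))) /
    sqrt(sum((a_cs - mean(a_cs))^2) * sum((a_sw - mean(a_sw))^2))
  expect_equal(cor(a_cs[, 1], a_sw[, 1]), r, tolerance = 1e-12)
})

test_that("real CS and SW segmentations agree at the arm level on a clean cohort", {
  sim <- synth_bin_cohort(cohort_spec(
    n_samples = 4, chrom_bins = c("1" = 60, "2" = 60), noise_sd = 0.05,
    broad_events = list(
      list(chrom = "1", start_bin = 1, end_bin = 30, strength = -0.8, fraction = 1),
      list(chrom = "2", start_bin = 31, end_bin = 60, strength = 0.8, fraction = 1)
    ),
    seed = 76
  ))
  bm <- sim$bin_matrix
  arms <- synth_arm_table(bm$bin_map)
  cs <- segment_genome_cs(bm, pcf_config(gamma = 1))
  sw <- segment_cohort_sw(bm, cbs_config(n_perm = 200, seed = 6))
  r <- mode_concordance(cs, sw, arms, bm)
  expect_true(all(r > 0.99))
})
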