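# A tiny shared segmentation with controllable means for threshold tests.
fake_shared <- function(means, n_bins, bm) {
  ends <- cumsum(n_bins)
  starts <- c(1L, head(ends, -1) + 1L)
  structure(
    list(
      segments = data.frame(
        chrom = as.character(bm$bin_map$chrom[starts]),
        start_bin = starts, end_bin = ends, n_bins = n_bins
      ),
      means = means,
      breakpoints = list(),
      cost = 0,
      samples = colnames(means) %||% paste0("S", seq_len(ncol(means))),
      config = pcf_config()
    ),
    class = "shared_segmentation"
  )
}

test_that("threshold rule is strict and the min-bin filter removes short segments", {
  bm <- quick_bin_matrix(matrix(0, 10, 3))
  means <- rbind(c(0.25, -0.25, 0.1), c(3, 3, 3), c(0.2, -0.2, 0))
  seg <- fake_shared(means, c(5L, 1L, 4L), bm)
  calls <- call_aberrations(seg, bm, calling_config(theta = 0.2, noise_adjust = FALSE))
  # single-bin segment with mean +3 is filtered out entirely
  expect_equal(nrow(calls$calls), 2)
  # mean +0.25 -> +1, -0.25 -> -1, 0.1 -> 0
  expect_equal(unname(calls$calls[1, ]), c(1L, -1L, 0L))
  # mean exactly +/- 0.2 under strict comparison -> 0
  expect_equal(unname(calls$calls[2, ]), c(0L, 0L, 0L))
  # frequencies reproduce by recounting
  expect_equal(calls$gain_freq, rowMeans(calls$calls == 1))
  expect_equal(calls$loss_freq, rowMeans(calls$calls == -1))
})

test_that("noise factor multiplies the threshold and floors at one", {
  # residual sd equal to the reference -> factor 1
  expect_equal(segment_noise_factor(c(-1, 1), reference_noise = sd(c(-1, 1))), 1)
  # residual sd 1.5x the reference -> theta_CBS = 0.2 * 1.5
  v <- c(-1.5, 1.5)
  f <- segment_noise_factor(v, reference_noise = sd(c(-1, 1)))
  expect_equal(0.2 * f, 0.3)
  # quieter-than-reference segments never lower the threshold
  expect_equal(segment_noise_factor(c(-0.1, 0.1), reference_noise = 1), 1)
  # single-bin segment: factor 1
  expect_equal(segment_noise_factor(0.7, reference_noise = 1), 1)
})

test_that("noise adjustment raises thresholds only for noisy segments", {
  set.seed(51)
  vals <- matrix(rnorm(60 * 4, sd = 0.05), 60, 4)
  vals[31:60, ] <- vals[31:60, ] * 6 # noisy half
  vals[31:60, 1] <- vals[31:60, 1] + 0.25
  bm <- quick_bin_matrix(vals)
  seg <- fake_shared(
    rbind(rep(0, 4), c(0.25, 0, 0, 0)), c(30L, 30L), bm
  )
  off <- call_aberrations(seg, bm, calling_config(noise_adjust = FALSE))
  on <- call_aberrations(seg, bm, calling_config(noise_adjust = TRUE))
  # without adjustment the 0.25 mean on the noisy segment is a gain
  expect_equal(unname(off$calls[2, 1]), 1L)
  # the noisy segment's threshold is raised above 0.25 and the call drops
  expect_gt(on$theta_eff[2, 1], 0.25)
  expect_equal(unname(on$calls[2, 1]), 0L)
  # quiet segments keep theta unchanged (floor at 1)
  expect_equal(on$theta_eff[1, ], rep(0.2, 4))
})

test_that("atomic intervals are the union of per-sample breakpoints", {
  mk <- function(ends, means) {
    starts <- c(1L, head(ends, -1) + 1L)
    data.frame(
      chrom = "1", start_bin = starts, end_bin = ends,
      n_bins = ends - starts + 1L, mean = means
    )
  }
  segs <- structure(
    list(A = mk(c(10L, 30L), c(0, 1)), B = mk(c(20L, 30L), c(0.5, 2))),
    class = "sample_segmentation_list"
  )
  d <- disjoint_intervals(segs)
  expect_equal(d$atoms$start_bin, c(1L, 11L, 21L))
  expect_equal(d$atoms$end_bin, c(10L, 20L, 30L))
  expect_equal(unname(d$means[, "A"]), c(0, 1, 1))
  expect_equal(unname(d$means[, "B"]), c(0.5, 0.5, 2))
  # identical breakpoints: atoms are exactly the segments
  same <- structure(
    list(A = mk(c(10L, 30L), c(0, 1)), B = mk(c(10L, 30L), c(1, 0))),
    class = "sample_segmentation_list"
  )
  expect_equal(disjoint_intervals(same)$atoms$end_bin, c(10L, 30L))
  # one sample: atoms are its segments
  one <- structure(list(A = mk(c(10L, 30L), c(0, 1))), class = "sample_segmentation_list")
  expect_equal(disjoint_intervals(one)$atoms$end_bin, c(10L, 30L))
})

test_that("arm-level weighted means use bin-length weights within arms", {
  bm <- quick_bin_matrix(matrix(0, 40, 2))
  arms <- synth_arm_table(bm$bin_map) # p = bins 1..20, q = 21..40
  # one segment covering the p arm exactly: arm value = segment mean
  seg <- fake_shared(rbind(c(0.4, 0.4), c(0, 0)), c(20L, 20L), bm)
  am <- arm_weighted_mean(seg, arms, bm)
  expect_equal(unname(am["1p", ]), c(0.4, 0.4))
  expect_equal(unname(am["1q", ]), c(0, 0))
  # 10-bin 0.4 and 30-bin 0.0 segments -> genome-wide arm mix: p arm gets
  # 10 bins of 0.4 + 10 bins of 0 -> 0.2; q arm all 0
  seg <- fake_shared(rbind(c(0.4, 0.4), c(0, 0)), c(10L, 30L), bm)
  am <- arm_weighted_mean(seg, arms, bm)
  expect_equal(unname(am["1p", 1]), (10 * 0.4 + 10 * 0) / 20)
  # convexity: equal segment means collapse to that mean
  seg <- fake_shared(rbind(c(0.3, 0.3), c(0.3, 0.3)), c(15L, 25L), bm)
  expect_equal(unname(arm_weighted_mean(seg, arms, bm)["1q", ]), c(0.3, 0.3))
})

test_that("arm classification thresholds without the bin filter", {
  m <- rbind("1p" = c(0.1, -0.21), "1q" = c(0.25, NA))
  calls <- classify_arms(m, calling_config(theta = 0.2))
  expect_equal(unname(calls$calls[1, ]), c(0L, -1L))
  expect_equal(unname(calls$calls[2, ]), c(1L, 0L)) # NA arm -> 0
  expect_error(calling_config(theta = 0), "theta")
})

test_that("similarity ordering groups identical profiles and is deterministic", {
  regions <- data.frame(label = paste0("r", 1:4))
  calls <- cbind(
    A = c(1L, 1L, 0L, -1L), B = c(1L, 1L, 0L, -1L), C = c(-1L, -1L, 0L, 1L)
  )
  ab <- aberration_matrix(regions, calls)
  ord <- order_by_similarity(ab)
  expect_equal(abs(which(ord == "A") - which(ord == "B")), 1) # identical pair adjacent
  expect_true(ord[1] == "C" || ord[3] == "C") # outlier at an end
  # all-identical cohort keeps input order
  same <- aberration_matrix(regions, cbind(A = calls[, 1], B = calls[, 1], C = calls[, 1]))
  expect_equal(order_by_similarity(same), c("A", "B", "C"))
  # calls are equivariant under sample permutation
  perm <- aberration_matrix(regions, calls[, c("C", "A", "B")])
  expect_setequal(order_by_similarity(perm), c("A", "B", "C"))
  ordp <- order_by_similarity(perm)
  expect_equal(abs(which(ordp == "A") - which(ordp == "B")), 1)
})
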