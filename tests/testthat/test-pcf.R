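test_that("noise estimator matches the closed form and is consistent", {
  expect_error(per_sample_noise(1), "2 bins")
  # constant vector floors at epsilon
  expect_equal(per_sample_noise(rep(2, 10)), 1e-8)
  # alternating 0/1: median |diff| = 1
  v <- rep(c(0, 1), 10)
  expect_equal(per_sample_noise(v), 1 / (0.6745 * sqrt(2)), tolerance = 1e-12)
  # consistency on N(0,1)
  set.seed(31)
  expect_equal(per_sample_noise(rnorm(1e5)), 1, tolerance = 0.02)
})

test_that("segment cost matches hand arithmetic and is additive over samples", {
  expect_equal(segment_cost(cbind(c(5)), 1, 1), 0)
  expect_equal(segment_cost(cbind(c(1, 1, 5, 5)), 1, 4), 16)
  two <- cbind(c(1, 1, 5, 5), c(1, 1, 5, 5))
  expect_equal(segment_cost(two, 1, 4), 32)
  expect_error(segment_cost(two, 3, 2), "i <= j")
  # standardisation divides each sample's SSE by its noise variance
  expect_equal(segment_cost(two, 1, 4, noise = c(2, 2)), 32 / 4)
})

test_that("exact DP equals exhaustive enumeration on small random matrices", {
  set.seed(32)
  for (trial in 1:60) {
    n <- sample(2:10, 1)
    S <- sample(1:4, 1)
    x <- matrix(rnorm(n * S, sd = sample(c(0.5, 1, 2), 1)), n, S)
    gamma <- sample(c(0.3, 1, 3), 1)
    cfg <- pcf_config(gamma = gamma, penalty_scale = "per_cohort", standardize = FALSE)
    fit <- pcf_exact(x, cfg)
    oracle <- brute_force_pcf(x, gamma)
    expect_equal(fit$cost, oracle$cost, tolerance = 1e-9)
    expect_equal(fit$segments$end_bin, oracle$ends)
  }
})

test_that("DP recovers hand-traced and degenerate cases", {
  cfg <- pcf_config(gamma = 1, penalty_scale = "per_cohort", standardize = FALSE)
  # constant matrix: one segment at any gamma
  fit <- pcf_exact(matrix(3, 20, 2), cfg)
  expect_equal(nrow(fit$segments), 1)
  # step (1,1,1,5,5,5): breakpoint after bin 3, means 1 and 5, cost 0 + 1
  fit <- pcf_exact(cbind(c(1, 1, 1, 5, 5, 5)), cfg)
  expect_equal(fit$breakpoints, 3L)
  expect_equal(as.vector(fit$means), c(1, 5))
  expect_equal(fit$cost, 1)
  # penalty dominance: gamma at least the 1-segment SSE -> single segment
  x <- cbind(c(1, 1, 1, 5, 5, 5))
  big <- pcf_config(
    gamma = segment_cost(x, 1, 6) + 1,
    penalty_scale = "per_cohort", standardize = FALSE
  )
  expect_equal(nrow(pcf_exact(x, big)$segments), 1)
})

test_that("breakpoint count is non-increasing in gamma and cost reconstructs", {
  set.seed(33)
  x <- matrix(rnorm(120 * 3, sd = 0.1), 120, 3)
  x[41:60, 1:2] <- x[41:60, 1:2] + 0.8
  prev <- Inf
  for (g in c(0.25, 0.5, 1, 2, 5, 20)) {
    fit <- pcf_fast(x, pcf_config(gamma = g))
    k <- length(fit$breakpoints)
    expect_lte(k, prev)
    prev <- k
    # reconstruction: cost equals recomputed standardised SSE + penalty * K
    noise <- apply(x, 2, per_sample_noise)
    sse <- sum(vapply(seq_len(nrow(fit$segments)), function(i) {
      segment_cost(x, fit$segments$start_bin[i], fit$segments$end_bin[i], noise)
    }, 0))
    expect_equal(fit$cost, sse + (g * 3 * log(120)) * k, tolerance = 1e-9)
  }
})

test_that("high-pass candidates respond to steps and sparsify noise", {
  cfg <- pcf_config(gamma = 1)
  # noiseless step at bin 50 is always a candidate
  x <- cbind(c(rep(0, 50), rep(1, 50)))
  expect_true(50 %in% candidate_breakpoints(x, cfg))
  # constant matrix has no interior candidates
  expect_length(candidate_breakpoints(matrix(1, 50, 2), cfg), 0)
  # pure noise: candidates strictly fewer than boundaries, the restricted
  # DP never beats the exact one, and it agrees with the exact optimum in
  # almost every trial once the penalty clears the noise floor (gamma 1 on
  # a 3-sample cohort; gamma 2 in the marginal single-sample regime)
  set.seed(34)
  for (case in list(list(S = 3, gamma = 1), list(S = 1, gamma = 2))) {
    agree <- 0
    for (t in 1:100) {
      x <- matrix(rnorm(200 * case$S), 200, case$S)
      cand <- candidate_breakpoints(x, pcf_config(gamma = case$gamma))
      expect_lt(length(cand), 199)
      fast <- pcf_fast(x, pcf_config(gamma = case$gamma, exact_threshold = 1))
      exact <- pcf_exact(x, pcf_config(gamma = case$gamma))
      expect_gte(fast$cost, exact$cost - 1e-9)
      if (isTRUE(all.equal(fast$cost, exact$cost, tolerance = 1e-9))) {
        agree <- agree + 1
      }
    }
    expect_gte(agree, 95)
  }
})

test_that("fast PCF matches exact below the threshold and recovers staircases", {
  set.seed(35)
  x <- matrix(rnorm(30 * 5), 30, 5)
  cfg <- pcf_config(gamma = 1)
  expect_equal(pcf_fast(x, cfg), pcf_exact(x, cfg)) # below exact_threshold
  stair <- cbind(rep(c(0, 1, 2), each = 20)) # noiseless 3-level staircase
  fit <- pcf_fast(stair, pcf_config(gamma = 1, exact_threshold = 1))
  expect_equal(fit$breakpoints, c(20L, 40L))
})

test_that("genome segmentation never crosses chromosome boundaries and is shared", {
  # two constant chromosomes at different levels -> 2 segments, 0 breakpoints
  vals <- rbind(matrix(0, 40, 3), matrix(1, 40, 3))
  bm <- quick_bin_matrix(vals, chroms = c("1", "2"))
  cs <- segment_genome_cs(bm, pcf_config(gamma = 1))
  expect_equal(nrow(cs$segments), 2)
  expect_equal(unlist(cs$breakpoints, use.names = FALSE), integer(0))
  expect_equal(as.character(cs$segments$chrom), c("1", "2"))
  # an event spanning the chr1/chr2 junction is reported as 2 segments
  set.seed(36)
  vals <- matrix(rnorm(80 * 3, sd = 0.1), 80, 3)
  vals[31:50, ] <- vals[31:50, ] + 2
  bm <- quick_bin_matrix(vals, chroms = c("1", "2"))
  cs <- segment_genome_cs(bm, pcf_config(gamma = 1))
  expect_true(all(table(as.character(cs$segments$chrom)) >= 2))
  expect_false(any(cs$segments$start_bin <= 40 & cs$segments$end_bin > 40))
  # determinism across runs on a seeded cohort
  sim <- synth_bin_cohort(cohort_spec(n_samples = 8, chrom_bins = c("1" = 80), seed = 3))
  a <- segment_genome_cs(sim$bin_matrix, pcf_config(gamma = 1))
  b <- segment_genome_cs(sim$bin_matrix, pcf_config(gamma = 1))
  expect_identical(a$segments, b$segments)
})
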