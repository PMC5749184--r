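test_that("normalize_to_log2 follows the log2-ratio definition", {
  # flat counts: log2 ratio ~ 0 everywhere
  p <- normalize_to_log2(toy_counts(rep(100, 10)))
  expect_equal(p$log2_ratio, rep(0, 10))
  # counts [10 x9, 22]: mean 11.2, so log2 ratios follow directly;
  # a bin at exactly 2x the mean has log2 ratio 1
  p2 <- normalize_to_log2(toy_counts(c(rep(10, 9), 22)))
  expect_equal(p2$log2_ratio[10], log2(22 / 11.2))
  # counts [60 x9, 135]: mean 67.5, so the last bin sits at exactly 2x
  p2b <- normalize_to_log2(toy_counts(c(rep(60, 9), 135)))
  expect_equal(p2b$log2_ratio[10], 1)
  # zero bins masked
  p3 <- normalize_to_log2(toy_counts(c(0, 10, 10)))
  expect_true(is.na(p3$log2_ratio[1]))
  expect_equal(p3$log2_ratio[2], 0)
  expect_error(normalize_to_log2(toy_counts(c(0, 0))), "zero")
})

test_that("deep planted gain recovers log2(1.5)", {
  bins <- tile_genome(c(chr1 = 200e6), 1e6)
  cn <- rep(2L, 200); cn[101:150] <- 3L
  tr <- sim_truth(bins = bins, cn_profile = cn, bias_sigma = 0, seed = 31L)
  out <- simulate_wgs_bins(tr, mean_depth_per_bin = 2000, n_cells = 1)
  p <- normalize_to_log2(out$cells[[1]])
  # profile is mean-normalized, so compare the gain-vs-background contrast
  contrast <- mean(p$log2_ratio[101:150]) - mean(p$log2_ratio[c(1:100, 151:200)])
  expect_equal(contrast, log2(1.5), tolerance = 0.02)
})

test_that("cbs_segment handles the stated base cases", {
  bins <- tile_genome(c(chr1 = 100e6), 1e6)
  # constant input: one segment
  pc <- cbs_segment(cn_profile(bins, rep(0.3, 100)),
                    cbs_params(n_perm = 100, seed = 1))
  expect_equal(nrow(pc$segments), 1L)
  expect_equal(pc$segments$seg_mean, 0.3)

  # noiseless step: exactly 2 segments, boundary at bin 50, means 0 and 1
  ps <- cbs_segment(cn_profile(bins, c(rep(0, 50), rep(1, 50))),
                    cbs_params(n_perm = 200, seed = 2))
  expect_equal(nrow(ps$segments), 2L)
  expect_equal(ps$segments$end_bin[1], 50L)
  expect_equal(ps$segments$seg_mean, c(0, 1))

  # too few bins: single segment with warning
  short <- cn_profile(tile_genome(c(chr1 = 4e6), 1e6), c(0, 0, 1, 1))
  expect_warning(res <- cbs_segment(short, cbs_params(n_perm = 100)),
                 "single segment")
  expect_equal(nrow(res$segments), 1L)
})

test_that("first split matches the exhaustive oracle on small instances", {
  pairs_of <- function(n) scduoqc:::arc_pairs(n, 3L)
  set.seed(77)
  for (case in 1:25) {
    n <- sample(12:60, 1)
    y <- rnorm(n)
    if (case %% 2 == 0) y <- y + c(rep(0, n %/% 2), rep(1.5, n - n %/% 2))
    got <- scduoqc:::max_arc_stat(y, pairs_of(n))
    want <- oracle_best_split(y, 3L)
    expect_equal(got$stat, want$stat)
    expect_equal(canonical_cuts(got, n), canonical_cuts(want, n))
  }
})

test_that("noisy step boundary lands within one bin", {
  bins <- tile_genome(c(chr1 = 100e6), 1e6)
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.1)
    seg <- cbs_segment(cn_profile(bins, y),
                       cbs_params(n_perm = 150, seed = s))
    b <- seg$segments$end_bin
    hits <- hits + any(abs(b[-length(b)] - 50) <= 1)
  }
  expect_gte(hits, 38L)   # >= 95% of seeds
})

test_that("segment means reconstruct within-segment averages", {
  bins <- tile_genome(c(chr1 = 120e6), 1e6)
  set.seed(5)
  y <- c(rnorm(40, 0, .1), rnorm(40, 1, .1), rnorm(40, -.5, .1))
  y[c(10, 75)] <- NA   # masked bins
  seg <- cbs_segment(cn_profile(bins, y), cbs_params(n_perm = 150, seed = 5))
  for (k in seq_len(nrow(seg$segments))) {
    b <- seg$segments$start_bin[k]:seg$segments$end_bin[k]
    expect_equal(seg$segments$seg_mean[k], mean(y[b], na.rm = TRUE))
  }
  # segments partition all bins
  expect_equal(seg$segments$start_bin[1], 1L)
  expect_equal(seg$segments$end_bin[nrow(seg$segments)], 120L)
})

test_that("segmentation is equivariant to a constant shift", {
  bins <- tile_genome(c(chr1 = 100e6), 1e6)
  set.seed(13)
  y <- c(rnorm(60, 0, .1), rnorm(40, .8, .1))
  a <- cbs_segment(cn_profile(bins, y), cbs_params(n_perm = 150, seed = 4))
  b <- cbs_segment(cn_profile(bins, y + 2.5), cbs_params(n_perm = 150, seed = 4))
  expect_equal(a$segments[c("start_bin", "end_bin")],
               b$segments[c("start_bin", "end_bin")])
  expect_equal(b$segments$seg_mean, a$segments$seg_mean + 2.5)
})

test_that("profile_correlation behaves per contract", {
  bins <- tile_genome(c(chr1 = 50e6), 1e6)
  set.seed(3)
  y <- rnorm(50)
  a <- cn_profile(bins, y)
  expect_equal(profile_correlation(a, a), 1)
  expect_equal(profile_correlation(a, cn_profile(bins, -y)), -1)
  expect_warning(r <- profile_correlation(a, cn_profile(bins, rep(1, 50))),
                 "zero variance")
  expect_true(is.na(r))
  few <- cn_profile(bins, c(y[1:2], rep(NA, 48)))
  expect_warning(r2 <- profile_correlation(a, few), "fewer than 3")
  expect_true(is.na(r2))

  # two cells simulated from one truth at deep coverage: r > 0.9
  tr <- planted_truth(seed = 17L)
  cells <- simulate_wgs_bins(tr, 500, 2)$cells
  r3 <- profile_correlation(normalize_to_log2(cells[[1]]),
                            normalize_to_log2(cells[[2]]))
  expect_gt(r3, 0.9)
})

test_that("average_profiles means bins and honors NA", {
  bins <- tile_genome(c(chr1 = 3e6), 1e6)
  p1 <- cn_profile(bins, c(1, 2, NA))
  p2 <- cn_profile(bins, c(3, 4, 5))
  p3 <- cn_profile(bins, c(5, 6, 7))
  avg <- average_profiles(list(p1, p2, p3))
  expect_equal(avg$log2_ratio, c(3, 4, 6))   # NA bin: mean of remaining two
  expect_equal(average_profiles(list(p2))$log2_ratio, p2$log2_ratio)
  expect_equal(average_profiles(list(p2, cn_profile(bins, -c(3, 4, 5))))$log2_ratio,
               c(0, 0, 0))
  expect_error(average_profiles(list()), "empty")
})

test_that("cluster_profiles is Ward on Euclidean distance", {
  m <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
  cl <- cluster_profiles(m)
  expect_equal(cl$tree$height, 5)   # two singletons merge at their distance

  # identical pair merges first among three
  m3 <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  t3 <- cluster_profiles(m3)$tree
  expect_equal(sort(t3$merge[1, ]), c(-2, -1))
  expect_error(cluster_profiles(m3[1, , drop = FALSE]), ">= 2 samples")
})

test_that("three planted cell lines cluster perfectly", {
  bins <- tile_genome(c(chr1 = 120e6), 1e6)
  cns <- list(rep(2L, 120),
              c(rep(2L, 40), rep(4L, 40), rep(2L, 40)),
              c(rep(1L, 60), rep(2L, 60)))
  profiles <- list(); truth_lab <- integer(0)
  for (line in 1:3) {
    tr <- sim_truth(bins = bins, cn_profile = cns[[line]], bias_sigma = 0.1,
                    bias_rho = 0.3, seed = 100L + line)
    cells <- simulate_wgs_bins(tr, 300, 5)$cells
    profiles <- c(profiles, lapply(cells, normalize_to_log2))
    truth_lab <- c(truth_lab, rep(line, 5))
  }
  cl <- cluster_profiles(profiles, k = 3)
  expect_equal(adjusted_rand_index(cl$labels, truth_lab), 1)
})

test_that("seg output table is well formed", {
  bins <- tile_genome(c(chr1 = 100e6), 1e6)
  seg <- cbs_segment(cn_profile(bins, c(rep(0, 50), rep(1, 50)),
                                sample_id = "s1"),
                     cbs_params(n_perm = 150, seed = 6))
  p <- tempfile()
  write_seg(seg, p)
  tab <- read.delim(p)
  expect_equal(names(tab), c("sample", "chrom", "start", "end",
                             "n_bins", "seg_mean"))
  expect_equal(sum(tab$n_bins), 100)
})
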