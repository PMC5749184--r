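toy_expr <- function() {
  m <- matrix(c(5, 0, 2,
                0, 0, 1,
                3, 1, 0,
                0, 0, 0,
                1, 2, 4), 5, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  expr_matrix(m)
}

test_that("detect_genes counts per-cell detections", {
  em <- toy_expr()
  expect_equal(unname(detect_genes(em)), c(3, 2, 3))   # hand count
  z <- expr_matrix(matrix(0, 4, 2))
  expect_equal(unname(detect_genes(z)), c(0, 0))
  ones <- expr_matrix(matrix(1, 7, 2))
  expect_equal(unname(detect_genes(ones)), c(7, 7))
  expect_equal(unname(detect_genes(em, min_count = 3)), c(2, 0, 1))
})

test_that("subsample_saturation matches the analytic detection curve", {
  # probs [0.5, 0.3, 0.2], n = 5: E[detected] = sum(1 - (1-p)^5) = 2.473
  counts <- c(5000, 3000, 2000)
  analytic <- sum(1 - (1 - c(0.5, 0.3, 0.2))^5)
  expect_equal(analytic, 2.473, tolerance = 5e-4)
  sat <- subsample_saturation(counts, depths = 5, n_rep = 10000, seed = 2)
  expect_equal(sat$mean_detected, analytic, tolerance = 0.05)
})

test_that("saturation is nested-monotone and exact at full depth", {
  set.seed(4)
  counts <- rpois(200, 2)
  full <- sum(counts)
  sat <- subsample_saturation(counts, depths = c(full, 50, 10, 200),
                              n_rep = 20, seed = 9)
  det <- attr(sat, "detected")
  ord <- order(sat$depth)
  for (r in seq_len(ncol(det)))
    expect_true(all(diff(det[ord, r]) >= 0))   # per replicate
  expect_equal(sat$mean_detected[sat$depth == full], sum(counts >= 1))
  expect_error(subsample_saturation(counts, full + 1), "exceeds")
})

test_that("ensemble_pool sums shared gene vectors", {
  a <- c(g1 = 1, g2 = 0); b <- c(g1 = 2, g2 = 5)
  expect_equal(ensemble_pool(list(a)), a)
  expect_equal(ensemble_pool(list(a, b)), c(g1 = 3, g2 = 5))
  expect_error(ensemble_pool(list(a, c(g3 = 1, g2 = 1))), "mismatched")
  em <- toy_expr()
  pooled <- ensemble_pool(em)
  expect_equal(unname(pooled), unname(rowSums(em$values)))
  # pooling can only add detections
  expect_gte(sum(pooled >= 1), max(detect_genes(em)))
})

test_that("body_coverage ranks, averages and normalizes", {
  # uniform coverage: flat profile of 1 for every class
  cov <- matrix(1, 300, 101)
  expr <- seq_len(300)
  bc <- body_coverage(cov, expr, class_size = 100)
  expect_true(all(bc$coverage_ratio == 1))
  expect_equal(rownames(bc$coverage_ratio), c("top", "middle", "bottom"))

  # middle class of 3000 ranked transcripts = ranks 1001-2000
  expr2 <- 3000:1
  cov2 <- matrix(1, 3000, 101)
  cov2[1001:2000, 101] <- 5   # marker only in middle-ranked transcripts
  bc2 <- body_coverage(cov2, expr2)
  expect_equal(unname(bc2$coverage_ratio["middle", 101]), 1)  # marker = max
  expect_equal(unname(bc2$coverage_ratio["middle", 1]), 1 / 5)
  expect_true(all(bc2$coverage_ratio["top", ] == 1))

  # exponential 3' bias: strictly increasing toward the 3' end
  cov3 <- simulate_transcript_coverage(600, bias_strength = 3,
                                       noise_sd = 0.05, seed = 3)
  bc3 <- body_coverage(cov3, rexp(600), class_size = 200)
  for (cls in rownames(bc3$coverage_ratio)) {
    prof <- bc3$coverage_ratio[cls, ]
    expect_gt(stats::cor(prof, seq_along(prof), method = "spearman"), 0.99)
    expect_equal(max(prof), 1)
  }
  expect_error(body_coverage(cov, expr, class_size = 200), "class_size")
})

test_that("ercc_correlation is log-log Pearson with guards", {
  inp <- 2^(1:20)
  # proportional observed counts: r = 1 up to the +1 pseudocount
  expect_equal(ercc_correlation(1e4 * inp, inp), 1, tolerance = 1e-6)
  expect_true(is.na(ercc_correlation(c(1, 2), c(1, 2))))
  set.seed(6)
  r <- replicate(50, ercc_correlation(sample(inp, 92, replace = TRUE),
                                      sort(runif(92, 1, 2^20))))
  expect_lt(abs(mean(r)), 0.1)   # permutation-style null around 0
  # scale invariance of observed counts (log shift; exact as counts grow)
  obs <- (rpois(20, inp / 100) + 1) * 1e4
  expect_equal(ercc_correlation(obs * 7, inp), ercc_correlation(obs, inp),
               tolerance = 1e-4)
})

test_that("select_housekeeping_genes finds stable high expressers", {
  set.seed(10)
  G <- 200; C <- 20
  m <- matrix(rpois(G * C, 5), G, C,
              dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:C)))
  hk_true <- sprintf("g%03d", 1:8)
  m[hk_true, ] <- 500   # zero variance at high level
  em <- expr_matrix(m)
  expect_setequal(select_housekeeping_genes(em, k = 8), hk_true)

  # brute-force oracle: top decile by mean, then lowest CV, gene-id ties
  sel <- select_housekeeping_genes(em, k = 5, top_fraction = 0.2)
  mu <- rowMeans(m)
  top <- names(sort(mu, decreasing = TRUE))[1:(G * 0.2)]
  cv <- apply(m[top, ], 1, sd) / mu[top]
  oracle <- top[order(cv, top)][1:5]
  expect_equal(sel, oracle)

  # CV tie broken by gene id order
  m2 <- matrix(100, 20, 4, dimnames = list(sprintf("g%02d", 20:1), NULL))
  sel2 <- select_housekeeping_genes(expr_matrix(m2), k = 3, top_fraction = 1)
  expect_equal(sel2, c("g01", "g02", "g03"))
})

test_that("qc_filter_cells applies the housekeeping detection rule", {
  m <- matrix(0, 8, 3, dimnames = list(paste0("hk", 1:8), paste0("c", 1:3)))
  m[, 1] <- 5                      # all 8 detected
  m[1:6, 2] <- 1                   # 6 of 8
  em <- expr_matrix(m)
  hk <- paste0("hk", 1:8)
  expect_equal(unname(qc_filter_cells(em, hk)), c(TRUE, FALSE, FALSE))
  expect_equal(unname(qc_filter_cells(em, hk, min_detected_hk = 6)),
               c(TRUE, TRUE, FALSE))
  # monotone: adding counts never flips pass -> fail
  m3 <- m; m3[, 2] <- m3[, 2] + 1; m3[7:8, 2] <- 1
  expect_true(all(qc_filter_cells(em, hk) <=
                    qc_filter_cells(expr_matrix(m3), hk)))
  expect_error(qc_filter_cells(em, c("hk1", "nope")), "absent")
})

test_that("cell_cycle_stage assigns by argmax mean marker z-score", {
  set.seed(15)
  G <- 90; C <- 60
  genes <- sprintf("g%02d", 1:G)
  markers <- list(G1 = genes[1:30], S = genes[31:60], G2M = genes[61:90])
  truth_phase <- rep(c("G1", "S", "G2M"), each = 20)
  m <- matrix(rpois(G * C, 20), G, C, dimnames = list(genes, paste0("c", 1:C)))
  for (i in seq_len(C))   # planted signal ~2 z-units on the true phase
    m[markers[[truth_phase[i]]], i] <- rpois(30, 60)
  calls <- cell_cycle_stage(expr_matrix(m), markers)
  expect_gte(mean(calls$phase == truth_phase), 0.95)

  # symmetric cell is unassigned under the tie tolerance
  flat <- matrix(rep(c(10, 20), each = 45), G, 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  flat[, 2] <- flat[, 1]   # identical cells: all z = 0 within gene
  calls2 <- cell_cycle_stage(expr_matrix(cbind(m[, 1:2], flat[, 1:2])),
                             markers, tie_tol = 10)
  expect_true(all(calls2$phase == "unassigned"))   # huge tie_tol
  expect_error(cell_cycle_stage(toy_expr(), markers), "no marker genes")
})
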