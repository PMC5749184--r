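#' Genes detected per cell
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param min_count Detection threshold on the raw count (default 1).
#' @return Named integer vector, genes detected per cell.
#' @export
detect_genes <- function(matrix, min_count = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  colSums(matrix$values >= min_count)
}

#' log2 counts-per-million normalization
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @return Gene-by-cell matrix of `log2(CPM + 1)` values.
#' @export
log_cpm <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  tot <- colSums(v)
  tot[tot == 0] <- 1
  log2(sweep(v, 2L, tot, `/`) * 1e6 + 1)
}

#' Saturation of gene detection under subsampling
#'
#' Draws `depth` reads without replacement from one cell's count vector
#' (multivariate hypergeometric), repeats `n_rep` times per depth, and
#' reports the mean number of genes detected. Within a replicate, depths
#' are nested (each smaller depth is subsampled from the next larger
#' draw), so every replicate's curve is monotone non-decreasing in depth.
#'
#' @param cell_counts Non-negative integer vector of per-gene counts.
#' @param depths Vector of target read totals (each `<= sum(cell_counts)`).
#' @param n_rep Replicates per depth.
#' @param seed Integer seed.
#' @param min_count Detection threshold.
#' @return Data frame with `depth`, `mean_detected`, `sd_detected`; also
#'   carries the per-replicate detection matrix as attribute `detected`
#'   (depths in rows, replicates in columns).
#' @export
subsample_saturation <- function(cell_counts, depths, n_rep = 10L,
                                 seed = 1L, min_count = 1L) {
  tot <- sum(cell_counts)
  if (any(depths > tot)) stop("depth exceeds total count")
  cell_counts <- as.numeric(cell_counts)
  ord <- order(depths, decreasing = TRUE)
  set.seed(seed)
  det <- matrix(0, length(depths), n_rep)
  for (r in seq_len(n_rep)) {
    sub <- cell_counts
    for (d in ord) {
      sub <- subsample_counts(sub, depths[d])
      det[d, r] <- sum(sub >= min_count)
    }
  }
  out <- data.frame(depth = depths, mean_detected = rowMeans(det),
                    sd_detected = if (n_rep > 1L) apply(det, 1L, stats::sd)
                                  else NA_real_)
  attr(out, "detected") <- det
  out
}

# One multivariate-hypergeometric draw of `depth` reads from `counts`,
# via sequential conditional hypergeometrics (exact, O(G)).
subsample_counts <- function(counts, depth) {
  G <- length(counts)
  remaining <- sum(counts)
  out <- numeric(G)
  need <- depth
  for (g in seq_len(G)) {
    if (need == 0) break
    remaining <- remaining - counts[g]
    out[g] <- stats::rhyper(1L, counts[g], remaining, need)
    need <- need - out[g]
  }
  out
}

#' Pool per-cell count vectors into an ensemble
#'
#' Element-wise sum over a shared gene index, emulating the pooling of raw
#' reads from all single-cell libraries.
#'
#' @param vectors List of named per-gene count vectors, or an
#'   [expr_matrix()] (pools all its cells).
#' @return Named pooled count vector.
#' @export
ensemble_pool <- function(vectors) {
  if (inherits(vectors, "expr_matrix")) return(rowSums(vectors$values))
  stopifnot(length(vectors) >= 1L)
  g <- names(vectors[[1L]])
  for (v in vectors)
    if (!identical(names(v), g)) stop("mismatched gene index")
  Reduce(`+`, vectors)
}

#' Gene-body coverage profile by expression class
#'
#' Transcripts are rank-ordered by expression; the top, middle and bottom
#' `class_size` transcripts form three classes. Per class, coverage vectors
#' (on a common 0-100 percentile grid of normalized transcript length) are
#' averaged across transcripts and normalized to the class maximum.
#'
#' @param coverage Transcripts-by-positions matrix (columns = percentile
#'   grid 0..100).
#' @param expression Per-transcript expression used for ranking.
#' @param class_size Transcripts per class (default 1000).
#' @return List with `percentile_grid` and `coverage_ratio`, a 3-row matrix
#'   (`top`, `middle`, `bottom`).
#' @export
body_coverage <- function(coverage, expression, class_size = 1000L) {
  coverage <- as.matrix(coverage)
  n <- nrow(coverage)
  stopifnot(length(expression) == n)
  if (n < 3L * class_size)
    stop("need at least 3 * class_size transcripts (lower class_size?)")
  ord <- order(expression, decreasing = TRUE)
  mid0 <- floor((n - class_size) / 2)
  classes <- list(top = ord[seq_len(class_size)],
                  middle = ord[mid0 + seq_len(class_size)],
                  bottom = ord[n - class_size + seq_len(class_size)])
  prof <- t(vapply(classes, function(ix) {
    m <- colMeans(coverage[ix, , drop = FALSE])
    m / max(m)
  }, numeric(ncol(coverage))))
  list(percentile_grid = seq(0, 100, length.out = ncol(coverage)),
       coverage_ratio = prof)
}

#' ERCC spike-in input/output correlation
#'
#' Pearson correlation of `log2(observed + 1)` against `log2(input)` over
#' spike-ins with positive observed and input values.
#'
#' @param observed Per-spike-in observed counts.
#' @param inputs Per-spike-in input molecule counts.
#' @return Pearson r, or `NA` with fewer than 3 usable points.
#' @export
ercc_correlation <- function(observed, inputs) {
  stopifnot(length(observed) == length(inputs))
  ok <- observed > 0 & inputs > 0
  if (sum(ok) < 3L) return(NA_real_)
  stats::cor(log2(observed[ok] + 1), log2(inputs[ok]))
}

#' Select housekeeping genes for cell quality control
#'
#' Among the `top_fraction` of genes by mean expression, returns the `k`
#' genes with the lowest coefficient of variation across cells — stably,
#' highly expressed genes whose detection indicates a sound library. Ties
#' in CV are broken by gene id order.
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param k Number of genes to select (default 8).
#' @param top_fraction Fraction of genes eligible by mean expression.
#' @return Character vector of `k` gene ids.
#' @export
select_housekeeping_genes <- function(matrix, k = 8L, top_fraction = 0.1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  mu <- rowMeans(v)
  n_top <- max(k, floor(nrow(v) * top_fraction))
  if (nrow(v) < k) stop("fewer than k genes")
  top <- names(sort(mu, decreasing = TRUE))[seq_len(n_top)]
  sdv <- apply(v[top, , drop = FALSE], 1L, stats::sd)
  cv <- sdv / mu[top]
  cv[is.na(cv)] <- Inf
  ord <- order(cv, top)   # tie-break: gene id order
  top[ord][seq_len(k)]
}

#' Filter cells by housekeeping-gene detection
#'
#' A cell passes when at least `min_detected_hk` of the housekeeping genes
#' are detected (count >= 1). Adding counts can never flip pass to fail.
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param min_detected_hk Minimum detected housekeeping genes (default all).
#' @return Named logical vector, `TRUE` = pass.
#' @export
qc_filter_cells <- function(matrix, housekeeping,
                            min_detected_hk = length(housekeeping)) {
  stopifnot(inherits(matrix, "expr_matrix"))
  missing <- setdiff(housekeeping, rownames(matrix$values))
  if (length(missing)) stop("housekeeping genes absent from matrix: ",
                            paste(missing, collapse = ", "))
  hk <- matrix$values[housekeeping, , drop = FALSE]
  colSums(hk >= 1) >= min_detected_hk
}

#' Cell-cycle stage assignment from marker gene sets
#'
#' Expression is log-CPM normalized, z-scored per gene across cells; each
#' phase's score is the mean z over its marker genes and the call is the
#' argmax phase, or `unassigned` when the top two scores are within
#' `tie_tol`.
#'
#' @param matrix An [expr_matrix()] of raw counts.
#' @param marker_sets Named list of character vectors (e.g. `G1`, `S`,
#'   `G2M`), each a phase's marker genes.
#' @param tie_tol Minimum score margin for a confident call.
#' @return Data frame with `cell_id`, `phase`, and one score column per
#'   phase.
#' @export
cell_cycle_stage <- function(matrix, marker_sets, tie_tol = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"), length(marker_sets) >= 2L)
  lc <- log_cpm(matrix)
  marker_sets <- lapply(marker_sets, intersect, y = rownames(lc))
  if (all(lengths(marker_sets) == 0L)) stop("no marker genes in matrix")
  sdv <- apply(lc, 1L, stats::sd)
  keep <- sdv > 0
  z <- (lc[keep, , drop = FALSE] - rowMeans(lc[keep, , drop = FALSE])) /
    sdv[keep]
  scores <- vapply(marker_sets, function(gs) {
    gs <- intersect(gs, rownames(z))
    if (length(gs) == 0L) return(rep(NA_real_, ncol(z)))
    colMeans(z[gs, , drop = FALSE])
  }, numeric(ncol(z)))
  scores <- matrix(scores, ncol = length(marker_sets),
                   dimnames = list(colnames(z), names(marker_sets)))
  phase <- apply(scores, 1L, function(s) {
    s[is.na(s)] <- -Inf
    o <- order(s, decreasing = TRUE)
    if (s[o[1L]] - s[o[2L]] < tie_tol) "unassigned" else names(s)[o[1L]]
  })
  data.frame(cell_id = rownames(scores), phase = phase, scores,
             row.names = NULL, check.names = FALSE)
}
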