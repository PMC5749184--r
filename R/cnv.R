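#' Copy-number profile container
#'
#' @param bins A [genome_bins()] grid.
#' @param log2_ratio Per-bin log2 relative copy number (`NA` = masked bin).
#' @param segments Optional data.frame with `start_bin`, `end_bin` (1-based
#'   inclusive bin indices) and `seg_mean`.
#' @param sample_id Sample identifier.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(bins, log2_ratio, segments = NULL,
                       sample_id = "sample") {
  stopifnot(inherits(bins, "genome_bins"),
            length(log2_ratio) == nrow(bins))
  structure(list(bins = bins, log2_ratio = as.numeric(log2_ratio),
                 segments = segments, sample_id = sample_id),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s: %d bins (%d masked), %s segments\n",
              x$sample_id, length(x$log2_ratio), sum(is.na(x$log2_ratio)),
              if (is.null(x$segments)) "no" else nrow(x$segments)))
  invisible(x)
}

#' CBS hyperparameters
#'
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Permutations per split test.
#' @param min_width Minimum segment width in bins.
#' @param seed Seed for the permutation stream.
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000L, min_width = 3L,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 100L, min_width >= 2L)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = as.integer(seed)),
            class = "cbs_params")
}

#' Normalize bin counts to log2 relative copy number
#'
#' `log2_ratio_b = log2(counts_b / mean(counts over usable bins))`, where
#' usable bins have positive count; zero-count bins are masked `NA`. Each
#' profile is normalized to its own mean (relative copy number; no matched
#' normal). With a GC table, counts are first divided by the median count
#' of their GC decile.
#'
#' @param counts A [binned_counts()] object.
#' @param gc_per_bin Optional numeric GC fraction per bin.
#' @return An unsegmented [cn_profile()].
#' @export
normalize_to_log2 <- function(counts, gc_per_bin = NULL) {
  stopifnot(inherits(counts, "binned_counts"))
  v <- counts$counts
  if (all(v == 0)) stop("all bins have zero count")
  if (!is.null(gc_per_bin)) {
    stopifnot(length(gc_per_bin) == length(v))
    dec <- cut(gc_per_bin, stats::quantile(gc_per_bin, 0:10 / 10),
               include.lowest = TRUE, labels = FALSE)
    med <- tapply(v[v > 0], dec[v > 0], stats::median)
    adj <- as.numeric(med[as.character(dec)])
    adj[is.na(adj) | adj == 0] <- stats::median(v[v > 0])
    v <- v / adj * stats::median(v[v > 0])
  }
  usable <- v > 0
  lr <- rep(NA_real_, length(v))
  lr[usable] <- log2(v[usable] / mean(v[usable]))
  cn_profile(counts$bins, lr, sample_id = counts$sample_id)
}

# Enumerate boundary pairs (i,j), 0 <= i < j <= n, arc (i, j], subject to
# min_width on both the arc (n1 = j - i) and its complement (n2 = n - n1).
arc_pairs <- function(n, min_width) {
  i <- rep.int(0:(n - 1L), n:1L)
  j <- sequence(n:1L) + i
  n1 <- j - i; n2 <- n - n1
  ok <- n1 >= min_width & n2 >= min_width
  if (!any(ok)) return(NULL)
  list(i = i[ok], j = j[ok], n1 = n1[ok], n2 = n2[ok],
       scale = sqrt(n1[ok] * n2[ok] / n), n = n)
}

# Max arc statistic over precomputed pairs. Known-variance z form:
# |mean_arc - mean_comp| * sqrt(n1*n2/n); the segment's residual scale
# cancels against permutations so no pooled-sd estimate is needed.
max_arc_stat <- function(y, pairs) {
  S <- c(0, cumsum(y))
  tot <- S[pairs$n + 1L]
  arc <- S[pairs$j + 1L] - S[pairs$i + 1L]
  stat <- abs(arc / pairs$n1 - (tot - arc) / pairs$n2) * pairs$scale
  best <- which.max(stat)
  list(stat = stat[best], i = pairs$i[best], j = pairs$j[best])
}

# Permutation acceptance test for the best split of one segment; early
# termination once rejection is certain.
split_significant <- function(y, obs_stat, pairs, params) {
  if (obs_stat <= 0) return(FALSE)
  limit <- params$alpha * (params$n_perm + 1) - 1   # max exceedances allowed
  exceed <- 0
  for (p in seq_len(params$n_perm)) {
    s <- max_arc_stat(sample(y), pairs)$stat
    if (s >= obs_stat) {
      exceed <- exceed + 1
      if (exceed > limit) return(FALSE)
    }
  }
  TRUE
}

#' Circular binary segmentation of a copy-number profile
#'
#' Recursively searches each segment for the circular arc whose mean most
#' differs from its complement (z statistic
#' `|mean_arc - mean_comp| * sqrt(n1 n2 / n)`), accepts the split when the
#' observed maximum exceeds the permutation null at level `alpha`, and
#' recurses into the resulting subsegments. No undo/pruning pass is
#' applied. Masked (`NA`) bins are excluded from all statistics and
#' assigned to the enclosing segment afterwards.
#'
#' @param profile An unsegmented [cn_profile()].
#' @param params A [cbs_params()] object.
#' @return The profile with its `segments` table filled in.
#' @export
cbs_segment <- function(profile, params = cbs_params()) {
  stopifnot(inherits(profile, "cn_profile"))
  idx <- which(!is.na(profile$log2_ratio))
  y_all <- profile$log2_ratio[idx]
  n <- length(y_all)
  if (n < 2L * params$min_width) {
    warning("too few usable bins; returning a single segment")
    segs <- data.frame(start_bin = 1L,
                       end_bin = length(profile$log2_ratio),
                       seg_mean = mean(y_all))
    profile$segments <- segs
    return(profile)
  }
  set.seed(params$seed)
  # recursion over index ranges into y_all; collect breakpoints
  bounds <- integer(0)  # boundary positions b: segment break after y_all[b]
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * params$min_width) return()
    y <- y_all[lo:hi]
    pairs <- arc_pairs(len, params$min_width)
    if (is.null(pairs)) return()
    m <- max_arc_stat(y, pairs)
    if (!split_significant(y, m$stat, pairs, params)) return()
    cuts <- unique(c(m$i, m$j))
    cuts <- cuts[cuts > 0L & cuts < len]
    if (length(cuts) == 0L) return()
    bounds <<- c(bounds, lo - 1L + cuts)
    edges <- c(lo - 1L, lo - 1L + sort(cuts), hi)
    for (k in seq_len(length(edges) - 1L))
      recurse(edges[k] + 1L, edges[k + 1L])
  }
  recurse(1L, n)
  edges <- c(0L, sort(unique(bounds)), n)
  seg_list <- lapply(seq_len(length(edges) - 1L), function(k) {
    a <- edges[k] + 1L; b <- edges[k + 1L]
    data.frame(start_bin = idx[a], end_bin = idx[b],
               seg_mean = mean(y_all[a:b]))
  })
  segs <- do.call(rbind, seg_list)
  # absorb masked bins into enclosing segments: stretch starts/ends
  segs$start_bin[1L] <- 1L
  if (nrow(segs) > 1L)
    segs$start_bin[-1L] <- segs$end_bin[-nrow(segs)] + 1L
  segs$end_bin[nrow(segs)] <- length(profile$log2_ratio)
  profile$segments <- segs
  profile
}

#' Per-bin segment means of a segmented profile
#'
#' @param profile A segmented [cn_profile()].
#' @return Numeric vector, one value per bin.
#' @export
segment_means_per_bin <- function(profile) {
  stopifnot(!is.null(profile$segments))
  out <- rep(NA_real_, length(profile$log2_ratio))
  for (k in seq_len(nrow(profile$segments))) {
    s <- profile$segments[k, ]
    out[s$start_bin:s$end_bin] <- s$seg_mean
  }
  out
}

#' Correlation between two copy-number profiles
#'
#' Pearson or Spearman correlation over bins that are non-masked in both
#' profiles, using raw per-bin log2 ratios or segment means.
#'
#' @param a,b [cn_profile()] objects on the same bin grid.
#' @param method `"pearson"` or `"spearman"`.
#' @param use `"log2"` (default) or `"segment"` for segment means.
#' @return Correlation coefficient, or `NA` (with a warning) when fewer
#'   than 3 shared bins or zero variance.
#' @export
profile_correlation <- function(a, b, method = c("pearson", "spearman"),
                                use = c("log2", "segment")) {
  method <- match.arg(method); use <- match.arg(use)
  va <- if (use == "segment") segment_means_per_bin(a) else a$log2_ratio
  vb <- if (use == "segment") segment_means_per_bin(b) else b$log2_ratio
  stopifnot(length(va) == length(vb))
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 3L) { warning("fewer than 3 shared bins"); return(NA_real_) }
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    warning("zero variance in shared bins"); return(NA_real_)
  }
  stats::cor(va[ok], vb[ok], method = method)
}

#' Average copy-number profiles bin-wise
#'
#' Per-bin mean of log2 ratios, ignoring `NA`; a bin masked in every
#' profile stays `NA`.
#'
#' @param profiles Non-empty list of [cn_profile()] objects on one grid.
#' @return An unsegmented [cn_profile()].
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("empty profile list")
  mat <- vapply(profiles, function(p) p$log2_ratio,
                numeric(length(profiles[[1L]]$log2_ratio)))
  avg <- rowMeans(as.matrix(mat), na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  cn_profile(profiles[[1L]]$bins, avg, sample_id = "average")
}

#' Hierarchical clustering of copy-number profiles
#'
#' Euclidean distance with Ward linkage (`stats::hclust`, `"ward.D2"`).
#' Bins masked in any profile are dropped listwise. Deterministic given
#' input order; `stats::hclust` breaks distance ties by merge order.
#'
#' @param profiles List of [cn_profile()] objects, or a samples-by-bins
#'   numeric matrix.
#' @param k Optional number of flat clusters to cut.
#' @param use `"log2"` or `"segment"` values (profiles input only).
#' @return List with `tree` (an `hclust`) and `labels` (named cluster ids
#'   at `k`, or `NULL`).
#' @export
cluster_profiles <- function(profiles, k = NULL, use = c("log2", "segment")) {
  use <- match.arg(use)
  if (is.list(profiles) && !is.matrix(profiles)) {
    mat <- t(vapply(profiles, function(p) {
      if (use == "segment") segment_means_per_bin(p) else p$log2_ratio
    }, numeric(length(profiles[[1L]]$log2_ratio))))
    rownames(mat) <- vapply(profiles, function(p) p$sample_id, "")
  } else mat <- as.matrix(profiles)
  if (nrow(mat) < 2L) stop("need >= 2 samples")
  keep <- colSums(is.na(mat)) == 0L
  if (!any(keep)) stop("no complete bins across samples")
  tree <- stats::hclust(stats::dist(mat[, keep, drop = FALSE]),
                        method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k) else NULL
  list(tree = tree, labels = labels)
}

#' Write segments as a SEG-style table
#'
#' @param profile A segmented [cn_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profile, path) {
  stopifnot(!is.null(profile$segments))
  segs <- profile$segments
  rows <- lapply(seq_len(nrow(segs)), function(k) {
    b <- segs$start_bin[k]:segs$end_bin[k]
    data.frame(sample = profile$sample_id,
               chrom = profile$bins$chrom[segs$start_bin[k]],
               start = min(profile$bins$start[b]),
               end = max(profile$bins$end[b]),
               n_bins = length(b), seg_mean = segs$seg_mean[k])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
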