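#' Sequencing quality metrics from alignment records
#'
#' Fractions of reads aligned, duplicated, properly paired, and with mates
#' on a different chromosome. The alignment fraction is over all reads;
#' duplication, pairing and cross-chromosome fractions are over mapped
#' reads (returned as `NA` when nothing is mapped).
#'
#' @param records A [read_records()] table.
#' @return List with `frac_aligned`, `frac_duplicated`,
#'   `frac_properly_paired`, `frac_mate_diff_chrom`, `n_reads`.
#' @export
sequencing_metrics <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no records")
  n <- nrow(records)
  mapped <- is_mapped(records)
  nm <- sum(mapped)
  if (nm == 0L) {
    return(list(frac_aligned = 0, frac_duplicated = NA_real_,
                frac_properly_paired = NA_real_,
                frac_mate_diff_chrom = NA_real_, n_reads = n))
  }
  mate_mapped <- records$mate_chrom != "*"
  list(frac_aligned = nm / n,
       frac_duplicated = sum(is_duplicate(records) & mapped) / nm,
       frac_properly_paired = sum(is_proper_pair(records) & mapped) / nm,
       frac_mate_diff_chrom =
         sum(mapped & mate_mapped & records$mate_chrom != records$chrom) / nm,
       n_reads = n)
}

#' Bin-to-bin coefficient of variation
#'
#' CV of per-bin read counts: sample standard deviation (n-1 denominator)
#' over the mean. A scalar index of coverage uniformity; Poisson sampling
#' alone gives `1/sqrt(mean)`.
#'
#' @param counts A [binned_counts()] object.
#' @param exclude_zero_bins Drop zero-count bins first.
#' @return CV as a single number.
#' @export
bin_cv <- function(counts, exclude_zero_bins = FALSE) {
  stopifnot(inherits(counts, "binned_counts"))
  x <- counts$counts
  if (exclude_zero_bins) x <- x[x > 0]
  if (length(x) < 2L) stop("need >= 2 usable bins")
  m <- mean(x)
  if (m == 0) stop("zero mean count")
  stats::sd(x) / m
}

#' Lorenz curve of coverage uniformity
#'
#' Bins are sorted ascending by count; the curve plots cumulative genome
#' fraction against cumulative read fraction, anchored at (0,0). Perfect
#' uniformity gives the diagonal with area under the curve 0.5; all reads
#' in one bin of n gives 1/(2n).
#'
#' @param counts A [binned_counts()] object with positive total count.
#' @return List with `x`, `y` (each length n+1, from 0 to 1) and `auc`
#'   (trapezoidal rule).
#' @export
lorenz_curve <- function(counts) {
  stopifnot(inherits(counts, "binned_counts"))
  v <- sort(counts$counts)
  tot <- sum(v)
  if (tot == 0) stop("total count is zero")
  n <- length(v)
  x <- c(0, seq_len(n) / n)
  y <- c(0, cumsum(v) / tot)
  list(x = x, y = y, auc = lorenz_auc(x, y))
}

#' Area under a Lorenz curve by the trapezoidal rule
#'
#' @param x,y Coordinates of the curve (non-decreasing, from 0 to 1).
#' @return The area under the curve.
#' @export
lorenz_auc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Power spectrum of binned read-depth variation
#'
#' Per chromosome, the relative-depth signal `x_b = counts_b / mean - 1`
#' is Fourier transformed; `psd_k = |X_k|^2 / N` at frequency
#' `k / (N * bin_size)` cycles per base pair, k = 1..N-1, which satisfies
#' `sum(psd) = N * var_pop(x)` (Parseval). Chromosome spectra are linearly
#' interpolated onto the frequency grid of the longest usable chromosome
#' and averaged. `summary` is the mean power over frequencies above
#' `1/summary_scale` (default 1/500 kb, i.e. genomic length scales finer
#' than 500 kb); it is `NA` when the bin size is too coarse for that band
#' (Nyquist = 1/(2 bin_size)).
#'
#' @param counts A [binned_counts()] object.
#' @param min_bins Chromosomes with fewer bins are skipped (with a message).
#' @param summary_scale Length scale (bp) whose inverse bounds the summary
#'   band from below.
#' @return List with `freqs`, `psd`, `summary`, and `per_chrom` (the
#'   unaveraged per-chromosome spectra).
#' @export
power_spectrum <- function(counts, min_bins = 8L, summary_scale = 5e5) {
  stopifnot(inherits(counts, "binned_counts"))
  bs <- bin_size(counts$bins)
  per_chrom <- list()
  for (ch in unique(counts$bins$chrom)) {
    v <- counts$counts[counts$bins$chrom == ch]
    if (length(v) < min_bins) {
      message("power_spectrum: skipping ", ch, " (", length(v), " bins)")
      next
    }
    if (mean(v) == 0) {
      message("power_spectrum: skipping ", ch, " (zero coverage)")
      next
    }
    x <- v / mean(v) - 1
    N <- length(x)
    X <- stats::fft(x)
    k <- seq_len(N - 1L)
    per_chrom[[ch]] <- list(freqs = k / (N * bs),
                            psd = Mod(X[k + 1L])^2 / N)
  }
  if (length(per_chrom) == 0L) stop("no usable chromosome")
  ref <- per_chrom[[which.max(vapply(per_chrom,
                                     function(p) length(p$freqs), 0))]]
  grid <- ref$freqs
  mat <- vapply(per_chrom, function(p) {
    stats::approx(p$freqs, p$psd, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  psd <- rowMeans(as.matrix(mat))
  band <- grid > 1 / summary_scale
  list(freqs = grid, psd = psd,
       summary = if (any(band)) mean(psd[band]) else NA_real_,
       per_chrom = per_chrom)
}

#' Mean power above a frequency threshold
#'
#' @param ps Result of [power_spectrum()].
#' @param min_freq Lower band edge in cycles per bp (default 1/500 kb).
#' @return Mean PSD over `freqs > min_freq`.
#' @export
psd_summary <- function(ps, min_freq = 1 / 5e5) {
  band <- ps$freqs > min_freq
  if (!any(band)) return(NA_real_)
  mean(ps$psd[band])
}

#' Randomly down-sample alignment records
#'
#' Draws `target_n` records without replacement, independently per
#' replicate, reproducibly from `seed`.
#'
#' @param records A [read_records()] table.
#' @param target_n Reads per replicate (must not exceed available reads).
#' @param n_replicates Number of independent replicates.
#' @param seed Integer seed.
#' @return List of record tables, one per replicate.
#' @export
downsample_reads <- function(records, target_n, n_replicates = 1L, seed = 1L) {
  n <- nrow(records)
  if (target_n > n) stop("target_n exceeds available reads")
  set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    idx <- sample.int(n, target_n)
    out <- records[sort(idx), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
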