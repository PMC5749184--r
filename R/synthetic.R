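#' Ground-truth parameters for a synthetic paired DNA/RNA dataset
#'
#' Bundles everything the generator needs to produce seed-reproducible
#' single-cell WGS bin counts, scRNA-seq matrices, SNV call sets and
#' cross-fraction contamination, with the truth retained for verification.
#'
#' @param bins A [genome_bins()] grid for the DNA side.
#' @param cn_profile Integer copy number per bin (baseline ploidy 2).
#' @param bias_sigma Innovation (conditional) standard deviation of the
#'   AR(1) Gaussian process on the log amplification bias. The marginal sd
#'   is `bias_sigma / sqrt(1 - bias_rho^2)`, so increasing `bias_rho` at
#'   fixed `bias_sigma` raises power at every genomic length scale.
#' @param bias_rho AR(1) autocorrelation of the log-bias, in `[0, 1)`.
#' @param dropout_midpoint,dropout_slope Logistic dropout versus log mean
#'   expression: detection probability
#'   `1 / (1 + exp(-slope * (log(mu) - midpoint)))`.
#' @param libsize_sigma Lognormal sd of per-cell library-size factors.
#' @param contamination_rna_in_dna,contamination_dna_in_rna Fractions in
#'   `[0, 1)` of reads leaking across fractions.
#' @param contaminant_dup_rate Duplicate-marking probability for contaminant
#'   reads (default 0.25, the elevated coding-region duplication seen in
#'   unseparated preparations).
#' @param true_variants A [variant_set()] of planted somatic SNVs.
#' @param sensitivity,fp_rate Per-cell SNV detection probability and expected
#'   false-positive call count.
#' @param seed Master integer seed; per-cell substreams are derived from it
#'   by fixed offsets so cell `i`'s data do not depend on `n_cells`.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(bins = tile_genome(c(chr1 = 100e6), 1e6),
                      cn_profile = rep(2L, nrow(bins)),
                      bias_sigma = 0.3, bias_rho = 0.5,
                      dropout_midpoint = log(5), dropout_slope = 1,
                      libsize_sigma = 0.3,
                      contamination_rna_in_dna = 0,
                      contamination_dna_in_rna = 0,
                      contaminant_dup_rate = 0.25,
                      true_variants = variant_set(),
                      sensitivity = 0.85, fp_rate = 5,
                      seed = 1L) {
  stopifnot(inherits(bins, "genome_bins"),
            length(cn_profile) == nrow(bins), all(cn_profile >= 0),
            bias_sigma >= 0, bias_rho >= 0, bias_rho < 1,
            contamination_rna_in_dna >= 0, contamination_rna_in_dna < 1,
            contamination_dna_in_rna >= 0, contamination_dna_in_rna < 1,
            sensitivity >= 0, sensitivity <= 1, fp_rate >= 0)
  structure(list(bins = bins, cn_profile = as.integer(cn_profile),
                 bias_sigma = bias_sigma, bias_rho = bias_rho,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 libsize_sigma = libsize_sigma,
                 contamination_rna_in_dna = contamination_rna_in_dna,
                 contamination_dna_in_rna = contamination_dna_in_rna,
                 contaminant_dup_rate = contaminant_dup_rate,
                 true_variants = true_variants,
                 sensitivity = sensitivity, fp_rate = fp_rate,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# Per-cell substream: fixed affine offset from the master seed, kept within
# 32-bit integer range. `stage` separates WGS/RNA/SNV streams.
cell_seed <- function(truth, cell, stage) {
  offs <- c(wgs = 11L, rna = 23L, snv = 37L, contam = 53L)[[stage]]
  # double arithmetic: exact below 2^53, avoids 32-bit overflow
  as.integer((as.numeric(truth$seed) * 1000003 + cell * 101 + offs) %%
               2147483647)
}

ar1_log_bias <- function(n, sigma, rho) {
  if (sigma == 0) return(numeric(n))
  g <- numeric(n)
  g[1L] <- stats::rnorm(1L, 0, sigma / sqrt(max(1 - rho^2, .Machine$double.eps)))
  if (n > 1L) {
    eps <- stats::rnorm(n - 1L, 0, sigma)
    for (b in 2:n) g[b] <- rho * g[b - 1L] + eps[b - 1L]
  }
  g
}

#' Simulate single-cell WGS bin counts
#'
#' Counts in bin `b` of each cell are Poisson with mean
#' `mean_depth_per_bin * cn_b / 2 * bias_b`, where `log(bias)` is an AR(1)
#' Gaussian process (innovation sd `bias_sigma`, correlation `bias_rho`)
#' drawn independently per cell and per chromosome, mean-centered so the
#' bias is depth-neutral on average.
#'
#' @param truth A [sim_truth()].
#' @param mean_depth_per_bin Expected reads per diploid, unit-bias bin.
#' @param n_cells Number of cells.
#' @return List with `cells` (list of [binned_counts()]) and `bias`
#'   (bin-by-cell matrix of realized amplification biases).
#' @export
simulate_wgs_bins <- function(truth, mean_depth_per_bin, n_cells = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (mean_depth_per_bin <= 0) stop("mean_depth_per_bin must be positive")
  bins <- truth$bins
  chrom_rle <- rle(bins$chrom)
  bias <- matrix(NA_real_, nrow(bins), n_cells)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(truth, i, "wgs"))
    g <- unlist(lapply(chrom_rle$lengths, ar1_log_bias,
                       sigma = truth$bias_sigma, rho = truth$bias_rho))
    b <- exp(g - mean(g))
    mu <- mean_depth_per_bin * truth$cn_profile / 2 * b
    cnt <- stats::rpois(nrow(bins), mu)
    bias[, i] <- b
    cells[[i]] <- binned_counts(bins, cnt,
                                sample_id = sprintf("cell%02d", i),
                                fraction_type = "FD")
  }
  list(cells = cells, bias = bias)
}

#' Simulate a single-cell RNA-seq count matrix with ERCC spike-ins
#'
#' Endogenous gene counts are Poisson around `libsize_c * p_g` (with `p_g`
#' the bulk relative abundance) thinned by gene-level logistic dropout in
#' the log of the cell's expected count. Spike-ins pass through the same
#' library-size and Poisson noise but are never dropped: they are exogenous
#' standards added in equal known amounts to every cell.
#'
#' @param bulk_profile Named non-negative vector of per-gene bulk means.
#' @param n_cells Number of cells.
#' @param truth A [sim_truth()] (dropout/library-size parameters, seed).
#' @param ercc_inputs Optional named vector of spike-in input molecule
#'   counts.
#' @param mean_libsize Expected endogenous reads per cell.
#' @param gene_coords Optional gene coordinate table passed through to the
#'   result.
#' @param dropout Set `FALSE` to disable dropout thinning.
#' @return List with `matrix` ([expr_matrix()] of endogenous counts),
#'   `spikes` (spike-in-by-cell count matrix or `NULL`), and `detection_prob`
#'   (gene-by-cell matrix of realized detection probabilities).
#' @export
simulate_scrna <- function(bulk_profile, n_cells, truth,
                           ercc_inputs = NULL, mean_libsize = 1e5,
                           gene_coords = NULL, dropout = TRUE) {
  stopifnot(inherits(truth, "sim_truth"), n_cells >= 1)
  if (all(bulk_profile <= 0)) stop("bulk_profile is all zero")
  if (is.null(names(bulk_profile)))
    names(bulk_profile) <- paste0("gene", seq_along(bulk_profile))
  p <- bulk_profile / sum(bulk_profile)
  G <- length(p)
  counts <- matrix(0L, G, n_cells,
                   dimnames = list(names(bulk_profile),
                                   sprintf("cell%02d", seq_len(n_cells))))
  det <- matrix(1, G, n_cells, dimnames = dimnames(counts))
  spikes <- NULL
  if (!is.null(ercc_inputs)) {
    spikes <- matrix(0L, length(ercc_inputs), n_cells,
                     dimnames = list(names(ercc_inputs),
                                     colnames(counts)))
  }
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(truth, i, "rna"))
    lib <- mean_libsize *
      stats::rlnorm(1L, -truth$libsize_sigma^2 / 2, truth$libsize_sigma)
    mu <- lib * p
    if (dropout) {
      keep_p <- stats::plogis(truth$dropout_slope *
                                (log(pmax(mu, .Machine$double.xmin)) -
                                   truth$dropout_midpoint))
      keep_p[mu == 0] <- 0
      kept <- stats::rbinom(G, 1L, keep_p)
      det[, i] <- keep_p
    } else {
      kept <- rep(1L, G)
    }
    counts[, i] <- stats::rpois(G, mu) * kept
    if (!is.null(spikes)) {
      sf <- lib / mean_libsize   # spike counts share the cell's size factor
      spikes[, i] <- stats::rpois(length(ercc_inputs), sf * ercc_inputs)
    }
  }
  list(matrix = expr_matrix(counts, gene_coords = gene_coords,
                            fraction_type = "FR"),
       spikes = spikes, detection_prob = det)
}

#' Simulate cross-fraction read contamination
#'
#' Moves a Binomial subset of the RNA fraction's reads (exonic-enriched by
#' construction) into the DNA fraction at rate `contamination_rna_in_dna`,
#' and vice versa at `contamination_dna_in_rna`. Moved reads are duplicate-
#' marked with probability `contaminant_dup_rate`, emulating the high
#' duplication of amplified cDNA contaminants. Total read count is conserved.
#'
#' @param dna_reads,rna_reads [read_records()] tables for the two fractions.
#' @param truth A [sim_truth()] carrying the contamination parameters.
#' @return List with `dna` and `rna` record tables.
#' @export
simulate_fraction_contamination <- function(dna_reads, rna_reads, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (truth$contamination_rna_in_dna >= 1 || truth$contamination_dna_in_rna >= 1)
    stop("contamination fraction must be < 1")
  set.seed(cell_seed(truth, 0L, "contam"))
  mark_dups <- function(rec) {
    dup <- stats::rbinom(nrow(rec), 1L, truth$contaminant_dup_rate) == 1L
    rec$flag <- rec$flag + ifelse(dup & !is_duplicate(rec), 1024L, 0L)
    rec
  }
  pick <- function(rec, rate) {
    n <- nrow(rec)
    take <- which(stats::runif(n) < rate)
    list(moved = rec[take, , drop = FALSE],
         kept = rec[setdiff(seq_len(n), take), , drop = FALSE])
  }
  r2d <- pick(rna_reads, truth$contamination_rna_in_dna)
  d2r <- pick(dna_reads, truth$contamination_dna_in_rna)
  dna_out <- rbind(d2r$kept, mark_dups(r2d$moved))
  rna_out <- rbind(r2d$kept, mark_dups(d2r$moved))
  class(dna_out) <- class(rna_out) <- c("read_records", "data.frame")
  rownames(dna_out) <- rownames(rna_out) <- NULL
  list(dna = dna_out, rna = rna_out)
}

#' Simulate per-cell SNV call sets
#'
#' Each cell's call set is a Bernoulli(`sensitivity`) thinning of the true
#' variant set plus `Poisson(fp_rate)` false positives drawn from random
#' positions outside the truth.
#'
#' @param truth A [sim_truth()] with non-empty `true_variants`.
#' @param n_cells Number of cells.
#' @param fp_space_size Size of the candidate position pool for false
#'   positives, per chromosome span.
#' @return List of [variant_set()] objects, one per cell.
#' @export
simulate_snv_calls <- function(truth, n_cells, fp_space_size = 1e6) {
  stopifnot(inherits(truth, "sim_truth"))
  tv <- truth$true_variants
  if (nrow(tv) == 0L) stop("true_variants is empty")
  truth_keys <- variant_keys(tv)
  chroms <- unique(truth$bins$chrom)
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n_cells), function(i) {
    set.seed(cell_seed(truth, i, "snv"))
    keep <- stats::runif(nrow(tv)) < truth$sensitivity
    n_fp <- stats::rpois(1L, truth$fp_rate)
    fp <- NULL
    if (n_fp > 0L) {
      repeat {
        ch <- sample(chroms, n_fp, replace = TRUE)
        pos <- sample.int(fp_space_size, n_fp, replace = TRUE) - 1L
        ref <- sample(bases, n_fp, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
        key <- paste(ch, pos, ref, alt, sep = ":")
        ok <- !(key %in% truth_keys) & !duplicated(key)
        if (all(ok)) break
        # resample clashes only
        n_fp <- n_fp  # loop rare; just redraw all
      }
      fp <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    }
    df <- rbind(as.data.frame(tv)[keep, c("chrom", "pos", "ref", "alt")], fp)
    variant_set(df$chrom, df$pos, df$ref, df$alt,
                sample_id = sprintf("cell%02d", i))
  })
}

#' Simulate per-transcript gene-body coverage vectors
#'
#' Produces coverage along a 0–100 percentile grid of normalized transcript
#' length with an optional exponential 3'-end bias, the pattern oligo-dT
#' primed libraries show.
#'
#' @param n_transcripts Number of transcripts.
#' @param bias_strength Exponential rate of the 3' bias (0 = uniform).
#' @param noise_sd Multiplicative lognormal noise per position.
#' @param seed Integer seed.
#' @return Matrix `n_transcripts` x 101 of coverage values; columns are
#'   percentiles 0..100 with 100 = 3' end.
#' @export
simulate_transcript_coverage <- function(n_transcripts, bias_strength = 0,
                                         noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  grid <- seq(0, 1, length.out = 101L)
  base <- exp(bias_strength * grid)
  m <- matrix(stats::rlnorm(n_transcripts * 101L, 0, noise_sd),
              n_transcripts, 101L)
  sweep(m, 2L, base, `*`)
}
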