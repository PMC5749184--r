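#' Bin gene expression onto a genomic grid
#'
#' Each gene is assigned to the single bin containing its TSS. Per cell,
#' the bin value is the mean `log2(CPM + 1)` over member genes; bin values
#' are then averaged across the selected cells. Bins without genes are
#' `NA`.
#'
#' @param matrix An [expr_matrix()] with gene coordinates.
#' @param bins A [genome_bins()] grid.
#' @param cells Optional cell selection (names or indices; default all).
#' @return List with `bins`, `value` (per-bin mean expression) and
#'   `n_genes` per bin.
#' @export
bin_expression <- function(matrix, bins, cells = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(bins, "genome_bins"))
  if (is.null(matrix$gene_coords)) stop("matrix has no gene coordinates")
  lc <- log_cpm(matrix)
  if (!is.null(cells)) lc <- lc[, cells, drop = FALSE]
  gc <- matrix$gene_coords
  bin_of <- rep(NA_integer_, nrow(gc))
  for (b in seq_len(nrow(bins))) {
    hit <- gc$chrom == bins$chrom[b] & gc$tss >= bins$start[b] &
      gc$tss < bins$end[b]
    bin_of[hit] <- b
  }
  if (all(is.na(bin_of))) stop("no genes mapped to any bin")
  value <- rep(NA_real_, nrow(bins))
  n_genes <- integer(nrow(bins))
  for (b in unique(bin_of[!is.na(bin_of)])) {
    rows <- which(bin_of == b)
    per_cell <- colMeans(lc[rows, , drop = FALSE])
    value[b] <- mean(per_cell)
    n_genes[b] <- length(rows)
  }
  list(bins = bins, value = value, n_genes = n_genes)
}

#' Copy-number versus expression dosage correlation
#'
#' Pearson correlation (with p-value) across bins shared between a
#' copy-number profile and binned expression. By default the DNA side uses
#' CBS segment means; set `use = "log2"` for raw per-bin ratios.
#'
#' @param cn A [cn_profile()] (segmented unless `use = "log2"`).
#' @param expr Result of [bin_expression()] on the same grid.
#' @param use `"segment"` (default) or `"log2"`.
#' @return List with `r`, `p_value`, `n_bins`; `r` is `NA` on degenerate
#'   variance or fewer than 3 shared bins.
#' @export
cnv_expression_correlation <- function(cn, expr, use = c("segment", "log2")) {
  use <- match.arg(use)
  dna <- if (use == "segment") segment_means_per_bin(cn) else cn$log2_ratio
  stopifnot(length(dna) == length(expr$value))
  ok <- !is.na(dna) & !is.na(expr$value)
  if (sum(ok) < 3L) return(list(r = NA_real_, p_value = NA_real_,
                                n_bins = sum(ok)))
  if (stats::sd(dna[ok]) == 0 || stats::sd(expr$value[ok]) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n_bins = sum(ok)))
  ct <- stats::cor.test(dna[ok], expr$value[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n_bins = sum(ok))
}

#' How well random single-cell subsets explain a bulk profile
#'
#' For each cell number `n` and each of `n_perm` permutations, draws `n`
#' cells uniformly without replacement and regresses the bulk per-gene
#' vector on those cells' expression (ordinary least squares with
#' intercept; collinear columns dropped with a warning), recording
#' adjusted `R^2 = 1 - (1 - R^2)(G - 1)/(G - n - 1)` with `G` genes.
#'
#' @param single_cells An [expr_matrix()] or gene-by-cell numeric matrix.
#' @param bulk Per-gene bulk vector (same gene order).
#' @param n_cells_list Cell numbers to evaluate.
#' @param n_perm Permutations per cell number.
#' @param seed Integer seed.
#' @return Named list (one entry per `n`) of adjusted-R^2 vectors of
#'   length `n_perm`.
#' @export
bulk_explained_variance <- function(single_cells, bulk, n_cells_list,
                                    n_perm = 1000L, seed = 1L) {
  X <- if (inherits(single_cells, "expr_matrix")) single_cells$values
       else as.matrix(single_cells)
  G <- nrow(X)
  stopifnot(length(bulk) == G)
  if (G <= max(n_cells_list) + 1L)
    stop("need more genes than max(n_cells_list) + 1")
  if (any(n_cells_list > ncol(X))) stop("n exceeds number of cells")
  set.seed(seed)
  tss <- sum((bulk - mean(bulk))^2)
  out <- lapply(n_cells_list, function(n) {
    vapply(seq_len(n_perm), function(p) {
      cols <- sample.int(ncol(X), n)
      M <- cbind(1, X[, cols, drop = FALSE])
      fit <- stats::lm.fit(M, bulk)
      k <- fit$rank - 1L           # predictors actually used
      if (k < n) warning("collinear cell columns dropped")
      r2 <- 1 - sum(fit$residuals^2) / tss
      1 - (1 - r2) * (G - 1) / (G - k - 1L)
    }, 0)
  })
  names(out) <- paste0("n", n_cells_list)
  out
}

#' Fraction of single-cell SNV calls verified in bulk
#'
#' `|cell intersect bulk| / |cell|`, optionally restricted to variants in a
#' region filter — the directional "verified by bulk sequencing" rate, not
#' a symmetric Jaccard index.
#'
#' @param cell,bulk [variant_set()] objects.
#' @param region_filter Optional data.frame `chrom`/`start`/`end` (0-based
#'   half-open) restricting both sets.
#' @return Fraction in `[0, 1]`, or `NA` if the filtered cell set is empty.
#' @export
snv_concordance <- function(cell, bulk, region_filter = NULL) {
  filt <- function(vs) {
    if (is.null(region_filter)) return(vs)
    keep <- rep(FALSE, nrow(vs))
    for (k in seq_len(nrow(region_filter))) {
      keep <- keep | (vs$chrom == region_filter$chrom[k] &
                        vs$pos >= region_filter$start[k] &
                        vs$pos < region_filter$end[k])
    }
    vs[keep, , drop = FALSE]
  }
  ck <- variant_keys(filt(cell))
  if (length(ck) == 0L) return(NA_real_)
  mean(ck %in% variant_keys(filt(bulk)))
}

#' Cross-fraction contamination metrics
#'
#' The exonic read fraction of a genomic-DNA library and the duplication
#' rate of its exonic (coding-region) reads — both elevated when amplified
#' cDNA leaks into the DNA fraction.
#'
#' @param records A [read_records()] table with region annotations.
#' @return List with `exonic_fraction`, `dup_rate_overall`,
#'   `dup_rate_coding` (the latter `NA` without exonic reads; all `NA`
#'   without mapped reads).
#' @export
contamination_metrics <- function(records) {
  mapped <- is_mapped(records)
  nm <- sum(mapped)
  if (nm == 0L) return(list(exonic_fraction = NA_real_,
                            dup_rate_overall = NA_real_,
                            dup_rate_coding = NA_real_))
  exonic <- mapped & records$annotation == "exonic"
  dup <- is_duplicate(records)
  list(exonic_fraction = sum(exonic) / nm,
       dup_rate_overall = sum(dup & mapped) / nm,
       dup_rate_coding = if (sum(exonic) == 0L) NA_real_
                         else sum(dup & exonic) / sum(exonic))
}

#' Region-class fractions of mapped reads
#'
#' @param records A [read_records()] table with region annotations.
#' @return Named vector of exonic/intronic/intergenic fractions (sum 1).
#' @export
region_fractions <- function(records) {
  mapped <- is_mapped(records)
  if (sum(mapped) == 0L) stop("no mapped reads")
  ann <- factor(records$annotation[mapped],
                levels = c("exonic", "intronic", "intergenic"))
  table(ann) / sum(mapped)
}

#' Relative quantity from qPCR crossing points
#'
#' `relative_quantity = efficiency^(cp_reference - cp_fraction)`: the
#' nucleic-acid amount in a fraction relative to the whole-cell-lysate
#' reference, assuming per-cycle amplification by `efficiency` (2 = perfect
#' doubling).
#'
#' @param cp_fraction,cp_reference Crossing-point (Cp/Ct) cycle values.
#' @param efficiency Amplification base, must exceed 1.
#' @return List with the inputs and `relative_quantity`.
#' @export
qpcr_relative_quantity <- function(cp_fraction, cp_reference,
                                   efficiency = 2.0) {
  if (efficiency <= 1) stop("efficiency must exceed 1")
  list(cp_fraction = cp_fraction, cp_reference = cp_reference,
       efficiency = efficiency,
       relative_quantity = efficiency^(cp_reference - cp_fraction))
}
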