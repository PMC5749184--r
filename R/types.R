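#' Construct a set of genome bins
#'
#' Bins are stored 0-based half-open, sorted by (chrom, start), and must not
#' overlap within a chromosome. All interval arithmetic in the package uses
#' this convention; 1-based formats (VCF) are converted at the boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param bin_size Nominal bin width in base pairs (default 1e6). Individual
#'   bins may be shorter (chromosome tails) but never longer.
#' @return A `genome_bins` data.frame with columns `chrom`, `start`, `end`.
#' @export
genome_bins <- function(chrom, start, end, bin_size = 1e6) {
  if (length(chrom) == 0L) stop("no bins")
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start) | is.na(end))) stop("NA coordinates in bins")
  if (any(start < 0)) stop("bin start < 0")
  if (any(end <= start)) stop("bin end must exceed start")
  if (any(end - start > bin_size)) stop("bin wider than bin_size")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # overlap check within chromosome on sorted bins
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)]))
    stop("overlapping bins")
  attr(df, "bin_size") <- bin_size
  class(df) <- c("genome_bins", "data.frame")
  df
}

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in base pairs.
#' @return A [genome_bins()] object covering each chromosome.
#' @export
tile_genome <- function(chrom_lengths, bin_size = 1e6) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    s <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = ch, start = s, end = pmin(s + bin_size, L))
  })
  df <- do.call(rbind, pieces)
  genome_bins(df$chrom, df$start, df$end, bin_size = bin_size)
}

#' Bin size of a genome_bins object
#' @param bins A `genome_bins` object.
#' @return Nominal bin width in bp.
#' @export
bin_size <- function(bins) attr(bins, "bin_size")

#' Per-bin read counts for one sample
#'
#' @param bins A [genome_bins()] object.
#' @param counts Non-negative integer vector, one count per bin.
#' @param sample_id Sample identifier.
#' @param fraction_type One of `"FD"`, `"WD"`, `"FR"`, `"WR"`, `"bulk"`:
#'   fractionated/whole-lysate DNA or RNA, or a bulk control.
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(bins, counts, sample_id = "sample",
                          fraction_type = c("FD", "WD", "FR", "WR", "bulk")) {
  stopifnot(inherits(bins, "genome_bins"))
  fraction_type <- match.arg(fraction_type)
  if (length(counts) != nrow(bins))
    stop("length(counts) must equal number of bins")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  structure(list(bins = bins, counts = as.numeric(counts),
                 sample_id = sample_id, fraction_type = fraction_type),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %s [%s]: %d bins, %.0f reads\n",
              x$sample_id, x$fraction_type, nrow(x$bins), sum(x$counts)))
  invisible(x)
}

#' A set of single-nucleotide variants
#'
#' Variants are keyed by (chrom, pos, ref, alt) with 0-based positions
#' internally; duplicates are collapsed.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the SNVs. `pos` is
#'   0-based internally.
#' @param sample_id Sample identifier.
#' @return A `variant_set` data.frame.
#' @export
variant_set <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        sample_id = "sample") {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) && (any(nchar(ref) != 1L) || any(nchar(alt) != 1L)))
    stop("single-nucleotide variants only")
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("variant_set", "data.frame")
  df
}

variant_keys <- function(vs) {
  if (nrow(vs) == 0L) return(character())
  paste(vs$chrom, vs$pos, vs$ref, vs$alt, sep = ":")
}

#' Gene-by-cell expression matrix with gene coordinates
#'
#' @param values Non-negative numeric matrix, genes in rows, cells in columns.
#' @param gene_coords Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based transcription start position), one row per gene, in row order
#'   of `values`. May be `NULL` when coordinates are not needed.
#' @param fraction_type Per-cell fraction labels (recycled if length 1).
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, gene_coords = NULL, fraction_type = "FR") {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("cell", seq_len(ncol(values)))
  if (!is.null(gene_coords)) {
    stopifnot(all(c("gene_id", "chrom", "tss") %in% names(gene_coords)))
    if (nrow(gene_coords) != nrow(values))
      stop("gene_coords rows must match matrix rows")
    gene_coords <- as.data.frame(gene_coords)
  }
  structure(list(values = values, gene_coords = gene_coords,
                 fraction_type = rep_len(fraction_type, ncol(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells%s\n", nrow(x$values),
              ncol(x$values),
              if (is.null(x$gene_coords)) "" else " (with coordinates)"))
  invisible(x)
}

#' Read-record table from alignments
#'
#' Normalizes a data.frame of per-read fields into the internal record table
#' used by the sequencing and contamination metrics. SAM flag bits used:
#' 0x4 unmapped, 0x2 properly paired, 0x400 duplicate.
#'
#' @param flag Integer SAM flags.
#' @param chrom,mate_chrom Reference names ("*" for none).
#' @param pos 0-based positions.
#' @param annotation One of `exonic`, `intronic`, `intergenic`, `unaligned`.
#'   Defaults to `unaligned` for reads with the unmapped bit, `intergenic`
#'   otherwise.
#' @return A `read_records` data.frame.
#' @export
read_records <- function(flag, chrom, pos = 0L, mate_chrom = "*",
                         annotation = NULL) {
  flag <- as.integer(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  if (is.null(annotation))
    annotation <- ifelse(unmapped, "unaligned", "intergenic")
  annotation <- as.character(annotation)
  ok <- annotation %in% c("exonic", "intronic", "intergenic", "unaligned")
  if (!all(ok)) stop("unknown annotation value")
  if (any(unmapped != (annotation == "unaligned")))
    stop("annotation 'unaligned' must match the unmapped flag bit")
  chrom <- as.character(chrom)
  mate_chrom <- rep_len(as.character(mate_chrom), length(flag))
  mate_chrom <- ifelse(mate_chrom == "=", chrom, mate_chrom)
  df <- data.frame(flag = flag, chrom = chrom, pos = as.numeric(pos),
                   mate_chrom = mate_chrom,
                   annotation = annotation, stringsAsFactors = FALSE)
  class(df) <- c("read_records", "data.frame")
  df
}

is_mapped <- function(records) bitwAnd(records$flag, 4L) == 0L
is_duplicate <- function(records) bitwAnd(records$flag, 1024L) != 0L
is_proper_pair <- function(records) bitwAnd(records$flag, 2L) != 0L
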