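#' Read a BED-like bin-count table
#'
#' Expects 4+ tab-separated columns chrom/start/end/count with 0-based
#' half-open intervals. Bins are sorted and validated (non-overlapping).
#'
#' @param path Path to the table.
#' @param sample_id,fraction_type Metadata attached to the result.
#' @param bin_size Nominal bin width; defaults to the widest observed bin.
#' @return A [binned_counts()] object.
#' @export
read_bin_counts <- function(path, sample_id = basename(path),
                            fraction_type = "FD", bin_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no bins in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed line ", which(nf < 4L)[1L], " in ", path,
         ": expected 4+ tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  count <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path, ": non-numeric field")
  ord <- order(chrom, start)
  if (is.null(bin_size)) bin_size <- max(end - start)
  bins <- genome_bins(chrom[ord], start[ord], end[ord], bin_size = bin_size)
  binned_counts(bins, count[ord], sample_id = sample_id,
                fraction_type = fraction_type)
}

#' Write a bin-count table
#'
#' Canonical tab-separated chrom/start/end/count rows; round-trips through
#' [read_bin_counts()] byte-identically for integer counts.
#'
#' @param x A [binned_counts()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "binned_counts"))
  lines <- sprintf("%s\t%s\t%s\t%s", x$bins$chrom,
                   format(x$bins$start, scientific = FALSE, trim = TRUE),
                   format(x$bins$end, scientific = FALSE, trim = TRUE),
                   format(x$counts, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Streams a text SAM file and extracts FLAG, RNAME, POS and RNEXT (with
#' `=` resolved to RNAME). Annotation defaults to `intergenic`/`unaligned`
#' from the unmapped bit; region annotation, when available, is supplied
#' separately (see [annotate_records()]).
#'
#' @param path Path to a SAM file (text, with or without header).
#' @return A [read_records()] data.frame.
#' @export
read_sam_records <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) stop("no alignment records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM line ", which(nf < 11L)[1L],
         ": missing mandatory column")
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  if (any(is.na(flag))) stop("non-integer FLAG field")
  chrom <- vapply(fields, `[[`, "", 3L)
  pos1 <- as.numeric(vapply(fields, `[[`, "", 4L))
  rnext <- vapply(fields, `[[`, "", 7L)
  mate <- ifelse(rnext == "=", chrom, rnext)
  read_records(flag, chrom, pos = pos1 - 1, mate_chrom = mate)
}

#' Annotate read records with genomic region classes
#'
#' Assigns `exonic` / `intronic` / `intergenic` to mapped reads by interval
#' lookup in an annotation table; unmapped reads keep `unaligned`.
#'
#' @param records A [read_records()] table.
#' @param regions Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `class` in `exonic`/`intronic` — anything not covered is
#'   `intergenic`. Exonic assignment wins over intronic on overlap.
#' @return The records with the `annotation` column filled in.
#' @export
annotate_records <- function(records, regions) {
  stopifnot(all(c("chrom", "start", "end", "class") %in% names(regions)))
  ann <- records$annotation
  mapped <- is_mapped(records)
  for (cls in c("intronic", "exonic")) {   # exonic last: takes precedence
    reg <- regions[regions$class == cls, , drop = FALSE]
    if (nrow(reg) == 0L) next
    for (k in seq_len(nrow(reg))) {
      hit <- mapped & records$chrom == reg$chrom[k] &
        records$pos >= reg$start[k] & records$pos < reg$end[k]
      ann[hit] <- cls
    }
  }
  ann[mapped & !(ann %in% c("exonic", "intronic"))] <- "intergenic"
  records$annotation <- ann
  records
}

#' Read SNVs from a VCF file
#'
#' Loads a VCF 4.x file, expands multi-allelic records, keeps biallelic
#' single-nucleotide records and drops indels (counted in the `n_skipped`
#' attribute). VCF 1-based positions are converted to the internal 0-based
#' convention.
#'
#' @param path Path to an uncompressed VCF.
#' @param sample_id Sample identifier for the result.
#' @return A [variant_set()] with attribute `n_skipped`.
#' @export
read_vcf_snvs <- function(path, sample_id = basename(path)) {
  hdr <- readLines(path, n = 500L)
  if (!any(startsWith(hdr, "#CHROM"))) stop("missing #CHROM header in ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  snv <- VariantAnnotation::isSNV(vcf)
  n_skipped <- sum(!snv)
  vcf <- vcf[snv]
  rr <- SummarizedExperiment::rowRanges(vcf)
  vs <- variant_set(as.character(GenomeInfoDb::seqnames(rr)),
                    BiocGenerics::start(rr) - 1,
                    as.character(rr$REF),
                    as.character(rr$ALT),
                    sample_id = sample_id)
  attr(vs, "n_skipped") <- n_skipped
  vs
}

#' Write SNVs to a minimal VCF file
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", vs$chrom,
                  as.integer(vs$pos) + 1L, vs$ref, vs$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an expression matrix from TSV or MTX
#'
#' TSV: genes in rows (first column = gene id), cells in columns with a
#' header line. MTX: MatrixMarket triplets with `<stem>.genes.txt` and
#' `<stem>.cells.txt` index files beside it. Chosen by file extension.
#'
#' @param path `.tsv` matrix or `.mtx` triplet file.
#' @param gene_coords Optional gene coordinate table (see [expr_matrix()]);
#'   matched to matrix rows by `gene_id`.
#' @return An [expr_matrix()] object.
#' @export
read_expression <- function(path, gene_coords = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rownames(m) <- readLines(paste0(stem, ".genes.txt"))
    colnames(m) <- readLines(paste0(stem, ".cells.txt"))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1L, check.names = FALSE)
    m <- as.matrix(df)
  }
  if (!is.null(gene_coords)) {
    idx <- match(rownames(m), gene_coords$gene_id)
    if (anyNA(idx)) stop("gene_coords missing entries for some matrix genes")
    gene_coords <- gene_coords[idx, , drop = FALSE]
  }
  expr_matrix(m, gene_coords = gene_coords)
}

#' Write an expression matrix
#'
#' @param x An [expr_matrix()].
#' @param path Output path; `.mtx` writes MatrixMarket plus index files,
#'   anything else writes a TSV with gene ids in the first column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  if (tolower(tools::file_ext(path)) == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(rownames(x$values), paste0(stem, ".genes.txt"))
    writeLines(colnames(x$values), paste0(stem, ".cells.txt"))
  } else {
    df <- data.frame(gene_id = rownames(x$values), x$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene coordinate table
#'
#' Three+ tab-separated columns `gene_id`, `chrom`, `tss` (0-based), as
#' derived from BED/GFF gene models.
#'
#' @param path Path to the table (header optional, detected by non-numeric
#'   third field).
#' @return Data frame with `gene_id`, `chrom`, `tss`.
#' @export
read_gene_coords <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("gene_id", "chrom", "tss")
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(df)))
  df$tss <- as.numeric(df$tss)
  df
}
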