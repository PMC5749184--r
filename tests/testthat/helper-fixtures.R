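# Programmatic fixtures shared across test files.

# Toy SAM with 10 records, 2 of them unmapped; one mate on another chrom,
# one duplicate-flagged. Flags: 99/147 proper pair, 4 unmapped, 1024 dup.
write_toy_sam <- function(path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:1000000", "@SQ\tSN:chr2\tLN:1000000")
  rec <- function(qname, flag, rname, pos, rnext) {
    paste(qname, flag, rname, pos, "60", "50M", rnext, pos, "0",
          "ACGT", "IIII", sep = "\t")
  }
  body <- c(
    rec("r1", 99, "chr1", 100, "="),
    rec("r1b", 147, "chr1", 200, "="),
    rec("r2", 99, "chr1", 300, "="),
    rec("r2b", 147, "chr1", 400, "="),
    rec("r3", 1123, "chr1", 500, "="),        # 99 + 1024: duplicate
    rec("r4", 97, "chr1", 600, "chr2"),       # mate on other chromosome
    rec("r5", 99, "chr2", 700, "="),
    rec("r5b", 147, "chr2", 800, "="),
    rec("r6", 4, "*", 0, "*"),                # unmapped
    rec("r7", 4, "*", 0, "*"))                # unmapped
  writeLines(c(hdr, body), path)
  path
}

write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t50\tPASS\t.",
    "chr1\t200\t.\tC\tG\t50\tPASS\t.",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.",
    "chr1\t400\t.\tAT\tA\t50\tPASS\t."), path)   # indel, must be skipped
  path
}

toy_bins <- function(n = 4L, bs = 1e6) tile_genome(c(chr1 = n * bs), bs)

toy_counts <- function(counts, bs = 1e6, ...) {
  binned_counts(toy_bins(length(counts), bs), counts, ...)
}

# Annotated read-record table: n reads with given annotation mix and
# duplicate rate; all mapped, properly paired, same chromosome.
make_reads <- function(n_exonic, n_intronic, n_intergenic, dup_rate = 0) {
  n <- n_exonic + n_intronic + n_intergenic
  ann <- rep(c("exonic", "intronic", "intergenic"),
             c(n_exonic, n_intronic, n_intergenic))
  flag <- rep(99L, n)
  if (dup_rate > 0) {
    dup <- stats::runif(n) < dup_rate
    flag <- flag + ifelse(dup, 1024L, 0L)
  }
  read_records(flag, "chr1", pos = seq_len(n), mate_chrom = "=",
               annotation = ann)
}

# Independent CBS oracle: naive double loop over all boundary pairs for
# the max arc z statistic (same definition, independent code path).
oracle_best_split <- function(y, min_width = 3L) {
  n <- length(y)
  best <- list(stat = -Inf, i = NA, j = NA)
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):n) {
      n1 <- j - i; n2 <- n - n1
      if (n1 < min_width || n2 < min_width) next
      arc <- y[(i + 1L):j]
      comp <- y[-((i + 1L):j)]
      stat <- abs(mean(arc) - mean(comp)) * sqrt(n1 * n2 / n)
      if (stat > best$stat) best <- list(stat = stat, i = i, j = j)
    }
  }
  best
}

# An arc (i, j] and its complement give the same partition and the same
# statistic; canonicalize a split to its interior cut points for comparison.
canonical_cuts <- function(split, n) sort(setdiff(c(split$i, split$j), c(0L, n)))

# Adjusted Rand index between two label vectors (independent oracle for
# clustering checks; standard contingency-table formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Truth with a gain (cn 3) and a loss (cn 1) planted on a diploid
# background; breakpoints after bins 40, 70, 90, 110 of 120.
planted_truth <- function(seed = 1L, bias_sigma = 0, bias_rho = 0) {
  bins <- tile_genome(c(chr1 = 120e6), 1e6)
  cn <- rep(2L, 120)
  cn[41:70] <- 3L
  cn[91:110] <- 1L
  sim_truth(bins = bins, cn_profile = cn, bias_sigma = bias_sigma,
            bias_rho = bias_rho, seed = seed)
}
planted_breaks <- c(40L, 70L, 90L, 110L)
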