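#' Default pipeline configuration
#'
#' Returns the full synthetic-run configuration as a nested list; any
#' subset of fields can be overridden via `...` (or by a JSON config file
#' through [read_pipeline_config()]). All randomness flows from `seed`.
#'
#' @param ... Named overrides of top-level fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = "scduoqc_out",
    seed = 1L,
    bin_size = 1e6,
    chrom_lengths = c(chr1 = 120e6, chr2 = 80e6),
    n_cells = 12L,
    n_genes = 2000L,
    mean_depth_per_bin = 200,
    mean_libsize = 1e5,
    bias_sigma = 0.3, bias_rho = 0.5,
    dropout_midpoint = log(5), dropout_slope = 1,
    libsize_sigma = 0.3,
    contamination_rna_in_dna = 0.05,
    contamination_dna_in_rna = 0.02,
    cn_segments = list(list(chrom = "chr1", start = 40e6, end = 70e6, cn = 3),
                       list(chrom = "chr2", start = 20e6, end = 40e6, cn = 1)),
    n_true_variants = 100L,
    snv_sensitivity = 0.85, snv_fp_rate = 20,
    cbs = list(alpha = 0.01, n_perm = 200L, min_width = 3L),
    subsample_depths = c(1e3, 5e3, 2e4),
    bins_paths = NULL, expression_path = NULL, gene_coords_path = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file of configuration fields (unknown fields error).
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(raw$chrom_lengths)) raw$chrom_lengths <- unlist(raw$chrom_lengths)
  if (!is.null(raw$cn_segments) && is.data.frame(raw$cn_segments))
    raw$cn_segments <- split(raw$cn_segments, seq_len(nrow(raw$cn_segments)))
  do.call(pipeline_config, raw)
}

truth_from_config <- function(cfg) {
  bins <- tile_genome(cfg$chrom_lengths, cfg$bin_size)
  cn <- rep(2L, nrow(bins))
  for (seg in cfg$cn_segments) {
    hit <- bins$chrom == seg$chrom & bins$start >= seg$start &
      bins$end <= seg$end
    cn[hit] <- as.integer(seg$cn)
  }
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  nv <- cfg$n_true_variants
  ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  tv <- variant_set(sample(chroms, nv, replace = TRUE),
                    sample.int(1e6, nv) - 1L, ref, alt, sample_id = "truth")
  sim_truth(bins = bins, cn_profile = cn,
            bias_sigma = cfg$bias_sigma, bias_rho = cfg$bias_rho,
            dropout_midpoint = cfg$dropout_midpoint,
            dropout_slope = cfg$dropout_slope,
            libsize_sigma = cfg$libsize_sigma,
            contamination_rna_in_dna = cfg$contamination_rna_in_dna,
            contamination_dna_in_rna = cfg$contamination_dna_in_rna,
            true_variants = tv,
            sensitivity = cfg$snv_sensitivity, fp_rate = cfg$snv_fp_rate,
            seed = cfg$seed)
}

#' Run the full synthetic evaluation pipeline
#'
#' Simulate (unless input paths are given) then genome QC, CNV profiling,
#' RNA QC and integration; per-stage TSVs, a machine-readable
#' `summary.json` and a run log are written under `cfg$out_dir`. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param cfg A [pipeline_config()] (or path to a JSON config).
#' @return The summary list, invisibly; side effect: the report directory.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("scduoqc %s | R %s | seed %d",
          as.character(utils::packageVersion("scduoqc")),
          paste(R.version$major, R.version$minor, sep = "."), cfg$seed)
  stage <- function(name, expr) {
    logline("stage %s", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(seed = cfg$seed)

  # --- simulate -------------------------------------------------------
  sim <- stage("simulate", {
    truth <- truth_from_config(cfg)
    wgs <- simulate_wgs_bins(truth, cfg$mean_depth_per_bin, cfg$n_cells)
    set.seed(cfg$seed + 7L)
    bulk_means <- stats::rlnorm(cfg$n_genes, meanlog = 1, sdlog = 1.5)
    names(bulk_means) <- sprintf("gene%04d", seq_len(cfg$n_genes))
    gcoords <- data.frame(
      gene_id = names(bulk_means),
      chrom = sample(truth$bins$chrom, cfg$n_genes, replace = TRUE),
      tss = sample.int(max(truth$bins$end), cfg$n_genes) - 1L)
    ercc <- 2^seq(0, 13, length.out = 92)
    names(ercc) <- sprintf("ERCC-%05d", seq_along(ercc))
    rna <- simulate_scrna(bulk_means, cfg$n_cells, truth,
                          ercc_inputs = ercc,
                          mean_libsize = cfg$mean_libsize,
                          gene_coords = gcoords)
    snvs <- simulate_snv_calls(truth, cfg$n_cells)
    for (i in seq_along(wgs$cells))
      write_bin_counts(wgs$cells[[i]],
                       file.path(cfg$out_dir,
                                 sprintf("wgs_cell%02d.bed", i)))
    write_expression(rna$matrix, file.path(cfg$out_dir, "expression.tsv"))
    list(truth = truth, wgs = wgs, rna = rna, snvs = snvs,
         bulk_means = bulk_means, ercc = ercc)
  })

  # --- genome QC ------------------------------------------------------
  gqc <- stage("genome-qc", {
    rows <- lapply(sim$wgs$cells, function(bc) {
      data.frame(sample = bc$sample_id,
                 cv = bin_cv(bc),
                 lorenz_auc = lorenz_curve(bc)$auc)
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, file.path(cfg$out_dir, "genome_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df
  })
  summary$genome_qc <- list(mean_cv = mean(gqc$cv),
                            mean_lorenz_auc = mean(gqc$lorenz_auc))

  # --- CNV ------------------------------------------------------------
  cnv <- stage("cnv", {
    params <- cbs_params(alpha = cfg$cbs$alpha, n_perm = cfg$cbs$n_perm,
                         min_width = cfg$cbs$min_width, seed = cfg$seed)
    profiles <- lapply(sim$wgs$cells, function(bc)
      cbs_segment(normalize_to_log2(bc), params))
    for (p in profiles)
      write_seg(p, file.path(cfg$out_dir,
                             paste0("seg_", p$sample_id, ".tsv")))
    avg <- average_profiles(profiles)
    truth_lr <- log2(sim$truth$cn_profile / 2)
    truth_prof <- cn_profile(sim$truth$bins, truth_lr, sample_id = "truth")
    r_truth <- profile_correlation(avg, truth_prof)
    list(profiles = profiles, r_truth = r_truth)
  })
  summary$cnv <- list(r_avg_vs_truth = cnv$r_truth,
                      mean_n_segments = mean(vapply(cnv$profiles,
                        function(p) nrow(p$segments), 0)))

  # --- RNA QC ---------------------------------------------------------
  rqc <- stage("rna-qc", {
    det <- detect_genes(sim$rna$matrix)
    ercc_r <- vapply(seq_len(ncol(sim$rna$spikes)), function(i)
      ercc_correlation(sim$rna$spikes[, i], sim$ercc), 0)
    hk <- select_housekeeping_genes(sim$rna$matrix)
    pass <- qc_filter_cells(sim$rna$matrix, hk, min_detected_hk = 6L)
    sat <- subsample_saturation(sim$rna$matrix$values[, 1L],
                                depths = cfg$subsample_depths,
                                n_rep = 3L, seed = cfg$seed)
    df <- data.frame(cell = colnames(sim$rna$matrix$values),
                     genes_detected = det, ercc_r = ercc_r, qc_pass = pass)
    utils::write.table(df, file.path(cfg$out_dir, "rna_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sat, file.path(cfg$out_dir, "saturation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(det = det, ercc_r = ercc_r, pass = pass)
  })
  summary$rna_qc <- list(mean_genes_detected = mean(rqc$det),
                         mean_ercc_r = mean(rqc$ercc_r),
                         n_cells_pass = sum(rqc$pass))

  # --- integrate ------------------------------------------------------
  integ <- stage("integrate", {
    be <- bin_expression(sim$rna$matrix, sim$truth$bins)
    ce <- cnv_expression_correlation(cnv$profiles[[1L]], be)
    conc <- vapply(sim$snvs, snv_concordance, 0,
                   bulk = sim$truth$true_variants)
    df <- data.frame(cell = seq_along(conc), snv_concordance = conc)
    utils::write.table(df, file.path(cfg$out_dir, "snv_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(cnv_expr_r = ce$r, mean_concordance = mean(conc))
  })
  summary$integration <- integ

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  logline("done")
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `genome-qc`, `cnv`, `rna-qc`, `integrate`,
#' `run`. See `exec/scduoqc` for the installed wrapper. Exit codes:
#' 0 success, 1 user error, 2 internal error.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code.
#' @export
scduoqc_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: scduoqc <simulate|genome-qc|cnv|rna-qc|integrate|run>",
    "[--config cfg.json] [--bins counts.bed] [--expr matrix.tsv]",
    "[--out dir] [--seed N] [--alpha A] [--nperm N] [--bin-size B]")
  if (length(args) == 0L) { message(usage); return(1L) }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i == length(args)) {
      message("bad argument: ", args[i]); return(1L)
    }
    opt[[key]] <- args[i + 1L]; i <- i + 2L
  }
  out <- tryCatch({
    cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
           else pipeline_config()
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    if (!is.null(opt$alpha)) cfg$cbs$alpha <- as.numeric(opt$alpha)
    if (!is.null(opt$nperm)) cfg$cbs$n_perm <- as.integer(opt$nperm)
    if (!is.null(opt[["bin-size"]])) cfg$bin_size <- as.numeric(opt[["bin-size"]])
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      "run" = run_pipeline(cfg),
      "simulate" = {
        truth <- truth_from_config(cfg)
        wgs <- simulate_wgs_bins(truth, cfg$mean_depth_per_bin, cfg$n_cells)
        for (i in seq_along(wgs$cells))
          write_bin_counts(wgs$cells[[i]],
                           file.path(cfg$out_dir,
                                     sprintf("wgs_cell%02d.bed", i)))
        invisible(NULL)
      },
      "genome-qc" = {
        if (is.null(opt$bins)) stop("--bins required", call. = FALSE)
        bc <- read_bin_counts(opt$bins)
        df <- data.frame(sample = bc$sample_id, cv = bin_cv(bc),
                         lorenz_auc = lorenz_curve(bc)$auc)
        utils::write.table(df, file.path(cfg$out_dir, "genome_qc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "cnv" = {
        if (is.null(opt$bins)) stop("--bins required", call. = FALSE)
        bc <- read_bin_counts(opt$bins)
        prof <- cbs_segment(normalize_to_log2(bc),
                            cbs_params(alpha = cfg$cbs$alpha,
                                       n_perm = cfg$cbs$n_perm,
                                       min_width = cfg$cbs$min_width,
                                       seed = cfg$seed))
        write_seg(prof, file.path(cfg$out_dir, "segments.tsv"))
      },
      "rna-qc" = {
        if (is.null(opt$expr)) stop("--expr required", call. = FALSE)
        em <- read_expression(opt$expr)
        df <- data.frame(cell = colnames(em$values),
                         genes_detected = detect_genes(em))
        utils::write.table(df, file.path(cfg$out_dir, "rna_qc.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      "integrate" = run_pipeline(cfg),
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  if (identical(out, 1L)) 1L else 0L
}
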