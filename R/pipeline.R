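#' Pipeline configuration
#'
#' Collects the file paths and analysis thresholds for a full run. All
#' thresholds default to the package-wide conventions: fold-change
#' cutpoints 1.50 / 0.67, FDR 0.05, miRNA detection in > 20% of normal
#' samples, 10,000 bootstrap resamples.
#'
#' @param counts,intensities,metadata,pathway_genes,protein_coding,
#'   mirna_fasta,utr_fasta input file paths (TSV matrices, metadata TSV,
#'   one-id-per-line gene lists, FASTA). `protein_coding`, `mirna_fasta`
#'   and `utr_fasta` may be `NULL` (all genes protein-coding; seed matching
#'   skipped).
#' @param fc_up,fc_down fold-change cutpoints; must satisfy
#'   `0 < fc_down < 1 < fc_up`.
#' @param fdr_alpha FDR significance level in (0, 1).
#' @param mirna_expr_frac miRNA detection-fraction threshold (default 0.20).
#' @param bootstrap_B bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap streams.
#' @param strata character subset of `c("overall", "MSI", "MSS")` for the
#'   differential-expression runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, intensities, metadata, pathway_genes,
                            protein_coding = NULL, mirna_fasta = NULL,
                            utr_fasta = NULL, fc_up = 1.50, fc_down = 0.67,
                            fdr_alpha = 0.05, mirna_expr_frac = 0.20,
                            bootstrap_B = 10000, seed = 1L,
                            strata = "overall") {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  if (!(is.numeric(cfg$fc_down) && is.numeric(cfg$fc_up) &&
        cfg$fc_down > 0 && cfg$fc_down < 1 && cfg$fc_up > 1))
    pm_stop("cutpoints must satisfy 0 < fc_down < 1 < fc_up",
            class = "pairmir_config_error")
  if (!(cfg$fdr_alpha > 0 && cfg$fdr_alpha < 1))
    pm_stop("fdr_alpha must lie in (0, 1)", class = "pairmir_config_error")
  bad <- setdiff(cfg$strata, c("overall", "MSI", "MSS"))
  if (length(bad) > 0)
    pm_stop(sprintf("unknown stratum: %s", paste(bad, collapse = ", ")),
            class = "pairmir_config_error")
  cfg
}

#' Run the full analysis chain
#'
#' Normalization (RPMPCG and q75), per-stratum paired differential
#' expression, miRNA expression filtering, differential-profile
#' association testing with the bootstrap F null, seed-region annotation,
#' and report rendering. Stage-level counts (genes passing cutpoints,
#' miRNAs passing the expression filter, significant associations, seed
#' matches) are logged via `message()`, and every result table is written
#' as TSV when `out_dir` is given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for result TSVs.
#' @return list with `de` (rbind over strata), `mirna_kept`, `assoc`,
#'   `seeds`, `report`, `summary` (cohort summary) and `manifest` (written
#'   files, when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  counts <- read_matrix(config$counts)
  intensity <- read_matrix(config$intensities)
  md <- read_metadata(config$metadata)
  pathway <- read_gene_list(config$pathway_genes)
  pc_ids <- if (!is.null(config$protein_coding))
    read_gene_list(config$protein_coding) else rownames(counts)
  message(sprintf("inputs: %d genes x %d samples, %d miRNAs, %d pathway genes",
                  nrow(counts), ncol(counts), nrow(intensity),
                  length(pathway)))

  cohort <- structure(list(gene_counts = counts, mirna_intensity = intensity,
                           metadata = md, pathway_genes = pathway,
                           protein_coding_ids = pc_ids),
                      class = "paired_cohort")
  cohort_sum <- summarize_cohort(md)

  # --- differential expression per stratum ---------------------------------
  de <- do.call(rbind, lapply(config$strata, function(s)
    run_de(cohort, gene_set = pathway, stratum = s, fc_up = config$fc_up,
           fc_down = config$fc_down)))
  sig_de <- de[!is.na(de$fdr_p) & de$fdr_p <= config$fdr_alpha &
                 de$direction %in% c("up", "down"), , drop = FALSE]
  dys_genes <- sort(unique(sig_de$gene))  # union across strata
  message(sprintf("differential expression: %d of %d pathway genes beyond %0.2f/%0.2f at FDR %0.2f (union over %s)",
                  length(dys_genes), length(pathway), config$fc_down,
                  config$fc_up, config$fdr_alpha,
                  paste(config$strata, collapse = "/")))

  # --- normalization and filtering for the association stage ---------------
  norm_counts <- rpmpcg(counts, pc_ids)
  norm_mirna <- q75_scale(intensity)
  normal_ids <- md$sample_id[md$tissue_status == "normal"]
  mirna_kept <- expression_filter(
    norm_mirna$values[, normal_ids, drop = FALSE],
    min_frac_expressed = config$mirna_expr_frac)
  message(sprintf("miRNA filter: %d of %d detected in > %d%% of normal samples",
                  length(mirna_kept), nrow(intensity),
                  round(100 * config$mirna_expr_frac)))

  gene_diffs <- differential_profile(norm_counts, md)
  mirna_diffs <- differential_profile(norm_mirna, md)

  overall_de <- de[de$stratum == "overall", , drop = FALSE]
  if (nrow(overall_de) == 0) overall_de <- de
  gene_fc <- stats::setNames(overall_de$ratio_of_means, overall_de$gene)
  is_tumor <- md$tissue_status == "tumor"
  mirna_fc <- rowMeans(norm_mirna$values[, is_tumor, drop = FALSE]) /
    rowMeans(norm_mirna$values[, !is_tumor, drop = FALSE])

  assoc <- run_associations(
    gene_diffs, mirna_diffs, candidate_genes = dys_genes,
    candidate_mirnas = mirna_kept, metadata = md, gene_fc = gene_fc,
    mirna_fc = mirna_fc, mirna_norm = norm_mirna, B = config$bootstrap_B,
    seed = config$seed, fdr_alpha = config$fdr_alpha,
    fc_up = config$fc_up, fc_down = config$fc_down)
  n_sig <- sum(assoc$significant)
  message(sprintf("associations: %d significant of %d tested pairs (%d genes x %d miRNAs)",
                  n_sig, nrow(assoc), length(dys_genes), length(mirna_kept)))

  # --- seed matching --------------------------------------------------------
  seeds <- NULL
  if (!is.null(config$mirna_fasta) && !is.null(config$utr_fasta) &&
      n_sig > 0) {
    mirna_seqs <- read_fasta(config$mirna_fasta)
    utr_seqs <- read_fasta(config$utr_fasta)
    seeds <- annotate_associations(assoc[assoc$significant, , drop = FALSE],
                                   mirna_seqs, utr_seqs)
    message(sprintf("seed matching: %d (pair, length) matches over %d significant pairs (%d inverse)",
                    nrow(seeds), n_sig,
                    sum(seeds$direction_class == "inverse")))
  }
  if (is.null(seeds))
    seeds <- annotate_associations(
      data.frame(gene = character(0), mirna = character(0),
                 gene_fc = numeric(0), mirna_fc = numeric(0)),
      character(0), character(0))

  report <- report_association_table(
    de[de$stratum == de$stratum[1], , drop = FALSE], assoc, seeds)

  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    w <- function(df, f) {
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      file.path(out_dir, f)
    }
    manifest <- c(de = w(de, "differential_expression.tsv"),
                  assoc = w(assoc, "associations.tsv"),
                  seeds = w(seeds, "seed_matches.tsv"),
                  report = w(report, "association_report.tsv"),
                  mirna_kept = {
                    writeLines(mirna_kept,
                               file.path(out_dir, "mirna_retained.txt"))
                    file.path(out_dir, "mirna_retained.txt")
                  })
  }
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  list(de = de, mirna_kept = mirna_kept, assoc = assoc, seeds = seeds,
       report = report, summary = cohort_sum, manifest = manifest)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `run-pipeline.R` script installed under
#' `inst/scripts`. Subcommands: `simulate` (write a synthetic cohort),
#' `all` (full chain via [run_pipeline()]). Flags: `--dir` (cohort/input
#' directory), `--out` (output directory), `--seed`, `--subjects`,
#' `--genes`, `--mirnas`, `--bootstrap-B`. Unknown flags or subcommands
#' print a usage message and return exit status 2.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 success, 1 stage error, 2 usage error).
#' @export
pipeline_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: run-pipeline.R <simulate|all> --dir DIR [--out DIR]\n",
        "  [--seed INT] [--subjects INT] [--genes INT] [--mirnas INT]\n",
        "  [--bootstrap-B INT]\n", sep = "")
    2L
  }
  if (length(argv) == 0) return(usage())
  cmd <- argv[1]
  opts <- list(seed = 1L, subjects = NULL, genes = NULL, mirnas = NULL,
               `bootstrap-B` = 10000L, dir = NULL, out = NULL)
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!startsWith(argv[i], "--") || !key %in% names(opts) ||
        i == length(argv)) {
      cat(sprintf("unknown or incomplete flag: %s\n", argv[i]))
      return(usage())
    }
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (is.null(opts$dir)) {
    cat("missing required flag: --dir\n")
    return(usage())
  }
  status <- tryCatch({
    if (cmd == "simulate") {
      cfg_args <- list(seed = as.integer(opts$seed))
      if (!is.null(opts$subjects))
        cfg_args$n_subjects <- as.integer(opts$subjects)
      if (!is.null(opts$genes)) cfg_args$n_genes <- as.integer(opts$genes)
      if (!is.null(opts$mirnas)) cfg_args$n_mirnas <- as.integer(opts$mirnas)
      sim <- generate_cohort(do.call(sim_config, cfg_args))
      write_cohort(sim$cohort, opts$dir, sim$truth)
      0L
    } else if (cmd == "all") {
      p <- function(f) file.path(opts$dir, f)
      cfg <- pipeline_config(
        counts = p("gene_counts.tsv"), intensities = p("mirna_intensity.tsv"),
        metadata = p("metadata.tsv"), pathway_genes = p("pathway_genes.txt"),
        protein_coding = if (file.exists(p("protein_coding.txt")))
          p("protein_coding.txt"),
        mirna_fasta = if (file.exists(p("mirna_sequences.fasta")))
          p("mirna_sequences.fasta"),
        utr_fasta = if (file.exists(p("utr_sequences.fasta")))
          p("utr_sequences.fasta"),
        bootstrap_B = as.integer(opts$`bootstrap-B`),
        seed = as.integer(opts$seed))
      run_pipeline(cfg, out_dir = opts$out %||% file.path(opts$dir, "results"))
      0L
    } else {
      cat(sprintf("unknown subcommand: %s\n", cmd))
      usage()
    }
  }, error = function(e) {
    cat(sprintf("error: %s\n", conditionMessage(e)))
    1L
  })
  status
}
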