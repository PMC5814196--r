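#' Configuration for the synthetic paired-cohort generator
#'
#' Builds and validates a simulation configuration. The defaults emulate
#' the scale and composition of a large paired colorectal tumor/normal
#' study — 217 subject pairs, 13.4% microsatellite-instable (MSI) tumors,
#' age 64.8 (SD 10.1) years — with the gene and miRNA panels reduced to
#' desk scale so that full pipeline runs stay fast. Fractions dysregulated
#' default to 0.375, the genome-wide rate observed in colorectal tumors for
#' fold changes beyond the 1.50/0.67 cutpoints.
#'
#' @param n_subjects number of tumor/normal pairs (default 217).
#' @param n_genes total protein-coding genes simulated (default 400).
#' @param n_pathway_genes genes designated as the pathway panel, taken as
#'   the first `n_pathway_genes` gene ids (default 30).
#' @param n_mirnas number of miRNAs (default 60).
#' @param frac_genes_dysregulated fraction of genes given a planted
#'   tumor/normal fold change (default 0.375; split evenly up/down).
#' @param fc_up_range fold-change interval for up-regulated genes
#'   (default `c(1.5, 7)`, spanning the strongest dysregulation reported
#'   for pathway genes).
#' @param fc_down_range interval in (0, 1) for down-regulated genes
#'   (default `c(0.28, 0.67)`).
#' @param nb_dispersion negative binomial size parameter k of the NB2
#'   parameterization, variance = mu + mu^2 / k (default 8).
#' @param subject_effect_sd SD of the log-normal subject intercept
#'   (default 0.4).
#' @param library_size_range per-sample total-count interval
#'   (default `c(2e5, 8e5)`).
#' @param mirna_noise_sd log-scale noise SD for miRNA intensities
#'   (default 0.4).
#' @param n_couplings number of planted gene::miRNA couplings (default 10).
#' @param coupling_effect_range interval of coupling slopes, on the scale
#'   RPMPCG differential per intensity differential (default `c(0.2, 0.4)`,
#'   matching the magnitude of reported association betas).
#' @param frac_seed_planted fraction of couplings whose miRNA also gets a
#'   seed-complementary site written into the gene's 3'UTR (default 0.4).
#' @param msi_fraction fraction of subjects with MSI tumors (default 0.134).
#' @param age_mean_sd numeric pair, mean and SD of subject age in years
#'   (default `c(64.8, 10.1)`).
#' @param mirna_length length of simulated mature miRNAs (default 22 nt).
#' @param utr_length length of simulated 3'UTRs (default 500 nt).
#' @param seed integer random seed driving the single generator stream.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 217, n_genes = 400,
                       n_pathway_genes = 30, n_mirnas = 60,
                       frac_genes_dysregulated = 0.375,
                       fc_up_range = c(1.5, 7),
                       fc_down_range = c(0.28, 0.67),
                       nb_dispersion = 8, subject_effect_sd = 0.4,
                       library_size_range = c(2e5, 8e5),
                       mirna_noise_sd = 0.4, n_couplings = 10,
                       coupling_effect_range = c(0.2, 0.4),
                       frac_seed_planted = 0.4, msi_fraction = 0.134,
                       age_mean_sd = c(64.8, 10.1), mirna_length = 22,
                       utr_length = 500, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' Default generator configuration
#'
#' Convenience wrapper returning [sim_config()] with all defaults: the
#' study-scale paired design (217 subjects, 13.4% MSI) at desk-scale gene
#' and miRNA counts.
#'
#' @return a `sim_config`.
#' @export
default_config <- function() sim_config()

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) pm_stop(sprintf("invalid sim_config field '%s': %s", field, why),
                     class = "pairmir_config_error")
  }
  count1 <- function(x) is.numeric(x) && length(x) == 1 && x >= 1 &&
    x == floor(x)
  prop <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  pos <- function(x) is.numeric(x) && length(x) == 1 && x > 0
  ival <- function(x) is.numeric(x) && length(x) == 2 && x[1] <= x[2]

  chk(count1(cfg$n_subjects), "n_subjects", "must be a count >= 1")
  chk(count1(cfg$n_genes), "n_genes", "must be a count >= 1")
  chk(count1(cfg$n_pathway_genes), "n_pathway_genes", "must be a count >= 1")
  chk(count1(cfg$n_mirnas), "n_mirnas", "must be a count >= 1")
  chk(cfg$n_pathway_genes <= cfg$n_genes, "n_pathway_genes",
      "cannot exceed n_genes")
  chk(prop(cfg$frac_genes_dysregulated), "frac_genes_dysregulated",
      "must be a proportion in [0,1]")
  chk(prop(cfg$frac_seed_planted), "frac_seed_planted",
      "must be a proportion in [0,1]")
  chk(prop(cfg$msi_fraction), "msi_fraction", "must be a proportion in [0,1]")
  chk(ival(cfg$fc_up_range) && all(cfg$fc_up_range > 1), "fc_up_range",
      "must be an interval of fold changes > 1")
  chk(ival(cfg$fc_down_range) && all(cfg$fc_down_range > 0) &&
        all(cfg$fc_down_range < 1), "fc_down_range",
      "must be an interval within (0,1)")
  chk(pos(cfg$nb_dispersion), "nb_dispersion", "must be > 0")
  chk(pos(cfg$subject_effect_sd), "subject_effect_sd", "must be > 0")
  chk(pos(cfg$mirna_noise_sd), "mirna_noise_sd", "must be > 0")
  chk(ival(cfg$library_size_range) && all(cfg$library_size_range > 0),
      "library_size_range", "must be an interval of positive reals")
  chk(is.numeric(cfg$n_couplings) && length(cfg$n_couplings) == 1 &&
        cfg$n_couplings >= 0 && cfg$n_couplings == floor(cfg$n_couplings),
      "n_couplings", "must be a nonnegative count")
  chk(cfg$n_couplings <= cfg$n_pathway_genes * cfg$n_mirnas, "n_couplings",
      "cannot exceed n_pathway_genes * n_mirnas")
  chk(ival(cfg$coupling_effect_range), "coupling_effect_range",
      "must be a numeric interval")
  chk(is.numeric(cfg$age_mean_sd) && length(cfg$age_mean_sd) == 2 &&
        cfg$age_mean_sd[2] > 0, "age_mean_sd", "must be (mean, sd>0)")
  chk(count1(cfg$mirna_length) && cfg$mirna_length >= 9, "mirna_length",
      "must be a count >= 9")
  chk(count1(cfg$utr_length) && cfg$utr_length >= 8, "utr_length",
      "must be a count >= 8")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed", "must be a finite integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: %d pairs, %d genes (%d pathway), %d miRNAs, seed %d>\n",
    x$n_subjects, x$n_genes, x$n_pathway_genes, x$n_mirnas,
    as.integer(x$seed)))
  invisible(x)
}

#' Generate a synthetic paired tumor/normal cohort
#'
#' Simulates a paired cohort with the structure the downstream stages
#' assume, and the planted ground truth needed to test their recovery:
#'
#' * Gene counts for sample s of subject i are negative binomial (NB2,
#'   size `nb_dispersion`) with mean
#'   `L_s * u_i * m_g * FC_g^tumor(s)`, where `L_s` is the library size,
#'   `u_i` a shared log-normal subject intercept (SD `subject_effect_sd` on
#'   the log scale), `m_g` a baseline relative abundance and `FC_g` the
#'   planted fold change (1 for non-dysregulated genes).
#' * miRNA intensities are log-normal with planted miRNA fold changes and
#'   log-scale noise SD `mirna_noise_sd`.
#' * Each planted coupling (gene g, miRNA j, slope b) shifts g's expected
#'   subject-level tumor-normal RPMPCG differential by b times that
#'   subject's realized miRNA intensity differential — the exact scale on
#'   which the association stage regresses.
#' * For `frac_seed_planted` of the couplings, the reverse complement of
#'   one of the miRNA's seeds is written into the gene's UTR at a recorded
#'   position.
#'
#' Output is deterministic given `config$seed`; all randomness flows
#' through one seeded stream, and the caller's RNG state is untouched.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (class `paired_cohort`: gene counts,
#'   miRNA intensities, metadata, miRNA and UTR sequences) and `truth`
#'   (class `sim_truth`: `true_fc_by_gene`, `mirna_fc`, `couplings`,
#'   `planted_sites`).
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  pathway <- genes[seq_len(cfg$n_pathway_genes)]
  mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  subjects <- sprintf("subj%03d", seq_len(n))

  # --- subjects and samples -------------------------------------------------
  meta <- data.frame(
    sample_id = c(paste0(subjects, "_N"), paste0(subjects, "_T")),
    subject_id = rep(subjects, 2),
    tissue_status = rep(c("normal", "tumor"), each = n),
    stringsAsFactors = FALSE
  )
  age <- rnorm(n, cfg$age_mean_sd[1], cfg$age_mean_sd[2])
  sex <- ifelse(runif(n) < 0.544, "M", "F")          # male-majority cohort
  msi <- ifelse(runif(n) < cfg$msi_fraction, "MSI", "MSS")
  site <- ifelse(runif(n) < 0.779, "colon", "rectal")
  idx <- match(meta$subject_id, subjects)
  meta$age <- round(age[idx], 1)
  meta$sex <- sex[idx]
  meta$msi_status <- msi[idx]
  meta$site <- site[idx]

  # --- planted gene fold changes -------------------------------------------
  # dysregulation stratified over the pathway panel and the background, so
  # the panel always carries its share of planted effects
  rest <- setdiff(genes, pathway)
  dys <- sample(c(
    sample(pathway, round(cfg$frac_genes_dysregulated * length(pathway))),
    sample(rest, round(cfg$frac_genes_dysregulated * length(rest)))))
  n_dys <- length(dys)
  n_up <- ceiling(n_dys / 2)
  fc <- stats::setNames(rep(1, cfg$n_genes), genes)
  if (n_dys > 0) {
    up <- dys[seq_len(n_up)]
    down <- setdiff(dys, up)
    fc[up] <- runif(length(up), cfg$fc_up_range[1], cfg$fc_up_range[2])
    fc[down] <- runif(length(down), cfg$fc_down_range[1], cfg$fc_down_range[2])
  }

  # --- gene baseline abundances --------------------------------------------
  m_g <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.2)
  names(m_g) <- genes
  # Balance the abundance mass moved up against the mass moved down, so the
  # tumor protein-coding total keeps the normal expectation and planted fold
  # changes are realized exactly on the normalized (per-total) scale. Without
  # this, strong asymmetric dysregulation would shift every normalized fold
  # change by the ratio of totals (compositional bias).
  up_set <- genes[fc > 1]; down_set <- genes[fc < 1]
  gain <- sum(m_g[up_set] * (fc[up_set] - 1))
  loss <- sum(m_g[down_set] * (1 - fc[down_set]))
  if (gain > 0 && loss > 0) m_g[down_set] <- m_g[down_set] * gain / loss
  m_g <- m_g / sum(m_g)                      # baseline relative abundance
  M_total <- sum(m_g)                        # = 1 by construction

  # --- miRNA fold changes and couplings ------------------------------------
  mirna_fc <- stats::setNames(rep(1, cfg$n_mirnas), mirnas)
  n_mdys <- round(cfg$frac_genes_dysregulated * cfg$n_mirnas)
  if (n_mdys > 0) {
    mdys <- sample(mirnas, n_mdys)
    mup <- mdys[seq_len(ceiling(n_mdys / 2))]
    mdown <- setdiff(mdys, mup)
    mirna_fc[mup] <- runif(length(mup), cfg$fc_up_range[1], cfg$fc_up_range[2])
    mirna_fc[mdown] <- runif(length(mdown), cfg$fc_down_range[1],
                             cfg$fc_down_range[2])
  }
  base_int <- stats::setNames(
    rlnorm(cfg$n_mirnas, meanlog = 2.5, sdlog = 1), mirnas)  # ~12 median

  # Couplings join dysregulated pathway genes to miRNAs that are themselves
  # given a dysregulated fold change, mirroring the discovery structure the
  # pipeline encodes (only FC-qualified genes and miRNAs enter the
  # significant set). Falls back to the full panel when nothing is planted.
  pathway_dys <- pathway[fc[pathway] != 1]
  if (length(pathway_dys) == 0) pathway_dys <- pathway
  # each coupled miRNA regulates a single gene (its base intensity is
  # calibrated to that gene's scale below); a gene may have several miRNAs
  n_cpl <- min(cfg$n_couplings, cfg$n_mirnas)
  couplings <- data.frame(
    gene = sample(pathway_dys, n_cpl, replace = TRUE),
    mirna = sample(mirnas, n_cpl),
    stringsAsFactors = FALSE)
  couplings$effect <- runif(nrow(couplings), cfg$coupling_effect_range[1],
                            cfg$coupling_effect_range[2]) *
    sample(c(-1, 1), nrow(couplings), replace = TRUE)
  for (j in unique(couplings$mirna)) {
    if (mirna_fc[j] == 1) {
      mirna_fc[j] <- if (runif(1) < 0.5)
        runif(1, cfg$fc_up_range[1], cfg$fc_up_range[2])
      else runif(1, cfg$fc_down_range[1], cfg$fc_down_range[2])
    }
  }
  # A coupled miRNA is given a base intensity calibrated so that the
  # injected differential signal (effect x miRNA differential) has SD near
  # a quarter of the target gene's baseline RPMPCG: commensurate with the
  # gene's expression scale (detectable at cohort size) yet small enough
  # that the shifted tumor mean virtually never truncates at zero.
  lognorm_cv <- sqrt(exp(cfg$mirna_noise_sd^2) - 1) *
    exp(cfg$mirna_noise_sd^2 / 2)
  for (j in unique(couplings$mirna)) {
    rows <- couplings$mirna == j
    tg <- couplings$gene[rows]
    # the larger of the gene's two group abundances carries the injection
    r_bar <- 1e6 * min(pmax(m_g[tg], m_g[tg] * fc[tg])) / M_total
    b_bar <- mean(abs(couplings$effect[rows]))
    diff_sd_per_unit <- lognorm_cv * sqrt(1 + mirna_fc[j]^2)
    base_int[j] <- 0.25 * r_bar / (b_bar * diff_sd_per_unit)
  }

  # --- miRNA intensities ----------------------------------------------------
  # intensity(j, sample) = base_j * FC_j^tumor * exp(noise)
  tumor_col <- meta$tissue_status == "tumor"
  logint <- matrix(log(base_int), cfg$n_mirnas, 2 * n) +
    outer(log(mirna_fc), as.numeric(tumor_col)) +
    matrix(rnorm(cfg$n_mirnas * 2 * n, 0, cfg$mirna_noise_sd),
           cfg$n_mirnas, 2 * n)
  intensity <- exp(logint)
  dimnames(intensity) <- list(mirnas, meta$sample_id)

  # subject-level miRNA intensity differentials; couplings inject the raw
  # (pre-scaling) differential so that no normalization noise — which the
  # q75 factors share across all miRNAs of a sample — leaks into the gene
  # counts and correlates them with uncoupled miRNAs
  norm_cols <- match(paste0(subjects, "_N"), meta$sample_id)
  tum_cols <- match(paste0(subjects, "_T"), meta$sample_id)
  mirna_diff <- intensity[, tum_cols, drop = FALSE] -
    intensity[, norm_cols, drop = FALSE]  # miRNA x subject

  # --- gene counts ----------------------------------------------------------
  L <- runif(2 * n, cfg$library_size_range[1], cfg$library_size_range[2])
  u <- exp(rnorm(n, 0, cfg$subject_effect_sd))[idx]  # per sample via subject

  # expected relative abundance per gene x sample, with coupling shifts on
  # the tumor side expressed in RPMPCG units (1e6 * m / M_total)
  rel <- m_g %o% rep(1, 2 * n)                       # n_genes x samples
  dimnames(rel) <- list(genes, meta$sample_id)
  rel[, tumor_col] <- rel[, tumor_col] * fc
  if (nrow(couplings) > 0) {
    for (k in seq_len(nrow(couplings))) {
      g <- couplings$gene[k]; j <- couplings$mirna[k]
      # centered differential: the slope seen by the regression is exactly
      # `effect`, while the gene's planted mean fold change is untouched
      d <- mirna_diff[j, ] - mean(mirna_diff[j, ])
      shift <- couplings$effect[k] * d * M_total / 1e6
      # realize the differential gain on the gene's larger group (add to
      # the tumor side for up/null genes, subtract from the normal side for
      # down genes) so the shifted mean virtually never truncates at zero
      if (fc[g] >= 1) {
        rel[g, tum_cols] <- pmax(rel[g, tum_cols] + shift, 1e-12)
      } else {
        rel[g, norm_cols] <- pmax(rel[g, norm_cols] - shift, 1e-12)
      }
    }
  }
  mu <- sweep(rel, 2, L * u, `*`)
  counts <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu),
                   nrow = cfg$n_genes)
  dimnames(counts) <- list(genes, meta$sample_id)

  # --- sequences ------------------------------------------------------------
  mirna_seqs <- stats::setNames(
    vapply(seq_len(cfg$n_mirnas), function(i)
      paste(sample(c("A", "C", "G", "U"), cfg$mirna_length, replace = TRUE),
            collapse = ""), character(1)), mirnas)
  utr_seqs <- stats::setNames(
    vapply(seq_len(cfg$n_genes), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$utr_length, replace = TRUE),
            collapse = ""), character(1)), genes)

  planted <- data.frame(mirna = character(0), gene = character(0),
                        seed_length = integer(0), utr_position = integer(0),
                        stringsAsFactors = FALSE)
  n_plant <- round(cfg$frac_seed_planted * nrow(couplings))
  if (n_plant > 0) {
    chosen <- sample(nrow(couplings), n_plant)
    occupied <- list()  # per gene: windows already written
    for (k in chosen) {
      g <- couplings$gene[k]; j <- couplings$mirna[k]
      len <- sample(c(6L, 7L, 8L), 1)
      seeds <- extract_seeds(mirna_seqs[[j]])
      site <- reverse_complement_dna(seeds$seed[seeds$seed_length == len])
      pos <- plant_window(cfg$utr_length, len, occupied[[g]] %||% integer(0))
      if (is.na(pos)) next
      substr(utr_seqs[[g]], pos + 1L, pos + len) <- site
      occupied[[g]] <- c(occupied[[g]], seq(pos + 1L, pos + len))
      planted <- rbind(planted, data.frame(
        mirna = j, gene = g, seed_length = len, utr_position = pos,
        stringsAsFactors = FALSE))
    }
  }

  cohort <- structure(list(
    gene_counts = counts, mirna_intensity = intensity, metadata = meta,
    mirna_sequences = mirna_seqs, utr_sequences = utr_seqs,
    pathway_genes = pathway, protein_coding_ids = genes
  ), class = "paired_cohort")
  truth <- structure(list(
    true_fc_by_gene = fc, mirna_fc = mirna_fc, couplings = couplings,
    planted_sites = planted
  ), class = "sim_truth")
  list(cohort = cohort, truth = truth)
}

# A random start (0-based) for a window of `len` in a UTR of `utr_len` that
# does not touch 1-based positions in `occupied`; NA when no slot is free.
plant_window <- function(utr_len, len, occupied) {
  starts <- 0:(utr_len - len)
  free <- vapply(starts, function(p)
    !any(seq(p + 1L, p + len) %in% occupied), logical(1))
  if (!any(free)) return(NA_integer_)
  candidates <- starts[free]
  candidates[sample.int(length(candidates), 1)]
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf(
    "<paired_cohort: %d genes x %d samples, %d miRNAs, %d subjects>\n",
    nrow(x$gene_counts), ncol(x$gene_counts), nrow(x$mirna_intensity),
    length(unique(x$metadata$subject_id))))
  invisible(x)
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `gene_counts.tsv`, `mirna_intensity.tsv`, `metadata.tsv`,
#' `mirna_sequences.fasta`, `utr_sequences.fasta`, `pathway_genes.txt` and
#' `protein_coding.txt`, plus `truth.json` when ground truth is supplied.
#' All files round-trip losslessly through the package's readers.
#'
#' @param cohort a `paired_cohort`.
#' @param directory output directory (created if absent).
#' @param truth optional `sim_truth` to serialize as JSON.
#' @return named character vector: manifest of written files.
#' @export
write_cohort <- function(cohort, directory, truth = NULL) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0)
    pm_stop(sprintf("directory not writable: %s", directory))
  p <- function(f) file.path(directory, f)
  write_matrix(cohort$gene_counts, p("gene_counts.tsv"))
  write_matrix(cohort$mirna_intensity, p("mirna_intensity.tsv"))
  utils::write.table(cohort$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(cohort$mirna_sequences, p("mirna_sequences.fasta"))
  write_fasta(cohort$utr_sequences, p("utr_sequences.fasta"))
  writeLines(cohort$pathway_genes, p("pathway_genes.txt"))
  writeLines(cohort$protein_coding_ids, p("protein_coding.txt"))
  manifest <- c(gene_counts = p("gene_counts.tsv"),
                mirna_intensity = p("mirna_intensity.tsv"),
                metadata = p("metadata.tsv"),
                mirna_sequences = p("mirna_sequences.fasta"),
                utr_sequences = p("utr_sequences.fasta"),
                pathway_genes = p("pathway_genes.txt"),
                protein_coding = p("protein_coding.txt"))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(true_fc_by_gene = as.list(truth$true_fc_by_gene),
           mirna_fc = as.list(truth$mirna_fc),
           couplings = truth$couplings,
           planted_sites = truth$planted_sites),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    manifest <- c(manifest, truth = p("truth.json"))
  }
  manifest
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param directory directory holding the cohort files.
#' @return a `paired_cohort`.
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  structure(list(
    gene_counts = read_matrix(p("gene_counts.tsv")),
    mirna_intensity = read_matrix(p("mirna_intensity.tsv")),
    metadata = read_metadata(p("metadata.tsv")),
    mirna_sequences = if (file.exists(p("mirna_sequences.fasta")))
      read_fasta(p("mirna_sequences.fasta")),
    utr_sequences = if (file.exists(p("utr_sequences.fasta")))
      read_fasta(p("utr_sequences.fasta")),
    pathway_genes = if (file.exists(p("pathway_genes.txt")))
      read_gene_list(p("pathway_genes.txt")),
    protein_coding_ids = if (file.exists(p("protein_coding.txt")))
      read_gene_list(p("protein_coding.txt"))
  ), class = "paired_cohort")
}
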