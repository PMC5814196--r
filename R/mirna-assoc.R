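#' Subject-level differential expression profile
#'
#' For every feature, the per-subject tumor-minus-normal difference of
#' (normalized) expression: the scale on which miRNA::mRNA associations
#' are modeled.
#'
#' @param expr `normalized_matrix` or numeric matrix, features x samples.
#' @param metadata per-sample metadata with `sample_id`, `subject_id`,
#'   `tissue_status`; every subject must have exactly one tumor and one
#'   normal sample present in `expr`.
#' @return numeric matrix, features x subjects, of tumor - normal
#'   differences; colnames are subject ids.
#' @export
differential_profile <- function(expr, metadata) {
  expr <- as_feature_matrix(expr, "expr")
  md <- validate_metadata(metadata)
  missing_samples <- setdiff(md$sample_id, colnames(expr))
  if (length(missing_samples) > 0)
    pm_stop(sprintf("metadata samples absent from matrix: %s",
                    paste(utils::head(missing_samples, 5), collapse = ", ")))
  subjects <- paired_subjects(md)  # errors naming unpaired subjects
  t_ids <- md$sample_id[match(paste0(subjects, ".tumor"),
                              paste0(md$subject_id, ".", md$tissue_status))]
  n_ids <- md$sample_id[match(paste0(subjects, ".normal"),
                              paste0(md$subject_id, ".", md$tissue_status))]
  diff <- expr[, t_ids, drop = FALSE] - expr[, n_ids, drop = FALSE]
  colnames(diff) <- subjects
  diff
}

#' Least-squares gene::miRNA differential association
#'
#' Ordinary least squares of the gene's differential profile on the
#' miRNA's differential profile with age and sex covariates:
#' `gene_diff ~ mirna_diff + age + sex`. The reported F statistic is the
#' partial F for dropping `mirna_diff` (full model vs the covariate-only
#' null).
#'
#' @param gene_diff,mirna_diff per-subject differentials (same length).
#' @param age per-subject age in years.
#' @param sex per-subject sex, coded 0/1 or as a two-level factor/character
#'   (coded to an indicator internally).
#' @return list with `beta` (slope on `mirna_diff`), `f_stat` (partial F;
#'   `Inf` for an exact fit) and `df` (numerator = 1, denominator).
#' @export
fit_association <- function(gene_diff, mirna_diff, age, sex) {
  X <- assoc_design(mirna_diff, age, sex)
  n <- length(gene_diff)
  if (length(mirna_diff) != n || length(age) != n || nrow(X) != n)
    pm_stop("gene_diff, mirna_diff, age and sex must have equal length")
  if (n < 5) pm_stop("at least 5 subjects are required")
  if (qr(X)$rank < ncol(X))
    pm_stop("design matrix is rank deficient (constant miRNA differential or collinear covariates)")
  f <- partial_f(gene_diff, X)
  list(beta = f$beta, f_stat = f$f_stat, df = c(1L, n - ncol(X)))
}

# Full design: intercept, mirna_diff, age, sex indicator. Column 2 is the
# tested term.
assoc_design <- function(mirna_diff, age, sex) {
  sex_num <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  cbind(`(Intercept)` = 1, mirna_diff = mirna_diff, age = age, sex = sex_num)
}

# Partial F for the second column of X, plus its OLS slope. Handles an
# exact fit (residual SS ~ 0) by returning f_stat = Inf.
partial_f <- function(y, X) {
  qr_full <- qr(X)
  qr_null <- qr(X[, -2, drop = FALSE])
  rss1 <- sum(qr.resid(qr_full, y)^2)
  rss0 <- sum(qr.resid(qr_null, y)^2)
  df2 <- length(y) - ncol(X)
  beta <- qr.coef(qr_full, y)[2]
  scale <- rss0 + rss1
  if (scale <= 0 || rss1 <= 1e-12 * scale) {
    f <- if (rss0 > rss1) Inf else 0
  } else {
    f <- (rss0 - rss1) / (rss1 / df2)
  }
  list(beta = unname(beta), f_stat = f, rss_full = rss1, rss_null = rss0)
}

#' Bootstrap p-value for a gene::miRNA association
#'
#' Builds the null distribution of the partial F statistic by residual
#' resampling: the covariate-only null model (`gene_diff ~ age + sex`) is
#' fit once; `B` times, its residuals are resampled with replacement and
#' added to the null fitted values, and the partial F for `mirna_diff` is
#' recomputed on the resampled response. The p-value uses the Monte-Carlo
#' `+1` convention, `p = (1 + #\{F* >= F_obs\}) / (B + 1)`, so the minimum
#' attainable value is `1/(B+1)`. Deterministic given `seed`.
#'
#' @inheritParams fit_association
#' @param B number of bootstrap resamples (>= 100; default 10000).
#' @param seed integer seed for the resampling stream.
#' @return list with `p` (bootstrap p-value), `f_obs`, `beta`, `B`.
#' @export
bootstrap_null_pvalue <- function(gene_diff, mirna_diff, age, sex,
                                  B = 10000, seed = 1L) {
  if (B < 100)
    pm_stop("B must be at least 100", class = "pairmir_config_error")
  obs <- fit_association(gene_diff, mirna_diff, age, sex)
  X <- assoc_design(mirna_diff, age, sex)
  p <- with_seed(seed,
                 bootstrap_f_pvalue(gene_diff, X, obs$f_stat, as.integer(B)))
  list(p = p, f_obs = obs$f_stat, beta = obs$beta, B = as.integer(B))
}

# Vectorized bootstrap of the partial F for column 2 of X. Consumes the
# current RNG stream; callers wrap in with_seed().
bootstrap_f_pvalue <- function(y, X, f_obs, B) {
  n <- length(y)
  qr_full <- qr(X)
  qr_null <- qr(X[, -2, drop = FALSE])
  fitted0 <- qr.fitted(qr_null, y)
  res0 <- qr.resid(qr_null, y)
  df2 <- n - ncol(X)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  Ystar <- fitted0 + matrix(res0[idx], n, B)
  rss0 <- colSums(qr.resid(qr_null, Ystar)^2)
  rss1 <- colSums(qr.resid(qr_full, Ystar)^2)
  fstar <- (rss0 - rss1) / (rss1 / df2)
  (1 + sum(fstar >= f_obs)) / (B + 1)
}

#' Run all candidate gene::miRNA association tests
#'
#' Tests every candidate gene against every candidate miRNA by
#' [bootstrap_null_pvalue()] on the subject-level differential profiles,
#' then adjusts p-values at the gene level: Benjamini-Hochberg within each
#' gene across its tested miRNAs (`fdr_scope = "gene"`, the default) or
#' across all pairs (`"global"`). The significant set additionally
#' requires both fold changes beyond the cutpoints (`fc_up` / `fc_down`),
#' so a pair with a small p-value but a miRNA fold change inside the
#' cutpoints is excluded.
#'
#' Per-pair bootstrap seeds are derived deterministically from `seed`, so
#' results do not depend on candidate order or subsetting.
#'
#' @param gene_diffs,mirna_diffs features x subjects differential matrices
#'   (see [differential_profile()]), on the RPMPCG and normalized-intensity
#'   scales respectively, with identical subject columns.
#' @param candidate_genes,candidate_mirnas feature ids to test (rows of the
#'   respective matrices). Candidates are expected to be pre-filtered
#'   (genes by differential-expression significance, miRNAs by
#'   [expression_filter()]).
#' @param metadata per-sample metadata carrying `age` and `sex` per subject.
#' @param gene_fc,mirna_fc named fold-change vectors used for the
#'   significant-set cutpoint rule and reported per pair.
#' @param mirna_norm optional normalized miRNA matrix (features x samples)
#'   from which per-group means/SDs are reported.
#' @param B bootstrap resamples per pair (default 10000).
#' @param seed integer master seed.
#' @param fdr_alpha significance level on the adjusted p (default 0.05).
#' @param fc_up,fc_down cutpoints for the significant set (1.50 / 0.67).
#' @param fdr_scope `"gene"` (within-gene BH, default) or `"global"`.
#' @return data.frame, one row per gene x miRNA: ids, `beta`, `f_stat`,
#'   `raw_p`, `fdr_p`, `gene_fc`, `mirna_fc`, miRNA group means/SDs (when
#'   `mirna_norm` is given) and `significant` (fdr_p <= alpha and both fold
#'   changes beyond the cutpoints). Empty candidate sets yield an empty
#'   data.frame with a message.
#' @export
run_associations <- function(gene_diffs, mirna_diffs, candidate_genes,
                             candidate_mirnas, metadata, gene_fc, mirna_fc,
                             mirna_norm = NULL, B = 10000, seed = 1L,
                             fdr_alpha = 0.05, fc_up = 1.50, fc_down = 0.67,
                             fdr_scope = c("gene", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  empty <- data.frame(gene = character(0), mirna = character(0),
                      beta = numeric(0), f_stat = numeric(0),
                      raw_p = numeric(0), fdr_p = numeric(0),
                      gene_fc = numeric(0), mirna_fc = numeric(0),
                      significant = logical(0))
  if (length(candidate_genes) == 0 || length(candidate_mirnas) == 0) {
    message("empty candidate set; no associations tested")
    return(empty)
  }
  md <- validate_metadata(metadata)
  subjects <- colnames(gene_diffs)
  if (!identical(subjects, colnames(mirna_diffs)))
    pm_stop("gene and miRNA differential profiles must share subject columns")
  per_subj <- md[!duplicated(md$subject_id), , drop = FALSE]
  row <- match(subjects, per_subj$subject_id)
  if (any(is.na(row)))
    pm_stop("differential-profile subjects missing from metadata")
  age <- per_subj$age[row]
  sex <- per_subj$sex[row]

  grid <- expand.grid(gene = candidate_genes, mirna = candidate_mirnas,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$gene, grid$mirna), , drop = FALSE]
  rownames(grid) <- NULL

  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid$gene[i]; j <- grid$mirna[i]
    pair_seed <- pair_seed_from(seed, g, j)
    bs <- bootstrap_null_pvalue(gene_diffs[g, ], mirna_diffs[j, ], age, sex,
                                B = B, seed = pair_seed)
    data.frame(gene = g, mirna = j, beta = bs$beta, f_stat = bs$f_obs,
               raw_p = bs$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  res$fdr_p <- if (fdr_scope == "gene") {
    stats::ave(res$raw_p, res$gene, FUN = bh_fdr)
  } else {
    bh_fdr(res$raw_p)
  }
  res$gene_fc <- unname(gene_fc[res$gene])
  res$mirna_fc <- unname(mirna_fc[res$mirna])

  if (!is.null(mirna_norm)) {
    m <- as_feature_matrix(mirna_norm, "mirna_norm")
    is_tumor <- md$tissue_status[match(colnames(m), md$sample_id)] == "tumor"
    res$mirna_tumor_mean <- rowMeans(m[res$mirna, is_tumor, drop = FALSE])
    res$mirna_tumor_sd <- apply(m[res$mirna, is_tumor, drop = FALSE], 1, sd)
    res$mirna_normal_mean <- rowMeans(m[res$mirna, !is_tumor, drop = FALSE])
    res$mirna_normal_sd <- apply(m[res$mirna, !is_tumor, drop = FALSE], 1, sd)
  }

  beyond <- function(fc) is.finite(fc) & (fc >= fc_up | fc <= fc_down)
  res$significant <- res$fdr_p <= fdr_alpha &
    beyond(res$gene_fc) & beyond(res$mirna_fc)
  res
}

# Deterministic per-pair seed independent of candidate ordering: a small
# string hash of "gene::mirna" folded into [0, 2^31) together with the
# master seed.
pair_seed_from <- function(seed, gene, mirna) {
  s <- paste0(gene, "::", mirna)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147480009
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}
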