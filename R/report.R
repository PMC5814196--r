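#' Render the gene x miRNA association report table
#'
#' One row per significant association, grouped by gene: gene-level
#' tumor/normal means and fold change, then the miRNA's group mean/SD,
#' fold change, regression beta, raw and FDR p-values, and a seed-match
#' flag (with the matching direction class when a seed record exists).
#' Genes with no significant miRNA are omitted. All values are computed at
#' full precision and rounded only here, half-away-from-zero to 2 decimals
#' (fold-change cells via [fold_change_from_means()], the single fold
#' change rendering path).
#'
#' @param de data.frame from [run_de()].
#' @param assoc data.frame from [run_associations()].
#' @param seeds data.frame from [annotate_associations()] (may be empty).
#' @param digits decimals for rendered values (default 2).
#' @return data.frame with columns `gene`, `gene_tumor_mean`,
#'   `gene_normal_mean`, `gene_fc`, `mirna`, `mirna_tumor_mean`,
#'   `mirna_tumor_sd`, `mirna_normal_mean`, `mirna_normal_sd`, `mirna_fc`,
#'   `beta`, `raw_p`, `fdr_p`, `seed_match`, `direction_class`.
#' @export
report_association_table <- function(de, assoc, seeds, digits = 2) {
  sig <- assoc[assoc$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene = character(0), mirna = character(0)))
  orphans <- setdiff(sig$gene, de$gene)
  if (length(orphans) > 0)
    pm_stop(sprintf("association genes missing from DE results: %s",
                    paste(orphans, collapse = ", ")))
  dei <- de[match(sig$gene, de$gene), , drop = FALSE]
  key <- paste(sig$gene, sig$mirna)
  seed_key <- if (nrow(seeds) > 0) paste(seeds$gene, seeds$mirna)
    else character(0)
  has_seed <- key %in% seed_key
  dir_class <- ifelse(has_seed,
                      seeds$direction_class[match(key, seed_key)],
                      NA_character_)
  r <- function(x) round_half_up(x, digits)
  out <- data.frame(
    gene = sig$gene,
    gene_tumor_mean = r(dei$tumor_mean),
    gene_normal_mean = r(dei$normal_mean),
    gene_fc = fold_change_from_means(dei$tumor_mean, dei$normal_mean,
                                     digits = digits),
    mirna = sig$mirna,
    mirna_tumor_mean = r(sig$mirna_tumor_mean %||% rep(NA_real_, nrow(sig))),
    mirna_tumor_sd = r(sig$mirna_tumor_sd %||% rep(NA_real_, nrow(sig))),
    mirna_normal_mean = r(sig$mirna_normal_mean %||% rep(NA_real_, nrow(sig))),
    mirna_normal_sd = r(sig$mirna_normal_sd %||% rep(NA_real_, nrow(sig))),
    mirna_fc = if (all(c("mirna_tumor_mean", "mirna_normal_mean") %in%
                       names(sig)))
      fold_change_from_means(sig$mirna_tumor_mean, sig$mirna_normal_mean,
                             digits = digits)
    else r(sig$mirna_fc),
    beta = r(sig$beta),
    raw_p = signif(sig$raw_p, 2),
    fdr_p = round_half_up(sig$fdr_p, 4),
    seed_match = has_seed,
    direction_class = dir_class,
    stringsAsFactors = FALSE
  )
  out[order(out$gene, out$mirna), , drop = FALSE]
}
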