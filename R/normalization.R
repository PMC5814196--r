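#' Reads per million protein-coding genes (RPMPCG)
#'
#' Scales each sample by its total count over a designated protein-coding
#' gene set: `value(g, s) = count(g, s) / sum over protein-coding counts in
#' s * 1e6`. Rows outside the protein-coding set (if any) are divided by the
#' same per-sample denominator, so within each sample the protein-coding
#' rows sum to exactly one million.
#'
#' @param counts numeric matrix, genes x samples, nonnegative; rownames are
#'   gene ids, colnames sample ids.
#' @param protein_coding_ids character vector of gene ids defining the
#'   denominator; defaults to all rows.
#' @return an object of class `normalized_matrix` with elements `values`
#'   (the scaled matrix), `method = "rpmpcg"` and `scale_factors`
#'   (per-sample multiplier `1e6 / protein-coding total`).
#' @export
#' @examples
#' m <- matrix(c(30, 70), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' rpmpcg(m)$values  # 3e5, 7e5
rpmpcg <- function(counts, protein_coding_ids = rownames(counts)) {
  counts <- as_feature_matrix(counts, "counts")
  if (any(counts < 0)) pm_stop("negative counts are not allowed")
  missing_ids <- setdiff(protein_coding_ids, rownames(counts))
  if (length(missing_ids) > 0)
    pm_stop(sprintf("protein-coding ids absent from count matrix: %s",
                    paste(utils::head(missing_ids, 5), collapse = ", ")))
  pc <- counts[rownames(counts) %in% protein_coding_ids, , drop = FALSE]
  totals <- colSums(pc)
  bad <- colnames(counts)[totals <= 0]
  if (length(bad) > 0)
    pm_stop(sprintf("zero protein-coding total in sample(s): %s",
                    paste(bad, collapse = ", ")))
  sf <- 1e6 / totals
  values <- sweep(counts, 2, sf, `*`)
  new_normalized_matrix(values, "rpmpcg", sf)
}

#' 75th-percentile scaling normalization
#'
#' Multiplies each sample (column) by `median over samples of P75 / P75 of
#' that sample`, where P75 is the per-sample 75th percentile of intensities.
#' After scaling, every sample's 75th percentile equals the median of the
#' original per-sample 75th percentiles, making the operation idempotent.
#'
#' @param intensity numeric matrix, features x samples, nonnegative.
#' @param type quantile algorithm passed to [stats::quantile()]; default 7,
#'   linear interpolation between order statistics.
#' @return a `normalized_matrix` with `method = "q75"` and the per-sample
#'   `scale_factors`.
#' @export
#' @examples
#' m <- cbind(s1 = c(0, 10), s2 = c(0, 20), s3 = c(0, 40))
#' rownames(m) <- c("a", "b")
#' q75_scale(m)$scale_factors
q75_scale <- function(intensity, type = 7) {
  intensity <- as_feature_matrix(intensity, "intensity")
  p75 <- apply(intensity, 2, stats::quantile, probs = 0.75,
               names = FALSE, type = type)
  bad <- colnames(intensity)[p75 <= 0]
  if (length(bad) > 0)
    pm_stop(sprintf("nonpositive 75th percentile in sample(s): %s",
                    paste(bad, collapse = ", ")))
  sf <- stats::median(p75) / p75
  values <- sweep(intensity, 2, sf, `*`)
  new_normalized_matrix(values, "q75", sf)
}

#' Filter miRNAs by detection frequency in normal samples
#'
#' Retains a feature when it is detected (intensity strictly above
#' `detect_threshold`) in strictly more than `min_frac_expressed` of the
#' supplied normal-tissue samples. The strict inequality means a feature
#' detected in exactly the threshold fraction of samples is dropped.
#'
#' @param normal_intensity numeric matrix, miRNAs x normal samples.
#' @param min_frac_expressed proportion in `[0, 1]`; default 0.20.
#' @param detect_threshold intensity above which a feature counts as
#'   detected; default 0.
#' @return character vector of retained feature ids (empty for an empty
#'   matrix).
#' @export
expression_filter <- function(normal_intensity, min_frac_expressed = 0.20,
                              detect_threshold = 0) {
  if (!is.numeric(min_frac_expressed) || min_frac_expressed < 0 ||
      min_frac_expressed > 1)
    pm_stop("min_frac_expressed must lie in [0, 1]")
  normal_intensity <- as_feature_matrix(normal_intensity, "normal_intensity")
  if (nrow(normal_intensity) == 0 || ncol(normal_intensity) == 0)
    return(character(0))
  frac <- rowMeans(normal_intensity > detect_threshold)
  rownames(normal_intensity)[frac > min_frac_expressed]
}

new_normalized_matrix <- function(values, method, scale_factors) {
  structure(list(values = values, method = method,
                 scale_factors = scale_factors),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix: %s, %d features x %d samples>\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Coerce to a numeric matrix with mandatory dimnames.
as_feature_matrix <- function(x, what) {
  if (inherits(x, "normalized_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) > 0 && is.null(rownames(x)))
    pm_stop(sprintf("%s must have feature ids as rownames", what))
  if (ncol(x) > 0 && is.null(colnames(x)))
    pm_stop(sprintf("%s must have sample ids as colnames", what))
  if (!is.numeric(x)) pm_stop(sprintf("%s must be numeric", what))
  x
}
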