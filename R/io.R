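#' Read a feature x sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Ragged rows, duplicated feature ids and non-numeric cells are rejected
#' with the offending line number.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) pm_stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) pm_stop(sprintf("%s: empty file", path))
  ragged <- which(nf != nf[1])
  if (length(ragged) > 0)
    pm_stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                    path, ragged[1], nf[ragged[1]], nf[1]))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  ids <- df[[1]]
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    pm_stop(sprintf("%s: duplicate feature id '%s' at line %d",
                    path, ids[dup[1]], dup[1] + 1L))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(vals) > 0 && NROW(bad) > 0)
    pm_stop(sprintf("%s: non-numeric cell '%s' at line %d, column %d",
                    path, vals[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                    bad[1, 2] + 1L))
  dimnames(num) <- list(ids, colnames(df)[-1])
  num
}

#' Write a feature x sample matrix as TSV
#'
#' Inverse of [read_matrix()]: first column `feature_id`, one header column
#' per sample.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat) %||% character(0),
                   mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Ids are the first whitespace-delimited token of each header; multi-line
#' sequences are concatenated and upper-cased. Duplicate ids and empty
#' sequences are rejected.
#'
#' @param path FASTA file path.
#' @return named character vector id -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) pm_stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    pm_stop(sprintf("%s: duplicate FASTA id '%s'", path, dup[1]))
  seqs <- toupper(as.character(set))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0)
    pm_stop(sprintf("%s: empty sequence for id '%s'", path, empty[1]))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector id -> sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- unlist(sequences)
  set <- Biostrings::BStringSet(
    stats::setNames(as.character(sequences), names(sequences)))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires columns `sample_id`, `subject_id`, `tissue_status`; passes any
#' additional columns (age, sex, msi_status, site, ...) through. Validates
#' that `tissue_status` only contains "tumor" and "normal".
#'
#' @param path TSV path.
#' @return data.frame of per-sample metadata.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  required <- c("sample_id", "subject_id", "tissue_status")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols) > 0)
    pm_stop(paste("metadata lacks column(s):",
                  paste(missing_cols, collapse = ", ")))
  bad <- setdiff(unique(md$tissue_status), c("tumor", "normal"))
  if (length(bad) > 0)
    pm_stop(paste("tissue_status values must be 'tumor' or 'normal'; found:",
                  paste(bad, collapse = ", ")))
  md$sample_id <- as.character(md$sample_id)
  md$subject_id <- as.character(md$subject_id)
  md
}

# Subjects contributing exactly one tumor and one normal sample; error (or
# drop, when complete_only) otherwise.
paired_subjects <- function(md, complete_only = FALSE) {
  tab <- table(md$subject_id,
               factor(md$tissue_status, levels = c("normal", "tumor")))
  complete <- rownames(tab)[tab[, "normal", drop = TRUE] == 1 &
                            tab[, "tumor", drop = TRUE] == 1]
  if (!complete_only && length(complete) < length(unique(md$subject_id))) {
    off <- setdiff(unique(md$subject_id), complete)
    pm_stop(sprintf("subject(s) without exactly one tumor and one normal sample: %s",
                    paste(utils::head(off, 5), collapse = ", ")))
  }
  complete
}

#' Summarize a paired cohort's population
#'
#' Per-subject counts and percentages (one decimal) for each categorical
#' descriptor present among `sex`, `msi_status`, `site`, plus the age mean
#' and SD (one decimal). Tissue-invariant descriptors are taken from each
#' subject's first record.
#'
#' @param metadata per-sample metadata (see [read_metadata()]), or an
#'   already per-subject table (no `tissue_status` column needed if
#'   `sample_id`/`subject_id` are unique).
#' @return object of class `cohort_summary`: list with `n_subjects`,
#'   `categories` (named list of data.frames with `level`, `n`, `pct`) and
#'   `age` (`mean`, `sd`), all percentages rendered to one decimal.
#' @export
#' @examples
#' md <- data.frame(subject_id = as.character(1:217),
#'                  site = rep(c("colon", "rectal"), c(169, 48)))
#' summarize_cohort(md)$categories$site
summarize_cohort <- function(metadata) {
  if (!"subject_id" %in% names(metadata))
    pm_stop("metadata lacks column(s): subject_id")
  per_subj <- metadata[!duplicated(metadata$subject_id), , drop = FALSE]
  n <- nrow(per_subj)
  cats <- list()
  for (col in intersect(c("site", "sex", "msi_status"), names(per_subj))) {
    tab <- table(per_subj[[col]])
    cats[[col]] <- data.frame(
      level = names(tab), n = as.integer(tab),
      pct = percent_of(as.integer(tab), n),
      stringsAsFactors = FALSE)
  }
  age <- if ("age" %in% names(per_subj)) {
    list(mean = round_half_up(mean(per_subj$age), 1),
         sd = round_half_up(stats::sd(per_subj$age), 1))
  }
  structure(list(n_subjects = n, categories = cats, age = age),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects\n", x$n_subjects))
  for (nm in names(x$categories)) {
    cat(nm, ":\n", sep = "")
    df <- x$categories[[nm]]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-20s %5d  %5.1f%%\n", df$level[i], df$n[i], df$pct[i]))
  }
  if (!is.null(x$age))
    cat(sprintf("age: mean %.1f (SD %.1f)\n", x$age$mean, x$age$sd))
  invisible(x)
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one id per line; blank lines and `#` comments
#'   ignored.
#' @return character vector of ids.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
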