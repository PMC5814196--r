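#' Extract miRNA seed regions of 6, 7 and 8 nucleotides
#'
#' The canonical seed convention: windows anchored at miRNA position 2
#' (1-based, i.e. skipping the 5'-most nucleotide), of lengths 6, 7 and 8 —
#' positions 2-7, 2-8 and 2-9 of the mature sequence. The anchor and the
#' window lengths are configurable.
#'
#' @param mirna_sequence mature miRNA sequence, 5'->3', RNA alphabet
#'   `{A, C, G, U}`; must cover the longest requested window.
#' @param start 1-based anchor of the seed windows (default 2).
#' @param lengths integer vector of window lengths (default `c(6, 7, 8)`).
#' @return data.frame with columns `seed_length` and `seed` (RNA, 5'->3').
#' @export
#' @examples
#' extract_seeds("UAAAGUGCUUAUAGUGCAGGUA")
extract_seeds <- function(mirna_sequence, start = 2, lengths = c(6L, 7L, 8L)) {
  check_alphabet(mirna_sequence, c("A", "C", "G", "U"), "miRNA sequence")
  need <- start + max(lengths) - 1
  if (nchar(mirna_sequence) < need)
    pm_stop(sprintf(
      "miRNA sequence of length %d too short for a %d-nt seed at position %d",
      nchar(mirna_sequence), max(lengths), start))
  data.frame(
    seed_length = as.integer(lengths),
    seed = vapply(lengths, function(l)
      substr(mirna_sequence, start, start + l - 1), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of an RNA seed, in DNA alphabet
#'
#' Maps A->T, U->A, C->G, G->C and reverses, producing the DNA string whose
#' occurrence in a sense-strand 3'UTR marks a potential binding site.
#'
#' @param seed RNA string, alphabet `{A, C, G, U}`.
#' @return DNA string (reverse complement).
#' @export
#' @examples
#' reverse_complement_dna("AUGC")  # "GCAT"
reverse_complement_dna <- function(seed) {
  check_alphabet(seed, c("A", "C", "G", "U"), "seed")
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(Biostrings::RNAString(seed))))
}

#' Find seed-region sites in a 3'UTR
#'
#' Locates every (possibly overlapping) occurrence of the seed's DNA
#' reverse complement in the UTR sense strand.
#'
#' @param seed RNA seed string.
#' @param utr 3'UTR sequence, DNA alphabet, sense strand, 5'->3'.
#' @return integer vector of 0-based offsets, ascending; empty when there
#'   is no site or the UTR is shorter than the seed.
#' @export
match_seed_to_utr <- function(seed, utr) {
  check_alphabet(utr, c("A", "C", "G", "T"), "UTR")
  rc <- reverse_complement_dna(seed)
  if (nchar(utr) < nchar(rc)) return(integer(0))
  hits <- Biostrings::matchPattern(rc, Biostrings::DNAString(utr))
  sort(Biostrings::start(hits)) - 1L
}

#' Annotate miRNA::gene associations with seed-region matches
#'
#' For each association, tests all seed lengths of the miRNA against the
#' gene's 3'UTR and emits one record per (pair, seed length) with at least
#' one site. The pair is classified `inverse` when exactly one of the gene
#' and miRNA fold changes is above 1 and the other below 1 — the pattern
#' expected for direct repression — and `concordant` otherwise. Pairs where
#' either fold change equals 1 exactly have no defined direction and are
#' classified concordant with `degenerate_fc = TRUE`.
#'
#' Associations whose miRNA or gene has no available sequence are skipped
#' with a message and counted in the `n_skipped` attribute.
#'
#' @param associations data.frame with columns `gene`, `mirna`, `gene_fc`,
#'   `mirna_fc` (e.g. the output of [run_associations()]).
#' @param mirna_sequences named character vector or list, miRNA id ->
#'   mature RNA sequence.
#' @param utr_sequences named character vector or list, gene id -> 3'UTR
#'   DNA sequence. A `U` in a UTR triggers a warning (likely an RNA file
#'   supplied in place of sense-strand DNA).
#' @param seed_start,seed_lengths seed convention, see [extract_seeds()].
#' @return data.frame with one row per (gene, mirna, seed_length) match:
#'   `mirna`, `gene`, `seed_length`, `seed`, `n_sites`, `site_positions`
#'   (comma-joined 0-based offsets), `direction_class`, `direct_candidate`,
#'   `degenerate_fc`. Attribute `n_skipped` counts associations lacking
#'   sequence.
#' @export
annotate_associations <- function(associations, mirna_sequences,
                                  utr_sequences, seed_start = 2,
                                  seed_lengths = c(6L, 7L, 8L)) {
  required <- c("gene", "mirna", "gene_fc", "mirna_fc")
  if (!all(required %in% names(associations)))
    pm_stop(paste("associations must have columns:",
                  paste(required, collapse = ", ")))
  mirna_sequences <- unlist(mirna_sequences)
  utr_sequences <- unlist(utr_sequences)
  if (any(grepl("U", utr_sequences, fixed = TRUE)))
    warning("UTR sequences contain 'U'; expected sense-strand DNA")

  out <- vector("list", nrow(associations))
  n_skipped <- 0L
  for (i in seq_len(nrow(associations))) {
    a <- associations[i, ]
    if (is.na(match(a$mirna, names(mirna_sequences))) ||
        is.na(match(a$gene, names(utr_sequences)))) {
      message(sprintf("no sequence for %s::%s; skipped", a$gene, a$mirna))
      n_skipped <- n_skipped + 1L
      next
    }
    seeds <- extract_seeds(mirna_sequences[[a$mirna]], start = seed_start,
                           lengths = seed_lengths)
    utr <- utr_sequences[[a$gene]]
    recs <- lapply(seq_len(nrow(seeds)), function(k) {
      pos <- match_seed_to_utr(seeds$seed[k], utr)
      if (length(pos) == 0) return(NULL)
      degenerate <- a$gene_fc == 1 || a$mirna_fc == 1
      inverse <- !degenerate && xor(a$gene_fc > 1, a$mirna_fc > 1)
      data.frame(
        mirna = a$mirna, gene = a$gene,
        seed_length = seeds$seed_length[k], seed = seeds$seed[k],
        n_sites = length(pos),
        site_positions = paste(pos, collapse = ","),
        direction_class = if (inverse) "inverse" else "concordant",
        direct_candidate = TRUE,
        degenerate_fc = degenerate,
        stringsAsFactors = FALSE
      )
    })
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mirna = character(0), gene = character(0),
                      seed_length = integer(0), seed = character(0),
                      n_sites = integer(0), site_positions = character(0),
                      direction_class = character(0),
                      direct_candidate = logical(0),
                      degenerate_fc = logical(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

check_alphabet <- function(x, alphabet, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x))
    pm_stop(sprintf("%s must be a single string", what))
  chars <- unique(strsplit(x, "")[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad) > 0)
    pm_stop(sprintf("%s contains characters outside {%s}: %s", what,
                    paste(alphabet, collapse = ","),
                    paste(bad, collapse = ",")))
  invisible(x)
}
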