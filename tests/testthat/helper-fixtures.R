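# Shared fixtures and independent oracles, built in code at test time.

# Simulate per-sample data directly from the paired NB mixed model (one
# gene), independent of the cohort generator.
sim_nb_pairs <- function(n_pairs = 100, beta0 = -10, beta_tumor = 0,
                         sigma = 0.3, k = 8, seed = 1) {
  set.seed(seed)
  off <- log(runif(2 * n_pairs, 2e5, 8e5))
  subj <- rep(sprintf("s%04d", seq_len(n_pairs)), each = 2)
  tis <- rep(c("normal", "tumor"), n_pairs)
  u <- rep(rnorm(n_pairs, 0, sigma), each = 2)
  mu <- exp(off + beta0 + beta_tumor * (tis == "tumor") + u)
  list(y = rnbinom(2 * n_pairs, size = k, mu = mu), off = off,
       tis = tis, subj = subj)
}

# Loop-based RPMPCG oracle (brute force, no vectorized sweep).
rpmpcg_oracle <- function(counts, pc_ids = rownames(counts)) {
  out <- counts * NA_real_
  for (s in seq_len(ncol(counts))) {
    tot <- 0
    for (g in seq_len(nrow(counts)))
      if (rownames(counts)[g] %in% pc_ids) tot <- tot + counts[g, s]
    for (g in seq_len(nrow(counts))) out[g, s] <- counts[g, s] / tot * 1e6
  }
  out
}

# Naive O(n*m) scan for all (overlapping) occurrences of the DNA reverse
# complement of an RNA seed in a UTR; returns 0-based offsets.
seed_scan_oracle <- function(seed, utr) {
  comp <- c(A = "T", U = "A", C = "G", G = "C")
  rc <- paste(rev(comp[strsplit(seed, "")[[1]]]), collapse = "")
  m <- nchar(rc); n <- nchar(utr)
  hits <- integer(0)
  if (n >= m) {
    for (i in 0:(n - m))
      if (substr(utr, i + 1, i + m) == rc) hits <- c(hits, i)
  }
  hits
}

# Random RNA / DNA strings.
random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")
random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# A tiny deterministic paired cohort for IO / profile tests.
tiny_cohort <- function(seed = 123, n_subjects = 8, n_genes = 12,
                        n_mirnas = 5) {
  generate_cohort(sim_config(
    n_subjects = n_subjects, n_genes = n_genes,
    n_pathway_genes = min(4, n_genes), n_mirnas = n_mirnas,
    n_couplings = 2, seed = seed))
}

# Per-subject metadata frame for association tests.
subject_metadata <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = c(sprintf("p%03d_N", 1:n), sprintf("p%03d_T", 1:n)),
    subject_id = rep(sprintf("p%03d", 1:n), 2),
    tissue_status = rep(c("normal", "tumor"), each = n),
    age = rep(round(rnorm(n, 64.8, 10.1), 1), 2),
    sex = rep(sample(c("M", "F"), n, replace = TRUE), 2),
    stringsAsFactors = FALSE)
}
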