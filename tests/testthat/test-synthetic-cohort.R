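test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(msi_fraction = 1.2), "msi_fraction")
  expect_error(sim_config(fc_down_range = c(0.5, 1.5)), "fc_down_range")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(n_pathway_genes = 50, n_genes = 10),
               "n_pathway_genes")
  expect_error(sim_config(n_genes = 10, n_pathway_genes = 2, n_mirnas = 3,
                          n_couplings = 100), "n_couplings")
})

test_that("default configuration emulates the study-scale paired design", {
  cfg <- default_config()
  expect_equal(cfg$n_subjects, 217)
  expect_equal(cfg$msi_fraction, 0.134)
  expect_equal(cfg$age_mean_sd, c(64.8, 10.1))
  expect_s3_class(cfg, "sim_config")
})

test_that("generated cohorts are paired, typed and deterministic", {
  cfg <- sim_config(n_subjects = 25, n_genes = 40, n_pathway_genes = 5,
                    n_mirnas = 8, seed = 51)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  md <- co$metadata
  # exactly one tumor and one normal sample per subject
  tab <- table(md$subject_id, md$tissue_status)
  expect_true(all(tab == 1))
  expect_equal(nrow(md), 50)
  # tissue-invariant metadata identical within subject
  for (col in c("age", "sex", "msi_status", "site")) {
    per <- tapply(md[[col]], md$subject_id, function(x) length(unique(x)))
    expect_true(all(per == 1))
  }
  # alphabets
  expect_true(all(grepl("^[ACGU]+$", co$mirna_sequences)))
  expect_true(all(grepl("^[ACGT]+$", co$utr_sequences)))
  # counts integer, nonnegative
  expect_true(all(co$gene_counts >= 0))
  expect_true(all(co$gene_counts == floor(co$gene_counts)))
  # truth covers every gene
  expect_setequal(names(sim$truth$true_fc_by_gene), rownames(co$gene_counts))
  # byte-identical regeneration under the same seed
  sim2 <- generate_cohort(cfg)
  expect_identical(sim, sim2)
  # different seed differs
  sim3 <- generate_cohort(sim_config(n_subjects = 25, n_genes = 40,
                                     n_pathway_genes = 5, n_mirnas = 8,
                                     seed = 52))
  expect_false(identical(sim$cohort$gene_counts, sim3$cohort$gene_counts))
})

test_that("no dysregulation planted means all true fold changes are one", {
  sim <- generate_cohort(sim_config(
    n_subjects = 10, n_genes = 30, n_pathway_genes = 3, n_mirnas = 4,
    frac_genes_dysregulated = 0, n_couplings = 0, seed = 53))
  expect_true(all(sim$truth$true_fc_by_gene == 1))
  expect_equal(nrow(sim$truth$couplings), 0)
})

test_that("planted fold changes are realized in the normalized group means", {
  sim <- generate_cohort(sim_config(
    n_subjects = 200, n_genes = 250, n_pathway_genes = 10, n_mirnas = 10,
    n_couplings = 0, seed = 54))
  co <- sim$cohort
  norm <- rpmpcg(co$gene_counts, co$protein_coding_ids)
  tum <- co$metadata$tissue_status == "tumor"
  ratio <- rowMeans(norm$values[, tum]) / rowMeans(norm$values[, !tum])
  tfc <- sim$truth$true_fc_by_gene
  dys <- names(tfc)[tfc != 1]
  expect_true(all(abs(ratio[dys] / tfc[dys] - 1) < 0.10))
})

test_that("every planted seed site is discoverable at the recorded offset", {
  sim <- generate_cohort(sim_config(
    n_subjects = 10, n_genes = 60, n_pathway_genes = 10, n_mirnas = 20,
    n_couplings = 12, frac_seed_planted = 1, seed = 55))
  ps <- sim$truth$planted_sites
  expect_gt(nrow(ps), 0)
  for (i in seq_len(nrow(ps))) {
    seeds <- extract_seeds(sim$cohort$mirna_sequences[[ps$mirna[i]]])
    s <- seeds$seed[seeds$seed_length == ps$seed_length[i]]
    hits <- match_seed_to_utr(s, sim$cohort$utr_sequences[[ps$gene[i]]])
    expect_true(ps$utr_position[i] %in% hits)
  }
})

test_that("cohorts round-trip through write_cohort and read_cohort", {
  sim <- tiny_cohort(seed = 56)
  d <- withr::local_tempdir()
  manifest <- write_cohort(sim$cohort, d, sim$truth)
  expect_true(all(file.exists(manifest)))
  back <- read_cohort(d)
  expect_equal(back$gene_counts, sim$cohort$gene_counts)
  expect_equal(back$mirna_intensity, sim$cohort$mirna_intensity,
               tolerance = 1e-12)
  expect_equal(back$metadata$subject_id, sim$cohort$metadata$subject_id)
  expect_identical(back$mirna_sequences, sim$cohort$mirna_sequences)
  expect_identical(back$utr_sequences, sim$cohort$utr_sequences)
  # one FASTA record per feature
  expect_equal(length(back$mirna_sequences), nrow(sim$cohort$mirna_intensity))
  expect_equal(length(back$utr_sequences), nrow(sim$cohort$gene_counts))
  # truth JSON readable
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(length(truth$true_fc_by_gene), nrow(sim$cohort$gene_counts))
})

test_that("an empty cohort writes valid empty files without crashing", {
  empty <- structure(list(
    gene_counts = matrix(numeric(0), 0, 0),
    mirna_intensity = matrix(numeric(0), 0, 0),
    metadata = data.frame(sample_id = character(0),
                          subject_id = character(0),
                          tissue_status = character(0)),
    mirna_sequences = setNames(character(0), character(0)),
    utr_sequences = setNames(character(0), character(0)),
    pathway_genes = character(0), protein_coding_ids = character(0)
  ), class = "paired_cohort")
  d <- withr::local_tempdir()
  manifest <- write_cohort(empty, d)
  expect_true(all(file.exists(manifest)))
})
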