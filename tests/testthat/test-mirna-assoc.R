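test_that("differential_profile is the per-subject tumor minus normal difference", {
  md <- subject_metadata(6, seed = 41)
  m <- matrix(rlnorm(2 * 6 * 3, 3, 1), 3, 12,
              dimnames = list(paste0("f", 1:3), md$sample_id))
  d <- differential_profile(m, md)
  expect_equal(dim(d), c(3, 6))
  # loop-based oracle
  for (s in colnames(d))
    for (f in rownames(d))
      expect_equal(d[f, s],
                   m[f, paste0(s, "_T")] - m[f, paste0(s, "_N")])
  # tumor == normal gives an all-zero profile
  m0 <- m
  m0[, md$sample_id[md$tissue_status == "tumor"]] <-
    m0[, md$sample_id[md$tissue_status == "normal"]]
  expect_true(all(differential_profile(m0, md) == 0))
  # missing mate sample: structural error naming the subject
  md_broken <- md[-1, ]
  expect_error(differential_profile(m, md_broken), "p001")
})

test_that("fit_association matches the normal-equations OLS oracle", {
  set.seed(42)
  n <- 200
  mir <- rnorm(n, 0, 3); age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
  y <- 2 + 0.3 * mir + 0.05 * age - 1 * sex + rnorm(n)
  f <- fit_association(y, mir, age, sex)
  X <- cbind(1, mir, age, sex)
  beta_or <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(f$beta - beta_or[2]), 1e-10)
  # partial F equals the anova() comparison of nested lm fits
  a <- anova(lm(y ~ age + sex), lm(y ~ mir + age + sex))
  expect_equal(f$f_stat, a$F[2])
  expect_equal(f$df[2], a$Res.Df[2])
})

test_that("exact linear relation yields the slope and an unbounded F", {
  set.seed(48)
  mir <- seq(-5, 5, length.out = 20)
  age <- runif(20, 40, 80); sex <- rbinom(20, 1, 0.5)
  y <- 0.3 * mir + 0.02 * age - 0.5 * sex   # exact fit, no noise
  f <- fit_association(y, mir, age, sex)
  expect_equal(f$beta, 0.3)
  expect_identical(f$f_stat, Inf)
})

test_that("degenerate designs are rejected", {
  n <- 30
  y <- rnorm(n); age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
  expect_error(fit_association(y, rep(2, n), age, sex), "rank")
  expect_error(fit_association(y[1:4], rnorm(4), age[1:4], sex[1:4]),
               "5 subjects")
})

test_that("bootstrap p-value is deterministic, bounded below, and minimal for a perfect fit", {
  set.seed(43)
  n <- 60
  mir <- rnorm(n); age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
  y <- 0.4 * mir + rnorm(n, 0, 0.2)
  b1 <- bootstrap_null_pvalue(y, mir, age, sex, B = 500, seed = 7)
  b2 <- bootstrap_null_pvalue(y, mir, age, sex, B = 500, seed = 7)
  expect_identical(b1$p, b2$p)
  expect_gte(b1$p, 1 / 501)
  # perfect linear relation attains the +1 minimum
  bp <- bootstrap_null_pvalue(0.3 * mir, mir, age, sex, B = 500, seed = 8)
  expect_equal(bp$p, 1 / 501)
  expect_error(bootstrap_null_pvalue(y, mir, age, sex, B = 50), "at least 100")
})

test_that("bootstrap null rejection rate is calibrated at the nominal level", {
  set.seed(44)
  rej <- replicate(400, {
    n <- 50
    y <- rnorm(n); mir <- rnorm(n)
    age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
    bootstrap_null_pvalue(y, mir, age, sex, B = 500,
                          seed = sample.int(1e6, 1))$p <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("bootstrap p converges to the classical F-test p on Gaussian data", {
  set.seed(45)
  diffs <- replicate(50, {
    n <- 80
    y <- rnorm(n); mir <- rnorm(n)
    age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
    bp <- bootstrap_null_pvalue(y, mir, age, sex, B = 10000,
                                seed = sample.int(1e6, 1))
    abs(bp$p - pf(bp$f_obs, 1, n - 4, lower.tail = FALSE))
  })
  expect_lt(mean(diffs), 0.01)
})

test_that("run_associations recovers planted couplings and applies the cutpoint rule", {
  sim <- generate_cohort(sim_config(
    n_subjects = 200, n_genes = 150, n_pathway_genes = 8, n_mirnas = 40,
    n_couplings = 5, frac_seed_planted = 0, seed = 46))
  co <- sim$cohort; md <- co$metadata
  ng <- rpmpcg(co$gene_counts, co$protein_coding_ids)
  nm <- q75_scale(co$mirna_intensity)
  gd <- differential_profile(ng, md)
  mdf <- differential_profile(nm, md)
  tum <- md$tissue_status == "tumor"
  gene_fc <- rowMeans(ng$values[, tum]) / rowMeans(ng$values[, !tum])
  mirna_fc <- rowMeans(nm$values[, tum]) / rowMeans(nm$values[, !tum])
  assoc <- run_associations(gd, mdf, co$pathway_genes, rownames(mdf), md,
                            gene_fc, mirna_fc, mirna_norm = nm, B = 2000,
                            seed = 9)
  expect_equal(nrow(assoc), 8 * 40)
  key <- paste(assoc$gene, assoc$mirna)
  tr <- sim$truth$couplings
  planted <- key %in% paste(tr$gene, tr$mirna)
  # every planted pair detected at gene-level FDR 0.05
  expect_true(all(assoc$fdr_p[planted] <= 0.05))
  # sign coherence with the planted coupling
  expect_equal(sign(assoc$beta[planted][order(key[planted])]),
               sign(tr$effect[order(paste(tr$gene, tr$mirna))]))
  # null pairs controlled
  expect_lt(mean(assoc$raw_p[!planted] < 0.05), 0.05 + 0.04)
  expect_lt(sum(assoc$significant[!planted]), 3)
  # within-gene BH: each gene's adjusted set is the BH of its raw set
  for (g in unique(assoc$gene)) {
    i <- assoc$gene == g
    expect_equal(assoc$fdr_p[i], bh_fdr(assoc$raw_p[i]))
  }
  # miRNA group summaries present
  expect_true(all(c("mirna_tumor_mean", "mirna_normal_sd") %in% names(assoc)))
})

test_that("pairs with fold changes inside the cutpoints are excluded from the significant set", {
  set.seed(47)
  n <- 80
  md <- subject_metadata(n, seed = 47)
  mir <- matrix(rnorm(n, 0, 3), 1, n,
                dimnames = list("mirX", sprintf("p%03d", 1:n)))
  gene <- matrix(0.5 * mir[1, ] + rnorm(n, 0, 0.5), 1, n,
                 dimnames = list("geneY", sprintf("p%03d", 1:n)))
  assoc <- run_associations(gene, mir, "geneY", "mirX", md,
                            gene_fc = c(geneY = 2.0),
                            mirna_fc = c(mirX = 1.2), B = 500, seed = 10)
  expect_lte(assoc$fdr_p, 0.05)       # strongly associated...
  expect_false(assoc$significant)     # ...but miRNA FC 1.2 is inside the cutpoints
  # empty candidate sets: empty result with a notice, not an error
  expect_message(
    empty <- run_associations(gene, mir, character(0), "mirX", md,
                              gene_fc = numeric(0), mirna_fc = numeric(0)),
    "empty")
  expect_equal(nrow(empty), 0)
})
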