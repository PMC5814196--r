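test_that("symmetric data gives a null tumor effect", {
  set.seed(21)
  n <- 40
  off <- rep(log(runif(n, 2e5, 8e5)), each = 2)
  y <- rep(rnbinom(n, size = 6, mu = exp(off[seq(1, 2 * n, 2)] - 10)),
           each = 2)
  f <- fit_nb_mixed(y, off, rep(c("normal", "tumor"), n),
                    rep(sprintf("s%02d", 1:n), each = 2), dispersion = 6)
  expect_true(f$converged)
  expect_lt(abs(f$beta_tumor), 1e-6)
  expect_equal(f$fold_change, exp(f$beta_tumor))
})

test_that("vanishing subject variance recovers the fixed-effects NB fit", {
  d <- sim_nb_pairs(n_pairs = 150, beta_tumor = log(1.8), sigma = 0,
                    k = 6, seed = 99)
  f <- fit_nb_mixed(d$y, d$off, d$tis, d$subj)
  g <- MASS::glm.nb(d$y ~ I(d$tis == "tumor") + offset(d$off))
  expect_lt(abs(f$beta_tumor - unname(coef(g)[2])), 1e-3)
  expect_lt(f$subject_sd, 0.2)
})

test_that("planted fold changes are recovered across the dynamic range", {
  fcs <- c(0.28, 0.67, 1.0, 1.5, 3.7)
  set.seed(22)
  med_err <- vapply(fcs, function(f) {
    est <- replicate(5, {
      d <- sim_nb_pairs(n_pairs = 200, beta_tumor = log(f), sigma = 0.3,
                        k = 8, seed = sample.int(1e6, 1))
      fit_nb_mixed(d$y, d$off, d$tis, d$subj)$fold_change
    })
    median(abs(est / f - 1))
  }, numeric(1))
  expect_true(all(med_err < 0.10))
})

test_that("dispersion and subject SD are estimated near their generative values", {
  d <- sim_nb_pairs(n_pairs = 300, beta_tumor = log(2), sigma = 0.4,
                    k = 5, seed = 23)
  f <- fit_nb_mixed(d$y, d$off, d$tis, d$subj)
  expect_true(f$converged)
  expect_lt(abs(f$dispersion / 5 - 1), 0.4)
  expect_lt(abs(f$subject_sd / 0.4 - 1), 0.3)
})

test_that("beta is invariant to a global library-size rescaling", {
  d <- sim_nb_pairs(n_pairs = 120, beta_tumor = log(1.6), sigma = 0.3,
                    seed = 24)
  ctl <- list(rel_tol = 1e-13)
  f1 <- fit_nb_mixed(d$y, d$off, d$tis, d$subj, control = ctl)
  f2 <- fit_nb_mixed(d$y, d$off + log(7), d$tis, d$subj, control = ctl)
  expect_lt(abs(f1$beta_tumor - f2$beta_tumor), 1e-8)
})

test_that("degenerate and malformed inputs are handled explicitly", {
  n <- 10
  off <- rep(10, 2 * n)
  tis <- rep(c("normal", "tumor"), n)
  subj <- rep(sprintf("s%02d", 1:n), each = 2)
  # all-zero gene: flagged, not an error
  f <- fit_nb_mixed(rep(0L, 2 * n), off, tis, subj)
  expect_false(f$converged)
  expect_true(is.na(f$fold_change))
  # unpaired subject: structural error naming it
  expect_error(fit_nb_mixed(rpois(2 * n, 5), off,
                            c(tis[-1], "tumor"), subj),
               "s10")
  expect_error(fit_nb_mixed(rpois(2 * n, 5), c(off[-1], Inf), tis, subj),
               "finite")
})

test_that("null Wald p-values are approximately uniform", {
  set.seed(25)
  ps <- replicate(1000, {
    d <- sim_nb_pairs(n_pairs = 50, beta_tumor = 0, sigma = 0.3, k = 8,
                      seed = sample.int(1e6, 1))
    fit_nb_mixed(d$y, d$off, d$tis, d$subj)$raw_p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("classify_direction applies the inclusive 1.50/0.67 cutpoints", {
  expect_equal(classify_direction(c(2.02, 0.76, 1.0, 1.50, 0.67, 0.28)),
               c("up", "neither", "neither", "up", "down", "down"))
  expect_error(classify_direction(-1), "positive")
})

test_that("bh_fdr reproduces the step-up adjustment and its dominance", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  set.seed(26)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("run_de reports means, both fold changes and BH-adjusted p per stratum", {
  sim <- generate_cohort(sim_config(
    n_subjects = 50, n_genes = 80, n_pathway_genes = 8, n_mirnas = 5,
    n_couplings = 0, frac_genes_dysregulated = 0.3, seed = 31))
  co <- sim$cohort
  de <- run_de(co)
  expect_equal(nrow(de), 8)
  expect_true(all(de$converged))
  expect_equal(de$fold_change, exp(de$beta_tumor))
  expect_true(all(de$fdr_p >= de$raw_p - 1e-12))
  # ratio of means equals the unrounded mean ratio of RPMPCG values
  norm <- rpmpcg(co$gene_counts, co$protein_coding_ids)
  tum <- co$metadata$tissue_status == "tumor"
  expect_equal(de$ratio_of_means,
               unname(rowMeans(norm$values[de$gene, tum]) /
                        rowMeans(norm$values[de$gene, !tum])))
  # strong planted effects called in the right direction
  tfc <- sim$truth$true_fc_by_gene[de$gene]
  called_up <- de$direction == "up" & de$fdr_p <= 0.05
  expect_true(all(tfc[called_up] > 1))
  # MSI stratum subsets complete pairs; tiny strata rejected
  de_msi <- run_de(co, stratum = "MSI")
  n_msi <- sum(co$metadata$msi_status == "MSI" &
                 co$metadata$tissue_status == "tumor")
  expect_true(all(de_msi$n_pairs == n_msi))
  tiny <- co
  tiny$metadata$msi_status <- "MSS"
  expect_error(run_de(tiny, stratum = "MSI"), "msi|pairs|stratum")
})

test_that("false positive rate among null genes is controlled by BH", {
  sim <- generate_cohort(sim_config(
    n_subjects = 30, n_genes = 400, n_pathway_genes = 1, n_mirnas = 5,
    n_couplings = 0, frac_genes_dysregulated = 0.01, seed = 32))
  co <- sim$cohort
  null_genes <- names(which(sim$truth$true_fc_by_gene == 1))
  de <- run_de(co, gene_set = null_genes)
  ok <- de$converged
  expect_gt(mean(ok), 0.98)
  expect_lt(mean(de$fdr_p[ok] <= 0.05), 0.05 + 0.02)
})
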