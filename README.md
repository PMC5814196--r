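# pairmir

Paired tumor/normal differential expression and miRNA association analysis
for pathway gene panels.

## The problem

In paired tumor/normal designs — the same subject contributing one
carcinoma and one adjacent-normal sample — a recurring analysis pattern in
colorectal cancer transcriptomics asks three questions about a pathway
gene panel (for example the Wnt-signaling pathway):

1. **Which panel genes are dysregulated in tumor tissue?** Answered per
   gene with a negative binomial mixed model on RNA-Seq counts,

   $$ y_{ij} \sim \mathrm{NB}(\mu_{ij}, k), \qquad
      \log \mu_{ij} = o_{ij} + \beta_0 + \beta_1\,\mathrm{tumor}_{ij} + u_i,
      \qquad u_i \sim N(0, \sigma^2), $$

   where the offset $o_{ij}$ is the log total protein-coding count, so
   $e^{\beta_1}$ is the tumor/normal fold change on the RPMPCG scale
   (reads per million protein-coding genes). The random intercept $u_i$
   captures the shared subject baseline. Genes are called up/down with
   the conventional FC ≥ 1.50 / ≤ 0.67 cutpoints at Benjamini–Hochberg
   FDR ≤ 0.05, optionally stratified by MSI/MSS status.

2. **Which miRNAs track those genes?** For each dysregulated gene and
   each expressed miRNA (detected in > 20% of normal samples on
   75th-percentile-scaled arrays), ordinary least squares of the
   per-subject *differential* (tumor − normal) gene expression on the
   miRNA differential, adjusted for age and sex. The partial-F p-value
   comes from a residual-resampling bootstrap (10,000 resamples of the
   null-model residuals), with BH control at the gene level and the same
   FC cutpoints applied to the significant set.

3. **Which associations could be direct?** miRNA seed regions (windows
   of 6/7/8 nt starting at position 2) are matched by exact reverse
   complement against the gene's 3'UTR; a seed site with opposite fold
   changes (inverse association) is the signature of candidate direct
   repression.

pairmir implements the full chain — normalization, the mixed model, the
bootstrap regression, seed matching, report rendering — together with a
synthetic paired-cohort generator that plants known fold changes, known
gene::miRNA couplings and known seed sites, so every stage is testable
against ground truth. It is intended for statisticians and computational
biologists who want the complete, reproducible pipeline rather than a
one-off analysis script.

## Worked example

```r
library(pairmir)

cfg <- sim_config(n_subjects = 120, n_genes = 150, n_pathway_genes = 8,
                  n_mirnas = 40, n_couplings = 4, frac_seed_planted = 1,
                  seed = 42)
sim <- generate_cohort(cfg)
sim$cohort
#> <paired_cohort: 150 genes x 240 samples, 40 miRNAs, 120 subjects>

de <- run_de(sim$cohort)
de[, c("gene", "fold_change", "fdr_p", "direction")]
#>              gene fold_change     fdr_p direction
#> gene0001 gene0001       0.900  3.80e-02   neither
#> gene0004 gene0004       0.485  2.20e-35      down
#> gene0006 gene0006       4.984 2.69e-213        up
#> gene0008 gene0008       0.570  1.58e-27      down
#> ...
```

Three of the eight panel genes pass both the FDR and fold-change
criteria (the planted truth for this seed). Writing the cohort to disk
and running the full chain:

```r
d <- file.path(tempdir(), "cohort")
write_cohort(sim$cohort, d, sim$truth)
p <- function(f) file.path(d, f)
res <- run_pipeline(pipeline_config(
  p("gene_counts.tsv"), p("mirna_intensity.tsv"), p("metadata.tsv"),
  p("pathway_genes.txt"), p("protein_coding.txt"),
  p("mirna_sequences.fasta"), p("utr_sequences.fasta"),
  bootstrap_B = 2000, seed = 1), out_dir = file.path(d, "results"))
#> differential expression: 3 of 8 pathway genes beyond 0.67/1.50 at FDR 0.05 ...
#> miRNA filter: 40 of 40 detected in > 20% of normal samples
#> associations: 4 significant of 120 tested pairs (3 genes x 40 miRNAs)
#> seed matching: 7 (pair, length) matches over 4 significant pairs (4 inverse)

res$report[, c("gene", "gene_fc", "mirna", "mirna_fc", "beta",
               "fdr_p", "seed_match", "direction_class")]
#>       gene gene_fc  mirna mirna_fc  beta fdr_p seed_match direction_class
#> 1 gene0004    0.48 mir001     3.98  0.26  0.02       TRUE         inverse
#> 2 gene0004    0.48 mir039     0.61 -0.17  0.04       TRUE      concordant
#> 3 gene0006    4.99 mir038     0.37  0.19  0.02       TRUE         inverse
#> 4 gene0008    0.57 mir037     0.60  0.34  0.02       TRUE      concordant
```

Each report row is one significant gene::miRNA association: the gene's
and miRNA's rendered fold changes, the regression slope (beta), the
bootstrap FDR p, and whether a 6/7/8-nt seed site exists in the gene's
3'UTR — `inverse` marking the opposite-direction pattern of candidate
direct repression (concordant seed matches suggest indirect, feedback-loop
regulation instead). All four significant pairs here are the planted
couplings, and all carry their planted seed sites.

Report arithmetic is reproducible from printed summary tables:

```r
fold_change_from_means(46.72, 23.14)   # tumor mean / normal mean -> 2.02
percent_of(169, 217)                   # cohort share -> 77.9
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/run-pipeline.R` (`simulate` and `all` subcommands).

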