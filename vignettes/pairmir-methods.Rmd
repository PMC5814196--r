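---
title: "Methods: paired differential expression and miRNA association in pairmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential expression and miRNA association in pairmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pairmir analyses paired tumor/normal expression cohorts in three linked
stages: per-gene paired differential expression for a pathway panel, miRNA
association with the dysregulated genes on the subject-differential scale,
and seed-region matching of associated pairs against 3'UTR sequences. This
vignette documents the statistical models, the tunable parameters, the
synthetic cohort generator used for calibration and recovery testing, and
the numerical and design choices a maintainer should know about.

## Normalization

Two normalizations are used, each tied to one platform:

* **RPMPCG** (reads per million protein-coding genes), for RNA-Seq counts:
  a gene's count divided by the sample's total count over a designated
  protein-coding gene set, times 10^6. Within every sample the
  protein-coding rows of the result sum to exactly one million; rows
  outside the set share the same denominator.
* **75th-percentile scaling**, for miRNA array intensities: each sample is
  multiplied by (median over samples of the per-sample 75th percentile) /
  (that sample's 75th percentile). Afterwards every sample's 75th
  percentile equals the common median, which makes the operation
  idempotent. The percentile uses linear interpolation between order
  statistics (`stats::quantile` type 7); the convention is exposed as an
  argument because array vendors do not standardize it. The percentile is
  computed over **all** rows of the matrix, not only detected probes —
  detected-only is the other defensible reading, and switching would only
  rescale all samples jointly.

miRNAs enter the association stage only if detected (intensity strictly
above `detect_threshold`, default 0) in **strictly more than**
`min_frac_expressed` (default 0.20) of the *normal* samples. The strict
inequality is deliberate: a feature detected in exactly 20% of samples is
dropped.

Zeros are preserved as zeros; no pseudocount is added at normalization
time. Pseudocounts, where wanted, belong to fold-change reporting
(`pseudocount` argument of `run_de()`, default 0).

## Paired differential expression

For gene $g$ with counts $y_{ij}$ (subject $i$, sample $j \in
\{\text{normal}, \text{tumor}\}$), pairmir fits a negative binomial mixed
model with log link:

$$ y_{ij} \sim \mathrm{NB}(\mu_{ij}, k), \qquad
   \log \mu_{ij} = o_{ij} + \beta_0 + \beta_1\,\mathrm{tumor}_{ij} + u_i,
   \qquad u_i \sim N(0, \sigma^2) $$

with NB2 variance $\mu + \mu^2/k$. The offset $o_{ij}$ is the log of the
sample's total protein-coding count, so $\beta_1$ is the log fold change
of the gene's *relative* expression (RPMPCG scale) in tumor versus paired
normal tissue, and the model is invariant to global library-size
rescaling. The random intercept $u_i$ absorbs whatever subject-level
baseline the offset does not.

Estimation choices (`fit_nb_mixed()`):

* The marginal likelihood integrates $u_i$ out by **adaptive
  Gauss–Hermite quadrature**: per subject, a damped Newton search finds
  the posterior mode of $u_i$ and its curvature, and the quadrature nodes
  (default `nagq = 9`) are centered and scaled there. `nagq = 1` is the
  Laplace approximation, available as a fast fallback.
* $(\beta_0, \beta_1, \log\sigma, \log k)$ are maximized jointly with
  `nlminb` (relative tolerance 1e-8, at most 200 iterations), which has
  the same maximizer as profiling the dispersion; $k$ is bounded in
  $[10^{-4}, 10^4]$ and $\sigma$ in $[10^{-8}, 50]$ for stability. The
  optimum is then polished by one or two Newton steps on a
  central-difference quadratic model, so algebraically equivalent
  reparameterizations (e.g. shifting all offsets by a constant) agree to
  about 1e-10 on $\beta_1$.
* `raw_p` is the Wald test on $\beta_1$ from the inverse numerical
  Hessian; a likelihood-ratio test is available via `test = "lrt"`. The
  two agree asymptotically and nothing in the downstream pipeline depends
  on the choice.
* Non-convergence (optimizer failure, non-finite standard error, all-zero
  gene) is flagged, never silent; `run_de()` excludes flagged fits from
  the FDR adjustment with a warning.

`run_de()` adjusts p-values across the genes of the run by
Benjamini–Hochberg and classifies directions with the inclusive cutpoints
`up` iff FC ≥ 1.50 and `down` iff FC ≤ 0.67 — the conventional
"meaningful fold change" thresholds used throughout the package (both are
configurable). Alongside the model fold change `exp(beta_tumor)`, the
ratio of arithmetic group means of RPMPCG values (`ratio_of_means`) is
reported: printed summary tables in this field are mean ratios, and report
parity requires reproducing that arithmetic exactly. Fold-change cells in
rendered reports always go through `fold_change_from_means()`, which
rounds half-away-from-zero to two decimals.

Stratified runs (`stratum = "MSI"` or `"MSS"`) subset subjects by
microsatellite status before fitting, keep complete pairs only, and
require at least 3 pairs.

## miRNA association

Differential profiles are per-subject tumor-minus-normal differences:
RPMPCG scale for genes, q75-normalized intensity scale for miRNAs, both
untransformed. For a candidate gene/miRNA pair, the model is ordinary
least squares of the gene differential on the miRNA differential with age
(years, uncentered) and sex (0/1 indicator) covariates; centering would
not change the reported partial F. The test statistic is the partial F
for dropping the miRNA term.

The p-value comes from a **residual-resampling bootstrap** of the null
model (covariates only): `B` times (default 10,000), null-model residuals
are resampled i.i.d. with replacement, added to the null fitted values,
and the partial F recomputed; the p-value is
$(1 + \#\{F^* \ge F_{\mathrm{obs}}\}) / (B + 1)$, the +1 convention
giving a valid Monte-Carlo p with minimum $1/(B+1)$. The resampling is
vectorized through a QR factorization of the two designs, so large `B` is
cheap. A per-pair seed is derived deterministically from the master seed
and the pair's identifiers, making results independent of candidate
ordering. An ordinary (i.i.d.) bootstrap matches the procedure's
assumptions of exchangeable residuals; a wild bootstrap was considered
and not included because the tested null model is homoscedastic in all
intended uses.

Multiplicity is controlled **at the gene level**: BH within each gene
across its tested miRNAs (`fdr_scope = "gene"`, the reading consistent
with per-gene FDR columns that differ across miRNAs within a gene; a
global BH is available). All candidate miRNAs are tested; the
*significant set* additionally requires both fold changes beyond the
1.50 / 0.67 cutpoints, so a pair with a small p-value but a miRNA fold
change of, say, 1.2 is excluded — the exclusion also applies when a gene
is otherwise significant, mirroring how borderline-FC miRNAs are dropped
from reported association tables.

## Seed matching

Seeds are the three windows of length 6, 7 and 8 anchored at miRNA
position 2 (1-based; the canonical seed convention). The anchor and
lengths are configurable because seed-construction conventions differ at
the margins (e.g. position-1 variants); the default covers the common
reading. Matching is exact string matching of the seed's DNA reverse
complement against the sense-strand 3'UTR — no G:U wobble, no mismatch
tolerance, no thermodynamic or conservation scoring: the procedure
identifies *candidate* direct sites, not validated targets. All
overlapping occurrences are reported (0-based offsets). A pair is
classified `inverse` when exactly one of the two fold changes is above 1
(the direct-repression pattern), `concordant` otherwise; fold changes of
exactly 1 are flagged `degenerate_fc` since their direction is undefined.
On uniform random UTRs of length $L$ the expected number of 6-mer sites
per pair is $(L-5)/4^6$, which quantifies the matcher's background rate.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline assumes, at
desk scale, with recorded ground truth. Defaults (`sim_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 217 | the paired-cohort scale the pipeline targets |
| `msi_fraction` | 0.134 | observed MSI share in such cohorts |
| `age_mean_sd` | 64.8, 10.1 years | observed age distribution |
| `n_genes` / `n_mirnas` | 400 / 60 | desk-scale panels; full runs stay in seconds |
| `frac_genes_dysregulated` | 0.375 | genome-wide dysregulation rate beyond the cutpoints |
| `fc_up_range` / `fc_down_range` | (1.5, 7) / (0.28, 0.67) | the span of reported pathway-gene fold changes |
| `nb_dispersion` | 8 | moderate overdispersion; free parameter, not estimated from any dataset |
| `subject_effect_sd` | 0.4 | log-scale subject heterogeneity; free parameter |
| `library_size_range` | (2e5, 8e5) | per-sample totals for reduced panels |
| `coupling_effect_range` | (0.2, 0.4) | magnitude of reported association slopes |

Counts are NB2 draws with mean `L_s · u_i · m_g · FC_g^tumor`; subject
intercepts are log-normal, so the downstream log-link model is correctly
specified. Because the offset is the realized protein-coding total, which
itself carries `u_i`, the fitted subject SD on generator output is near
zero; fitter tests that exercise $\sigma > 0$ therefore simulate directly
from the single-gene model instead.

Several generator details exist to make planted truth *identifiable*, and
are worth knowing:

* **Abundance mass balance.** Up- and down-regulated mass must cancel in
  a closed compositional system, or every normalized fold change is
  shifted by the ratio of totals. The generator rescales down-regulated
  genes' baseline abundance so the tumor protein-coding total keeps its
  normal expectation; planted fold changes are then realized exactly on
  the RPMPCG scale (verified within 10% at 200 pairs).
* **Stratified dysregulation.** The dysregulated set is sampled
  separately within the pathway panel and the background, so the panel
  always carries its share of planted effects.
* **Coupling injection.** Each coupling (gene, miRNA, slope `b`) adds
  `b ×` the subject's *centered, raw-scale* miRNA intensity differential
  to the gene's expected differential. Centering leaves the regression
  slope and partial F unchanged (the mean is absorbed by the intercept)
  while preserving the gene's planted fold change; using the raw rather
  than the q75-normalized differential keeps the q75 scale factors —
  which all miRNAs of a sample share — from leaking correlated
  normalization noise into the gene and inflating null associations with
  uncoupled miRNAs. The injection lands on the gene's larger group side
  (tumor for up/null genes, normal with flipped sign for down genes) so
  the shifted mean essentially never truncates at zero.
* **Coupled-miRNA intensity calibration.** A coupled miRNA's base
  intensity is set so the injected signal SD is about a quarter of the
  target gene's scale: strong enough to be detectable at ~200 pairs (the
  noncentrality regime of reported associations), small enough to avoid
  truncation. Each coupled miRNA regulates one gene; genes may have
  several miRNAs.
* Coupled genes are drawn from the dysregulated pathway genes and coupled
  miRNAs receive dysregulated fold changes, mirroring the discovery
  structure (only FC-qualified genes and miRNAs can enter the significant
  set).
* UTR background is i.i.d. uniform over {A,C,G,T} and planted sites
  overwrite non-overlapping windows at recorded offsets, so false-positive
  seed matches are exactly quantifiable.

One integer seed drives a single RNG stream (subjects → gene fold changes
→ abundances → miRNA fold changes/couplings → intensities → counts →
sequences → planted sites); identical configs and seeds give byte-identical
cohorts, and the caller's RNG state is left untouched.

What the generator does **not** emulate: FFPE degradation, array QC
failures, GC/length biases, correlated gene-gene expression modules,
read-level data, or real 3'UTR composition. Passing recovery tests
therefore demonstrates internal consistency of the estimators under the
assumed models — not robustness to the artefacts of real FFPE RNA-Seq or
array data.

## Numerical choices and degenerate inputs

* All report rounding is half-away-from-zero, applied only at render
  time; computation is at full precision.
* Bootstrap p-values can never be 0 (the +1 convention) and `B < 100` is
  rejected.
* An all-zero gene yields a flagged, NA-valued fit; a subject without
  exactly one tumor and one normal sample is a structural error naming
  the subject; a sample with zero protein-coding total or nonpositive
  75th percentile is an error naming the sample; rank-deficient
  association designs (constant miRNA differential) are errors.
* Fold change exactly 1 has no direction: `classify_direction` returns
  `neither`, and seed-match records flag `degenerate_fc`.

## Problem sizes used by the test-suite

Calibration and recovery checks run at the cohort scale the methods
target — 200 subject pairs — with panels reduced to a few hundred genes
and tens of miRNAs: fold-change recovery uses two 220-gene cohorts at 200
pairs; bootstrap size is checked over 1000 null simulations at B = 1000;
null-gene FDR control over 400 genes at 30 pairs; Wald-p uniformity over
1000 single-gene fits at 50 pairs; seed-matcher equivalence over 1000
random seed/UTR pairs. These sizes keep the full suite at a few minutes
while leaving Monte-Carlo margins well inside the tested bounds.

## Known limitations

* Wald p-values on the tumor coefficient are asymptotic; at very small
  pair counts (< ~20) or very low counts they can be mildly
  anticonservative. The LRT option behaves better in small samples.
* The gene-level BH reading of "FDR at the gene level" is one of two
  defensible interpretations; the global option is provided.
* Seed matching ignores wobble pairing and site context; it deliberately
  over-reports candidate sites relative to thermodynamic predictors.
* The generator's dispersion and subject-effect magnitudes are free
  parameters: nothing in the package estimates them from real data.
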