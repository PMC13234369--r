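---
title: "Pathway scores, anchor signatures and optimal-cutpoint survival: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway scores, anchor signatures and optimal-cutpoint survival: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathstrat)
```

## What this package computes

`pathstrat` implements the transcriptome-analysis toolkit used in
tumor-metabolism studies that relate a mitochondrial pathway (oxidative
phosphorylation, OxPhos) to an oncogenic signaling pathway (Wnt/β-catenin)
and to patient outcome. The pipeline has five statistical ingredients,
each exposed as an ordinary R function:

1. a **single-sample pathway activity score** — the oriented first
   principal component (PC1) of the z-scored log2 expression of a gene
   set's members;
2. an **anchor-gene co-expression signature** — the set of features whose
   Pearson correlation with an anchor feature (e.g. an *AK3* microarray
   probe) satisfies $r \le -\theta$ or $r \ge \theta$;
3. **association statistics** for tumor-vs-normal panels — paired and
   pooled-variance Student t-tests, and Pearson correlation with a
   pointwise 95% confidence band for the regression mean;
4. **survival stratification** — Kaplan–Meier estimation, the k-group
   log-rank test, the minimum-p log-rank cutpoint scan with an optional
   permutation correction, and a two-marker 2×2 stratification;
5. an image **co-localization percentage** — the ROI-masked Pearson
   coefficient $R$ between two fluorescence channels mapped to
   $(R+1)/2 \times 100$.

A latent-factor synthetic-data generator (`gen_expression()` and
friends) produces inputs with exactly the structure these methods assume,
so the whole pipeline is testable without cohort downloads.

## The pathway score model

For a gene set $G$ with expression $x_{gs}$ (log2 scale, gene $g$, sample
$s$), each gene is standardized across samples,
$z_{gs} = (x_{gs} - \bar{x}_g)/\mathrm{sd}(x_g)$, and PCA is run with
genes as variables and samples as observations. Sample $s$'s score is its
projection on PC1:

$$\mathrm{score}_s = \sum_{g \in G} v_g\, z_{gs},$$

where $v$ is the leading eigenvector of the gene–gene covariance of $z$.
The score is a consistent estimator of a per-sample pathway activity
under a single-factor model $x_{gs} = \mu_g + \lambda_g f_s +
\varepsilon_{gs}$ — which is precisely the structure the synthetic
generator plants, making the score's recovery a testable claim rather
than an assumption.

Numerical and design choices:

* **Standardization.** "Mean-centered and z-transformed" is implemented
  as one per-gene center-and-scale. The sample (n−1) SD is the default
  because that matches standard PCA practice and leaves the PC1 direction
  unchanged relative to the population SD (the two differ by a global
  scale factor only); `sd_type = "population"` is available for exact
  comparison against conventions that divide by n.
* **Orientation.** PC1 is defined only up to sign. The default rule
  (`"mean-z"`) orients the component so its correlation with the
  per-sample mean z-score of the set is non-negative, making "high score
  = high pathway expression" — the convention labels like OxPhos^high
  require. An anchor-gene rule (`"anchor:<id>"`, loading of the anchor
  forced non-negative) and `"none"` are provided. Whatever the rule, the
  output is deterministic: identical input yields bit-identical scores.
* **Cohort.** PCA is fit on all samples supplied; restricting to tumors
  is an explicit caller-side filter, never hidden behavior.
* **Missing and degenerate genes.** Set members absent from the matrix
  are dropped with a warning and listed in `genes_missing`; zero-variance
  genes are dropped with a warning; fewer than two usable genes is an
  error. Nothing is imputed.
* **Tolerances.** Scores are exactly re-centered after projection; the
  mean-zero invariant is tested at `1e-8` times the score SD.
* The OxPhos gene set is the KEGG oxidative-phosphorylation set
  augmented (set union) with the five pyruvate-dehydrogenase-complex
  genes `PDHA1, PDHB, DLAT, DLD, PDHX` via `build_oxphos_geneset()`.

## The anchor-gene signature

`build_gene_signature()` computes the Pearson correlation of every other
nonconstant feature with the anchor row and applies the membership rule
$r \le -\theta$ or $r \ge \theta$ with $\theta = 0.3$ by default. Points
worth stating explicitly:

* Membership uses **only** the correlation-magnitude rule. Two-sided P
  values (t-distribution, n−2 df) are reported alongside for reference,
  but no P threshold and no multiple-testing correction enter the rule —
  the signature definition is the thresholded coefficient itself.
* The anchor is excluded from its own signature (its inclusion would be
  vacuous at $r = 1$).
* Which samples enter the correlation (all vs tumors only) is a caller
  parameter, default all supplied samples. For published cohorts the
  original choice is not always recorded; the reproduction test tries
  both and accepts the one that matches the published count.
* Enrichment of a signature (GSEA, gene-ontology tools) is out of scope:
  the package only writes the `.rnk` (fold-change pre-ranking,
  `rank_by_fold_change()` + `write_rnk()`) and `.gmt` inputs those
  external tools consume. The conventional significance constants for
  those tools (P < 0.05, FDR < 0.25) are recorded in the run manifest as
  metadata only.

## Survival stratification and the min-p cutpoint

`km_estimate()` wraps the product-limit estimator (via the `survival`
package); subjects censored at an event time remain in the risk set at
that time. `logrank_test()` implements the unweighted k-group log-rank
chi-square (observed−expected deaths with hypergeometric variance)
in-package; it is cross-checked against `survival::survdiff()` in the
test suite and shares its internals with the cutpoint scan.

`minp_cutoff()` dichotomizes a marker at the cutoff minimizing the
two-group log-rank P value:

* **Candidates** are midpoints between consecutive distinct sorted
  marker values — midpoints keep group labels stable under measurement
  jitter, unlike cutting at observed values.
* **Group-size floors.** Both groups must contain at least 5% of the
  cohort and at least 10 subjects by default. The 5% fraction is chosen
  deliberately low because published optimal splits can be as unbalanced
  as 31 vs 343 (≈ 8%); the common 10% floor would exclude them.
* **Tie-breaks.** Equal minimum P values resolve to the more balanced
  split, then to the smaller cutoff, so results are reproducible.
* **"Low" is closed on the low side:** low = marker ≤ cutoff; this rule
  is stated in every output header and in the run manifest.
* The scan is computed by a vectorized formulation: with subjects sorted
  by marker, every candidate's per-event-time low-group risk counts are
  cumulative sums of an at-risk indicator matrix, so one matrix product
  yields all candidate chi-squares. The test suite verifies the scan
  equals `survdiff` at every candidate.

**Selection bias.** Minimizing P over cutoffs inflates the type-I error
well above nominal — under the null the raw min-p procedure rejects at
several times α = 0.05 (the test suite demonstrates this at n = 200 over
1000 replicates). The permutation option (`n_permutations`) re-runs the
scan on marker-permuted cohorts and reports the fraction of permuted
minimum P values at or below the observed one; this restores nominal
size. It is **off by default** because published min-p analyses
conventionally report the raw log-rank P; anyone using the cutpoint
inferentially should switch it on.

`stratify_two_markers()` builds the 2×2 classification (each marker cut
by its own min-p scan, or at its median) and reports one overall 4-group
log-rank test; `pairwise_logrank()` provides the six pairwise tests when
needed. Whether a published 4-group figure used the overall or pairwise
test is often unstated; the overall test is this package's primary
output because it answers a single well-posed question, and the pairwise
table is deliberately left unadjusted (callers choose their correction).

## Association tests

* The unpaired test defaults to the classical pooled-variance Student
  form because that is what "Student's t-test" names; Welch's form is a
  flag. Degenerate inputs (zero-variance differences, constant vectors)
  raise errors instead of propagating NaN, so pipeline failures are loud.
* `pearson_with_regression()` reports the 95% **confidence band for the
  conditional mean** (not a prediction interval) on a 100-point grid over
  the x-range — the convention behind the gray bands in score-vs-score
  scatter plots. |r| = 1 is flagged as degenerate with P reported as 0.

## Co-localization percentage

`coloc_percentage()` computes the plain Pearson coefficient over the
masked pixels and maps it by $(R+1)/2 \times 100$. No intensity
thresholding and no Costes-style randomization are applied: common
ImageJ plugins apply such pre-processing, but the formula itself is
defined on the plain coefficient, and adding unstated pre-processing
would be invention. The statistic is invariant to positive affine
rescaling of either channel and symmetric under channel swap.
Per-cell percentages aggregate by mean ± SEM (`per_cell_summary()`); a
single cell reports SEM 0 with an explicit `single_cell` flag.

## The synthetic-data generator

`gen_expression()` draws
$x_{gs} = \mu_g + \lambda_g f_{p(g),s} + \delta_g\,[\mathrm{tumor}] +
\varepsilon_{gs}$ directly on the log2 scale, with pathway factors
$f \sim \mathcal{N}(0, R)$ jointly normal at a configurable correlation
matrix, an anchor gene tracking its own latent factor, planted signature
genes whose loading is chosen so their true correlation with the anchor
equals the configured ρ exactly, and i.i.d. Gaussian noise.
`gen_survival()` draws Weibull (default exponential) proportional-hazards
event times with uniform censoring; `gen_paired_cohort()` gives each
subject a tumor and a normal column sharing the latent profile;
`gen_coloc_field()` draws bivariate-normal pixel pairs.

Default conditions (fixed once, stated here so that recovery tests are
interpretable): 226 samples — a lung-adenocarcinoma microarray cohort
size — with two 50-gene pathways, loadings $\mathcal{N}(1, 0.25^2)$,
noise SD 0.5 (per-gene SNR ≈ 2), factor correlation ρ(OxPhos, Wnt) =
−0.7 matching the magnitude reported for such cohorts, 100 signature
genes at ρ = 0.5 over 500 background genes, anchor tumor shift −1 log2
unit, baseline hazard 0.1 with uniform censoring on (0, 30) (≈ 32%
censoring), and hazard ratio 3 at a 40th-percentile threshold for
change-point designs.

What the generator does **not** emulate — and hence what passing
recovery tests do not establish about real cohorts: probe-level
artifacts (cross-hybridization, probe-affinity biases), batch and array
effects, heavy-tailed or skewed expression noise, correlated background
genes, non-proportional hazards, and informative censoring. Recovery
results certify the estimators under their own model assumptions, not
robustness to violations of them.

## Verification problem sizes

The automated checks run at the sizes the recovery claims name: PC1
oracle equivalence on random matrices up to 10×10 against a brute-force
covariance eigendecomposition (tolerance 1e-8, up to sign); score–factor
recovery at n = 200 with 50 genes; signature sensitivity/specificity at
n = 300; cutpoint recovery at n = 400; factor-correlation recovery at
n = 226 averaged over 200 replicates; null calibration of the log-rank
(median split) and Pearson tests over 1000 replicates each; and the
min-p selection-bias demonstration with its permutation correction at
n = 200 over 1000 replicates with 200 permutations per replicate —
enabled by the vectorized scan, which makes a full corrected replicate
cost roughly a quarter of a second.

## Known limitations

* The min-p cutpoint is a biased estimator of any true change point and
  its raw P value is anti-conservative; the permutation correction fixes
  size but not the optimism of the cutoff location itself.
* Pathway scores summarize a gene set by one component; sets whose
  member genes split into anti-correlated modules are poorly summarized
  by PC1, and `explained_variance_fraction` should be inspected.
* Signature membership by a fixed |r| threshold has no error-rate
  guarantee; the reported P values make the operating characteristics
  visible but do not enter the rule.
* No Cox modeling, hazard-ratio confidence intervals, GSVA/ssGSEA-style
  scores, or normalization are provided; inputs are assumed
  pre-normalized.
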