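---
title: "Screening immune-related lncRNA–mRNA ceRNA pairs: models and methods"
author: "immuneCeRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening immune-related lncRNA–mRNA ceRNA pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immuneCeRNA)
```

# Scope and data model

The package analyses a two-group (control vs case) genes-by-samples
expression matrix, held in an `ExpressionExperiment` (a
`SummarizedExperiment` with a `group` column and a `scale` flag). All
statistics operate on log2 expression; linear-scale input is transformed
as log2(x + 1) with a fixed pseudo-count of 1, and deconvolution — which
works on the linear scale — inverts that transform. Each group must have
at least two samples; the defaults throughout mirror a small clinical
microarray design of 11 controls vs 15 cases, with an independent
11-vs-12 validation cohort.

Three annotation inputs complete the picture: a `GeneCatalog`
partitioning genes into mRNA/lncRNA with an immune flag (ImmPort-style
list membership; only mRNAs carry the flag, since immune gene lists
contain protein-coding genes only), an `InteractionTable` of
deduplicated (miRNA, gene) edges (miRcode-style, covering both
biotypes), and for deconvolution an LM22-style marker-genes × cell-types
signature matrix.

# Differential-expression screen

Per gene, the log2 fold change is mean(case) − mean(control) and the
p-value comes from a two-sided Welch t-test (default) or Kruskal–Wallis
test. The screening call is `p < alpha` and `|log2FC| > lfcCutoff`
(defaults 0.05 and 1.0) with **strict** inequalities, so boundary genes
are excluded — with continuous data the boundary has measure zero, and
strictness makes the rule unambiguous. The raw p is the default basis
for the call, matching common practice in small-cohort biomarker
screens; BH-adjusted p-values are always computed and stored, and
`useAdjusted = TRUE` switches the call to them — the better-calibrated
choice when genome-scale error control matters more than sensitivity.
A gene with zero variance in both groups has no testable signal; it
receives p = 1 with a warning rather than an error, so one degenerate
probe cannot abort a screen. Welch rather than a count-based
negative-binomial model is deliberate: the intended inputs are
continuous (microarray or otherwise normalised) gene-level intensities,
not raw counts.

`pcaCoordinates()` projects samples onto principal components of the
sample-centred matrix (no gene scaling), reporting explained-variance
ratios; it is quality control, not inference.

# ceRNA admission

The screen's core is a two-criterion rule on (candidate lncRNA, immune
mRNA) pairs:

1. the two genes share at least one miRNA in the interaction table, and
2. their Pearson correlation exceeds +`rThreshold` (default 0.8).

The literature formulates criterion 2 as "positively correlated with
|r| > 0.8"; positivity is the binding constraint, so admission requires
`r > +0.8`, and strongly negative pairs are reported by
`pairwiseCorrelation()` but never admitted. Correlations are computed
across **all samples pooled** (a per-group analysis is available by
subsetting the `ExpressionExperiment`), because the published scatter
fits that motivate the criterion pool both groups. Pooling has a
well-known side effect worth keeping in mind: two genes that are both
differentially expressed in the same direction are correlated through
the group shift alone — with |log2FC| = 2 and within-group sd 0.5 the
expected pooled r is already ≈ 0.8 for *independent* genes. The shared
miRNA requirement and the validation stage are what keep such pairs in
check; an optional `corrAlpha` adds a significance requirement on the
correlation itself.

Correlation p-values use the exact t-distribution with n − 2 df.
Zero-variance genes make r undefined; those records are flagged
`degenerate` (r = 0, p = 1) and excluded from admission. Output is
sorted by r descending with lexicographic (lncRNA, mRNA) tie-breaks so
identical inputs always give identical ordered output. The
high-stringency tier (`stringencyFilter()`, cutoff 0.91) is applied
*after* the miRNA join; because both filters are intersections the final
set is the same in either order. `assembleNetwork()` expands admitted
pairs into the tripartite graph (every shared miRNA contributes one edge
to each member), which exports to Cytoscape as SIF or GraphML; by
construction every miRNA node links at least one lncRNA and one mRNA.

# Cross-cohort validation

No standard retention rule exists for confirming co-expression pairs in
an independent cohort, so the package takes the strictest reading
consistent with reported usage: a pair is `validated` iff both members
are significantly up-regulated in cases (p < alpha, log2FC > 0 — no
fold-change magnitude requirement, as confirmation figures report
significance only) **and** the validation correlation is positive with
p < alpha. `direction = "consistent"` relaxes "up" to
"same significant direction for both members", for settings where
down-regulated pairs are of interest. Pairs missing a member in the
validation matrix fail with reason `"absent"` rather than erroring.

# Signature deconvolution

`estimateFractions()` re-implements the published signature-regression
scheme rather than calling an external service. Per sample, the profile
restricted to the signature's markers (at least 50% of markers must be
present) is regressed on the signature columns either by

* **NNLS** (Lawson–Hanson via `pracma::lsqnonneg`) — the fast default,
  exact on noise-free mixtures; or
* **ν-SVR** — linear ν-support-vector regression at ν ∈
  {0.25, 0.5, 0.75} (`e1071::svm`), keeping the lowest-RMSE fit and
  clamping negative coefficients to zero, as in the published algorithm.

Coefficients are renormalised to sum to 1, giving non-negative fractions
on the simplex (tolerance 1e-9, enforced by the `FractionTable`
validity). Z-score standardisation of the marker vectors is on by
default for ν-SVR (matching the published scheme, whose coefficients are
renormalised anyway) and off for NNLS, where it would break the exact
recovery of noise-free linear mixtures; `standardize` overrides either
default. With `nPerm > 0`, an empirical p-value per sample compares the
reconstruction correlation against refits of random-gene profiles drawn
from the full matrix: p = (1 + #{r\* ≥ r}) / (nPerm + 1), bounded below
by 1/(nPerm + 1); samples with p ≥ 0.05 are conventionally excluded
from downstream composition analyses. Group comparison of fractions uses
Kruskal–Wallis (default) or Wilcoxon per cell type with BH adjustment —
fractions are bounded, compositional and non-normal, so rank tests are
the defensible default. Note the simplex constraint itself induces
negative cell–cell correlations (exactly −1 with two cell types);
`celltypeCorrelations()` reports the raw Pearson structure and leaves
compositional corrections to the analyst.

# The synthetic-data generator

`simulateTranscriptome()` emulates the study design so that recovery is
checkable:

* baseline log2 means per gene ~ N(6, 1.5²), within-group noise sd 0.5 —
  values typical of normalised log2 microarray intensities;
* planted DE genes shift the case mean by |log2FC| = 2 (an
  unambiguously large effect at n = 11 vs 15);
* each of 10 planted ceRNA pairs (lncRNA + immune mRNA, both up) shares
  a latent per-sample factor. The loading is chosen so the **total**
  within-group variance stays at noiseSd²: loading² = r·noiseSd²,
  residual variance (1 − r)·noiseSd², giving within-group Pearson
  correlation exactly the target r (default 0.95) while keeping pair
  members statistically identical to other DE genes. Feasible targets
  are r ∈ (0, 1]; r = 1 means zero residual noise.
* 10 decoys per class: *correlated-no-miRNA* (true-pair statistics, no
  shared miRNA — caught by the join), *miRNA-no-correlation* (shared
  miRNA, independent noise) and *anti-correlated* (shared miRNA,
  negatively loaded factor). Members of the latter two classes are
  planted DE in opposite directions; with same-direction shifts the
  pooled-correlation confound described above would make "uncorrelated"
  decoys borderline-admissible by construction, which would test the
  confound rather than the screen. All decoy mRNAs carry the immune
  flag, so decoys survive the DEG and immune stages and exercise the
  admission criteria themselves.
* the interaction table adds random background edges (filtered so they
  never create sharing for a correlated-no-miRNA decoy);
* passing a previous run's `truth` redraws only the noise — the model of
  an independent validation cohort from the same population.

`simulateMixtures()` draws fractions from a symmetric Dirichlet
(concentration 1 = uniform on the simplex), forms signature × fractions
on the linear scale, adds Gaussian noise truncated at zero, and returns
the truth. `syntheticSignature()` builds a block marker structure (5
types × 10 markers by default, markers ≈ 100 in their own type vs ≈ 10
elsewhere); the shipped `inst/extdata/synthetic_signature_5type.tsv` is
one such synthetic matrix, not a published signature.

What the generator does **not** emulate: probe-level effects, batch
effects, count overdispersion, correlated background co-expression
modules, miRNA expression itself, and realistic marker collinearity
between immune subtypes. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated model, not performance on
real cohorts — in real data, correlated backgrounds and collinear
signatures will push all recovery rates down.

Simulation sizes used by the test-suite and the acceptance script —
1,000 genes (100 lncRNAs) × 26 samples, five seed replicates, 50
mixture samples, 2,000 null genes for calibration — keep every stage at
seconds scale while leaving Monte-Carlo error well inside the asserted
margins.

# Numerical and formatting choices

* TSV dialect everywhere: tab delimiter, "." decimal, no quoting, UTF-8;
  numeric output at 17 significant digits so write-then-read round-trips
  are bit-identical. Published correlation tables printing the Unicode
  minus (U+2212) are normalised to the ASCII hyphen on read.
* Duplicate gene rows collapse by per-sample maximum (configurable to
  mean) — the usual rule for multiple probes per symbol.
* Symbol matching is exact and case-sensitive by default, with an
  opt-in uppercase normalisation for human symbols.
* All generators and permutation procedures are seed-deterministic;
  ordered outputs break ties lexicographically.

# Limitations

The screen is correlational: admitted pairs are co-expression hypotheses
consistent with a ceRNA mechanism, not demonstrations of miRNA-mediated
competition (miRNA expression is never observed). Pooled correlations
conflate group shift with within-group co-variation, as discussed.
Database-derived inputs (immune lists, interaction edges, signatures)
carry their own version- and coverage-dependence, which is why
dataset-level counts from any particular cohort/database combination are
not meaningful targets for this package and are not asserted anywhere in
it.
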