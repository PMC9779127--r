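# immuneCeRNA

Immune-related lncRNA–mRNA ceRNA screening and immune-cell deconvolution
for two-group bulk transcriptomes.

## The problem

In diseases with an inflammatory component — the motivating setting is
pulmonary arterial hypertension (PAH), profiled as case-vs-control lung
transcriptomes — long non-coding RNAs can act as competing endogenous RNAs
(ceRNAs): a lncRNA and an mRNA that share miRNA response elements compete
for the same miRNAs, so their expression tends to be positively
correlated. This package implements the complete desk analysis used to
nominate such immune-related lncRNA–mRNA pairs from expression data, and
to ask how they relate to immune-cell infiltration:

1. **Differential expression** — per-gene Welch *t* (or Kruskal–Wallis)
   on log2 expression; a gene is a DEG when *p* < 0.05 and
   |log2 fold change| > 1 (strict inequalities; BH-adjusted *p* is always
   computed and can be used instead). A PCA projection of the samples is
   provided for quality control.
2. **Immune intersection** — DEG mRNAs are intersected with an
   ImmPort-style immune gene list; DEG lncRNAs are the pairing candidates
   (lncRNAs acquire immune relevance only through co-expression).
3. **ceRNA admission** — a (lncRNA, mRNA) pair is admitted iff it shares
   at least one miRNA in a miRcode-style interaction table **and** its
   Pearson correlation across all samples satisfies *r* > 0.8 (positivity
   is binding: strong negative correlations are never admitted). A
   high-stringency tier retains pairs with |*r*| > 0.91. Admitted pairs
   assemble into a tripartite lncRNA–miRNA–mRNA network, exportable as
   Cytoscape SIF or GraphML.
4. **Cross-cohort validation** — each admitted pair is re-tested in an
   independent two-group dataset: validated iff both members are
   significantly up-regulated in cases and the pair correlation is
   positive and significant.
5. **Immune-cell deconvolution** — CIBERSORT-style signature regression
   (non-negative least squares, or a linear ν-SVR ensemble over
   ν ∈ {0.25, 0.5, 0.75} with negative coefficients clamped) estimates
   per-sample cell-type fractions (non-negative, summing to 1), with
   permutation *p*-values, group comparison per cell type, cell–cell
   correlation structure, and pair-expression↔fraction association.

Because the original cohorts live in GEO and the annotation databases
cannot be redistributed, the package ships a synthetic-data generator
(`simulateTranscriptome()`, `simulateMixtures()`) that plants known fold
changes, latent-factor-correlated ceRNA pairs with shared miRNAs, three
decoy-pair classes, and Dirichlet signature mixtures — so every stage is
verified by parameter recovery.

## Worked example

```r
library(immuneCeRNA)

sim <- simulateTranscriptome(seed = 1)   # 11 control vs 15 case, 1000 genes
sim$expr
#> ExpressionExperiment: 1000 genes x 26 samples (log2 scale)
#>   groups: 11 control / 15 case

deg <- differentialExpression(sim$expr)
cls <- classifyDEGs(deg, alpha = 0.05, lfcCutoff = 1)
# up: 84   down: 36

ii    <- immuneIntersect(c(cls$up, cls$down), sim$catalog)
# immune mRNAs: 51   candidate lncRNAs: 41
cors  <- pairwiseCorrelation(sim$expr, ii$candidate_lncrnas, ii$immune_mrnas)
pairs <- buildCeRNAPairs(cors, sim$interactions, rThreshold = 0.8)
head(pairs[, c("lncrna", "mrna", "r", "shared_mirnas", "tier")], 4)
#>    lncrna     mrna         r   shared_mirnas     tier
#> 1 LNC0002 GENE0002 0.9952920 miR-002;miR-003 standard
#> 2 LNC0001 GENE0001 0.9924406         miR-001 standard
#> 3 LNC0006 GENE0006 0.9921995         miR-008 standard
#> 4 LNC0005 GENE0005 0.9921480         miR-007 standard

nrow(stringencyFilter(pairs, 0.91))      # 10 — exactly the planted pairs
net <- assembleNetwork(pairs)
#> ceRNA network: 35 nodes, 28 edges

valid <- simulateTranscriptome(nControl = 11, nCase = 12,
                               truth = sim$truth, seed = 2)
res <- validatePairs(pairs, valid$expr)
#> 11 / 11 pairs validated
```

The screen admits all 10 planted pairs (plus one background pair that is
genuinely correlated and miRNA-linked); none of the 30 planted decoys is
admitted, and every admitted pair is confirmed in the independent cohort.

Deconvolution against a 5-cell-type synthetic signature:

```r
sig <- syntheticSignature(seed = 3)
mix <- simulateMixtures(sig, nSamples = 26, noiseSd = 2, seed = 4)
ft  <- estimateFractions(mix$expr, sig)
round(cellFractions(ft)[1:3, ], 3)
#>        CellTypeA CellTypeB CellTypeC CellTypeD CellTypeE
#> MIX001     0.504     0.016     0.269     0.120     0.091
#> MIX002     0.027     0.070     0.860     0.003     0.039
#> MIX003     0.041     0.538     0.000     0.213     0.208
```

Estimated fractions track the generator's Dirichlet truth with a mean
absolute error of about 0.005 per fraction at this noise level.

Real data enter through `readExpressionTable()`, `readGeneCatalog()`,
`readInteractionTable()` and `readSignatureMatrix()` (tab-separated, see
the help pages); `inst/extdata/` holds a published high-stringency pair
table used in examples and a small synthetic signature fixture.

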