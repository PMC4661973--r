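---
title: "Modeling p65 recruitment from pre-stimulation chromatin: methods and design"
author: "kbcistrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling p65 recruitment from pre-stimulation chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(kbcistrome)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter, what
the synthetic generator does and does not emulate, and where the design was
genuinely open.

## The modeling problem

NF-κB dimers containing p65 are held inactive in the cytoplasm and flood
the nucleus within minutes of stimulation — too fast for the chromatin
landscape to be rebuilt first. Site selection must therefore be readable,
to a large extent, from the *pre-stimulation* state: DNase accessibility,
histone marks, DNA methylation, sequence motifs, and the TFs already bound.
The package treats this as a supervised problem. The unit of analysis is
the **regulatory site**; the outcome is binary post-stimulation p65
occupancy; the features are everything measured before stimulation.

## Regulatory sites

Sites are maximal groups of TF and DHS peaks that overlap or are directly
adjacent — a zero-length gap merges, a 1-bp gap does not. This conservative
union restricts all statistics to regions with *a priori* regulatory
evidence, which makes enrichment tests stringent: the background is not the
genome but the regulatory compartment. p65 peaks that touch no site are
kept as **inaccessible** sites (no TFs, no DHS); by construction they are
all p65-positive, so propensity contrasts (methylation enrichment,
occupancy curves) are best read within the accessible compartment, and the
package's own validation does exactly that.

Occupancy counts distinct bound TFs but never CTCF, RAD21 (cohesin) or
DHS — architectural/accessibility signals rather than sequence-specific
activators. Stages encode the assembly state: promoters with 1–2 TFs
(`prox_s1`), distal sites with exactly one TF (`dist_s1`, nascent
enhancers), distal sites with 2–4 TFs (`dist_s2`, partially assembled);
everything else is `other`. TSS proximity means overlap with the TSS point
itself; a `tssFlank` parameter exists for sensitivity analyses but defaults
to 0 because the classification rule is an overlap rule.

Methylation context uses only CpGs covered by ≥ 10 reads in *both*
replicates (`minCoverage`); the site value is the mean over retained CpGs
of the replicate-mean percent, binned at 25/75. CpG-island status requires
both island definitions to agree; disagreement yields `unclassified`
rather than a forced call.

## Signal scaling

Counts are normalized by site length and passed through
`s(d) = tanh(c · d / q)`, with `q` the 95th percentile of the mark's
nonzero densities and `c = 0.5`. The functional form was an open choice —
only "sigmoid, approximately linear up to the 95th percentile" is
specified by the approach the package implements — and tanh with `c = 0.5`
satisfies it: on `[0, q]` the map deviates from linearity by under 4 %
(tanh(0.5) = 0.462 ≈ 0.5), and it is bounded by 1 so outlier densities
cannot dominate a factorization. `q` is computed over nonzero densities
only, otherwise sparse marks would scale against a zero quantile. Both `c`
and the percentile sit in `RunConfig`. A consequence worth stating: scaled
magnitudes are comparable across sites within one mark, but not between
marks — each mark has its own `q`.

## Chromatin codes (NMF)

For each site class, the scaled matrix `V` (sites × 8 marks, values in
[0, 1]) is factorized as `V ≈ W·H` with `W, H ≥ 0`, rank `k = 4`. Rows of
`H` are "codes" — combinations of tied mark levels — and `W[i, ]` says how
much of each code site *i* uses. Codes decorrelate the notoriously
collinear histone marks, so downstream regression coefficients are
interpretable where raw-mark coefficients would not be.

Fitting choices (all open in the source approach, fixed here):

* **Loss/updates**: Frobenius loss with multiplicative updates, which keep
  non-negativity exactly and decrease the loss monotonically.
* **Initialization**: NNDSVD for the first start (deterministic, good
  basins), plus 9 uniform-random restarts; best reconstruction error wins.
  Tolerance 1e-5 relative change, cap 2000 iterations.
* **Identifiability**: the scale split between `W` and `H` is arbitrary,
  so each code row is max-normalized (scale moved into `W`) and codes are
  ordered by descending total weight mass. This makes factorizations
  comparable across classes and runs; `compareCodes()` then matches codes
  between classes by exhaustive best cosine assignment (k! = 24
  permutations).
* **Rank**: fixed at 4 per class. `nmfScree()` provides the error-vs-rank
  diagnostic but rank selection is not part of inference.

## Logistic prediction

`fitLogistic()` implements the full protocol: stratified 80/20 split;
10-fold cross-validation on the training set over penalty {L1, L2} ×
C ∈ {0.01, 0.1, 1, 10, 100} scored by mean MCC at cut-off 0.5; refit at
the winning setting; scan of the cut-off p_c on a 0.01 grid maximizing
training MCC; report AUC and MCC on the held-out fifth. Stratification is
our addition: at 2–8 % positive rates an unstratified split can lose the
positive class entirely. Among grid points whose CV MCC is within 0.005 of
the best we select the largest C (weakest penalty): MCC is a thresholded
metric and nearly flat in C, while shrinkage visibly biases the slope of a
rare binary covariate such as motif presence. Continuous features are
z-scored (slopes are standardized natural-log odds ratios); binary motif
stays 0/1. `glmnet` does the penalized fitting with λ = 1/(C·n).
`dropOneRobustness()` reports the mean ± SD of each slope across refits
omitting one other covariate — an inexpensive collinearity diagnostic: an
SD comparable to the slope means the coefficient is not attributable to
its covariate.

Note the two log bases in the package: 2×2 enrichment statistics are
log₂-odds; regression slopes are natural-log odds ratios, as standard for
logistic coefficients.

## Enrichment statistics

`fetLogOdds()` reports the base-2 log odds ratio with Haldane–Anscombe
0.5-correction applied only when a cell is zero — and only to the ratio,
never to the exact p-value, which always comes from the uncorrected
counts. The RS statistic compares a set's mean feature value to its exact
sampling moments under random same-size sets, with the finite-population
correction (under it, the statistic is exactly antisymmetric between a set
and its complement); its p-value is one-sided because the statistic is
framed as enrichment. Proportions use Wilson intervals and the chi-square
score test without continuity correction. Raw p-values are reported
throughout (that is the convention of the analyses the package
implements); a Benjamini–Hochberg step can be applied by the caller via
`p.adjust` where families are large.

## Combinatorial TF analysis

The cooperativity matrix compares sites bound by both TFs of a pair
against sites bound by exactly one (within stage-2 enhancers, which hold
occupancy roughly constant); the direction is positive only if the joint
probability beats *both* single-TF probabilities. Entries with p ≥ 0.05
are masked in the display matrix and entries with p ≥ 1e-5 are capped at
+2/−1 *for display only* — stored statistics are never capped. A secondary
column compares each pair's joint odds to the mean joint odds over all
pairs ("two random proteins" baseline).

`tgcSearch()` grows clusters greedily from every single-TF seed: at each
step it adds the TF that maximizes the class log₂-odds, accepting only if
the gain is ≥ 0.2 (`tgcDelta`) *and* genome-wide support stays ≥ 40
(`tgcMinSupport`). Open details fixed here: seeds are single TFs;
expansion is best-first; ties break lexicographically by TF label (making
the search deterministic); the same rules run sign-flipped for depleted
clusters; only clusters that grew beyond their seed are emitted, since
singleton enrichments are already covered by `tfEnrichment()`. Support and
confidence are always genome-wide recounts over all regulatory sites;
enrichment and its exact p-value are class-local. `tnrSearch()` is the
complementary, less greedy view: level-wise (Apriori-pruned) enumeration
of TF itemsets up to size 4 with support ≥ 40, ranked by confidence then
support, dropping rules whose antecedent has a subset doing at least as
well. On data with genuine combinatorial structure the significant greedy
clusters re-appear among the top non-redundant rules, and the package
tests that property. `bestClusterExhaustive()` certifies optima on panels
small enough to enumerate.

## Linking sites to genes

The probabilistic gene–enhancer assignment that inspired this stage is
under-specified in its source, so the package states its own score and
treats it as a design assumption: a gene takes the site overlapping its
TSS as proximal (nearest midpoint on ties) and up to 3 distal sites within
100 kb, scored `jaccard(TF sets) × exp(−distance/50 kb)`. The Jaccard term
encodes the observation that an enhancer and its promoter tend to share
bound factors; the 50-kb kernel scale makes the score drop to ~0.14 of its
maximum at the 100-kb cut-off, keeping distant candidates alive only when
their TF similarity is strong. Genes without a proximal site use a neutral
similarity of 0.5. All three constants are `RunConfig` parameters. The
up-regulation analysis then compares fractions of up-regulated linked
genes between low- (≤ 2) and high- (≥ 5) occupancy promoter groups.

## The synthetic generator

`simulateBundle()` is first-class, tested code, and its defaults *are* the
study conditions of the package's validation: they were fixed once, by
matching the generator's marginals to the anchors the modeled system is
known to satisfy, before any downstream test was written.

* Toy genome of 5 chromosomes × 10 Mb; 20,000 sites of 300–1500 bp with
  ≥ 20 bp gaps (so merged site reconstruction is exact).
* p65 model: `logit P = −4.30 + 0.46·occupancy + 0.86·motif +
  Σ effects·z(W) + 0.9·hyper`, with code effects (0.3, −0.3, 0.8, −0.4)
  and motif prevalence 7.4 %. The base and occupancy slope were calibrated
  jointly so that the stage-2 background rate is ≈ 8 %, sites bound by 12
  TFs recruit p65 ≈ 75 % of the time, and the small inaccessible
  compartment (3 % of sites, all p65-positive) accounts for ≈ 24.5 % of
  p65 binding — the regime the method is meant to operate in.
* Marks: Poisson counts around `length × density-scale × (W·H)` with the
  four planted codes (active, repressive, primed, elongation) and sparse
  exponential weights; inaccessible sites get 10× attenuated weights.
* TF clusters: a planted CREB1/RAD21/JUND/FOXA2 cluster whose fully
  assembled sites recruit p65 at 0.75, surrounded by *partially* assembled
  sites (random proper subsets at background rate) so that every member TF
  is individually informative — successive intersections genuinely improve
  enrichment, as at real partially assembled enhancers. A depleted
  GATA3/TCF12/USF1 cluster (confidence 0.01) mirrors the one negative
  cluster the method is expected to find.
* Methylation: CGI sites draw low percents, a planted 15 % of distal
  non-CGI sites are hyper-methylated (and receive the +0.9 logit bonus);
  CpG counts, per-replicate noise and coverage are drawn so that the
  ≥ 10× both-replicate filter bites.
* Expression: genes linked to p65-bound promoters are up-regulated at 16 %
  (occupancy ≤ 2) falling linearly to 5 % (≥ 5); non-p65 promoters at 4 %.

What the generator does **not** emulate: read-level noise and mappability,
peak-caller artifacts, correlated TF co-binding beyond the planted
clusters, chromatin-state autocorrelation along the genome, CNVs, and
motif *positions* within sites (motifs are site-level flags). Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated generative model — identifiability, calibration, determinism —
not performance on real ChIP-seq, where mark collinearity and confounding
are harsher.

## Problem sizes and determinism

The validation suite runs the generator at 20,000 sites for cluster
recovery (20 seeds) and permutation calibration (100 relabelings), 5,000
sites for factorization recovery (noise SD 0.05), 20,000 observations for
slope recovery, 2,000 replicates at N = 1,000 for RS calibration, and a
200-site fixture for the end-to-end smoke test — sizes chosen so each
experiment has comfortable statistical power while the whole suite stays
quick on a laptop. Every stochastic stage consumes an explicit seed
(`RunConfig@seed` plus fixed stage offsets), and the pipeline writes a
manifest of config, input digests and output digests; identical seeds give
digest-identical reruns.

## Known limitations

* The sigmoid's exact form, the NMF normalization, the TGC seeding/tie
  rules and the link score are reasonable fixed choices for genuinely open
  design points; conclusions that hinge on them should be checked against
  the exposed `RunConfig` alternatives.
* The MCC-based grid selection is noisy at very low positive counts; below
  ~30 positives the reported test MCC is unstable even though the code
  runs.
* `tnrSearch()` enumerates itemsets; beyond ~40 TFs or support thresholds
  far below 40 it will get slow — it is not an FP-growth implementation.
* Inaccessible sites are p65-positive by definition, so any statistic that
  mixes them with accessible sites inherits that tautology; subset first.
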