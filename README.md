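# kbcistrome

Predicting stimulus-induced NF-κB (p65/RELA) recruitment from the
pre-stimulation chromatin landscape.

## The problem

Within minutes of an inflammatory stimulus (e.g. TNF), activated NF-κB
dimers enter the nucleus and bind tens of thousands of genomic sites. Which
sites are selected is largely pre-determined by the chromatin state before
stimulation: accessibility, histone modifications, DNA methylation and the
transcription factors (TFs) already parked on the DNA. `kbcistrome` is a
statistical toolkit for dissecting that pre-determination. It is aimed at
computational biologists who have peak calls, per-region mark counts and
methylation tables in hand and want to quantify which chromatin features —
singly and in combination — predict inducible TF binding.

## What it computes

* **Regulatory sites** — maximal groups of TF/DHS peaks that overlap or are
  directly adjacent (no gap) are merged into sites; post-stimulation p65
  peaks outside all of them become *inaccessible* sites. Sites are
  classified by TSS overlap and occupancy (TFs bound, never counting CTCF,
  RAD21 or DHS): stage-1 promoters (1–2 TFs), stage-1 enhancers (exactly 1
  TF, distal), stage-2 enhancers (2–4 TFs, distal), plus CpG-island
  (two-definition consensus) and methylation context (per-CpG coverage ≥ 10
  in both replicates; site mean binned low < 25 % ≤ medium ≤ 75 % < high).
* **Scaled mark signals** — per-site read counts are length-normalized to
  densities *d* and scaled per mark with *s(d) = tanh(c·d/q₉₅)*, a sigmoid
  that is nearly linear up to the 95th percentile of nonzero densities and
  saturates at 1.
* **Chromatin codes** — non-negative matrix factorization *V ≈ W·H* (rank 4
  per site class) decomposes mark patterns into codes (rows of *H*, tied
  mark levels) and per-site weights (*W*), which feed the predictor.
* **MCC-tuned logistic models** — binding is modeled as
  *logit P(p65) = β₀ + Σ βᵢ xᵢ* over code weights, single marks and binary
  motif presence; penalty (L1/L2) and strength C are selected by 10-fold
  cross-validated Matthews correlation coefficient on an 80 % training
  split, the cut-off p_c is tuned on the training set, and AUC/MCC are
  reported on the held-out 20 %.
* **TF combinatorics** — per-TF enrichment and pairwise cooperativity as
  base-2 log-odds from Fisher's exact test (2×2), plus two cluster searches:
  TGC greedily grows TF sets while each added TF improves the class
  log₂-odds by ≥ 0.2 without dropping genome-wide support below 40; TNR
  enumerates itemsets and keeps the top-k non-redundant association rules
  (TF set → p65) by confidence.
* **Gene linkage** — each gene gets ≤ 1 TSS-overlapping proximal site and
  ≤ 3 distal sites within 100 kb, scored by TF-set Jaccard similarity times
  an exponential distance kernel; up-regulation fractions are compared
  between low- and high-occupancy promoters with Wilson intervals and a
  two-proportion score test.
* **Statistics** — Fisher log₂-odds with Haldane–Anscombe zero-cell
  handling, the random-set (RS) statistic
  *Z = (X̄ − μ)/(σ/√m · √((N−m)/(N−1)))* for continuous features versus
  binary binding, and Wilson proportion intervals.

A synthetic-data generator (`simulateBundle()`) emits every input format
with planted, serialized ground truth (codes, effect sizes, TF clusters,
methylation structure, expression coupling), so the whole pipeline is
validated end-to-end against known answers.

## Worked example

```r
library(kbcistrome)

bundle <- simulateBundle(syntheticTruth(), nSites = 6000, nGenes = 2000, seed = 42)
cfg    <- runConfig(seed = 42)

sites <- buildSites(bundle$tfPeaks, bundle$p65Peaks, bundle$dhsPeaks)
sites <- classifySites(sites, bundle$tss, bundle$motifPeaks, cfg)
table(S4Vectors::mcols(sites)$stage)
#> dist_s1 dist_s2   other prox_s1
#>    1128    2008    2078     786

occ <- occupancyTable(sites)
occ
#> OccupancyTable: 6000 sites x 30 TFs; 728 p65-positive

head(occupancyCurve(occ), 4)
#>   occupancy n_sites p65_fraction     ci_low    ci_high
#> 1         0     883   0.23216308 0.20551111 0.26113538
#> 2         1    1476   0.04945799 0.03951880 0.06173628
#> 3         2    1536   0.05859375 0.04791265 0.07147721
#> 4         3    1061   0.14326107 0.12346637 0.16562968

cl <- tgcSearch(occ, "dist_s2", config = cfg)
head(cl[, c("cluster", "log2_odds", "p_value", "support", "confidence")], 3)
#>                 cluster log2_odds      p_value support confidence
#>  CREB1+FOXA2+JUND+RAD21  5.186156 8.439787e-42      72 0.76388889
#>        GATA3+TCF12+USF1 -3.566928 7.529320e-03      50 0.02000000
#>              NRF1+RAD21 -2.834057 6.566185e-02      60 0.06666667
```

The generator planted a CREB1/RAD21/JUND/FOXA2 cluster whose fully
co-occupied sites recruit p65 with probability 0.75, against a stage-2
background near 0.08; the greedy search recovers exactly that TF set, with
the empirical confidence (0.764 over 72 genome-wide sites) and a strongly
significant class enrichment. The occupancy curve shows the planted
monotone occupancy effect among TF-bound sites (occupancy-0 sites mix
DHS-only regions with inaccessible p65-only sites, hence their high
fraction).

Factorizing the stage-1 enhancer mark matrix:

```r
marks <- scaleCounts(bundle$markCounts, bundle$lengths, cfg)
sel   <- S4Vectors::mcols(sites)$stage == "dist_s1"
fit   <- fitNMF(markValues(marks)[sel, ], k = 4, seed = 42,
                siteClass = "dist_s1", config = cfg)
round(codes(fit), 2)
#>       H2A.Z H3K27ac H3K27me3 H3K4me1 H3K4me2 H3K4me3 H3K79me2 H3K9ac
#> code1  0.01    0.05     0.03    0.40    0.00    0.03     1.00   0.03
#> code2  0.52    0.01     0.00    0.86    1.00    0.02     0.01   0.02
#> code3  0.72    0.97     0.00    0.00    0.04    1.00     0.00   0.98
#> code4  0.24    0.04     1.00    0.01    0.06    0.01     0.01   0.04
```

Each row is a "chromatin code": a combination of tied mark levels
(elongation-like H3K79me2+H3K4me1, a primed H3K4me1/me2+H2A.Z code, an
active acetylation+H3K4me3 code, and a repressive H3K27me3 code — matching
the four planted generative codes up to order).

The whole chain — sites, scaling, NMF, prediction, clusters, cooperativity,
linkage — also runs as one call over a bundle directory:

```r
writeBundle(bundle, "sim")
runPipeline("sim", "out", cfg)   # writes TSVs + manifest.yaml
```

or from the shell via `inst/exec/kbcistrome simulate|run`.

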