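---
title: "Methods: Monte Carlo feature selection and epigenetic regulatory modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo feature selection and epigenetic regulatory modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mcfsomics` implements a multi-omics feature-selection and regulatory-modeling
workflow for cancer/normal cohorts measured on three layers: mRNA expression,
miRNA expression, and DNA methylation beta-values. Its core is Monte Carlo
feature selection with interdependency discovery (MCFS-ID); around it sit the
genomic-context annotation of differentially methylated sites (DMSs),
enrichment screens with constructed resampling nulls, methylation-aware
transcription-factor motif analysis, TF-IDF clustering of gene functional
descriptions, mass per-gene regression experiments, and per-target linear
regulatory models. Because real cohorts of this kind cannot ship with a
package, a synthetic-data module generates a complete miniature study with
known planted structure; every pipeline stage is validated by recovering that
structure.

# The MCFS-ID core

## Relative importance

MCFS-ID ranks features by growing a large forest of decision (or regression)
trees on random feature projections. With `mode = 2` (the default), each
sweep partitions the features into disjoint random blocks of `m` features
(`m = 200` by default, the conventional "splitSetSize" for wide omics
tables), so every feature is evaluated equally often; `mode = 1` instead
draws each projection independently. Each projection is evaluated on `t = 5`
random train/test splits (train fraction 0.66), one greedy binary tree per
split.

The relative importance of feature $g$ accumulates over all trees $\tau$ and
all nodes $n_g$ split on $g$:

$$ RI(g) \;=\; \sum_{\tau} q(\tau)^u \sum_{n_g \in \tau}
   IG(n_g)\left(\frac{n(n_g)}{n(\mathrm{root}(\tau))}\right)^{v}, $$

where $IG$ is the node's information gain in bits (classification) or its
population-variance reduction (regression), $n(\cdot)$ counts samples
reaching a node, and $q$ is the tree's held-out quality: weighted accuracy
(the mean of per-class accuracies) for classification, and
$\max(0, r_{\mathrm{Pearson}})$ between held-out predictions and truth for
regression. The exponents default to $u = v = 1$. Information gain is
measured in bits; any fixed logarithm base yields identical rankings, and
bits make hand-checkable oracles clean.

The regression-mode quality is a package design decision: it is bounded in
$[0, 1]$ like weighted accuracy and matches the Pearson-correlation lens
used by the downstream regression experiments.

## Interdependency graph

Every directly nested pair of split nodes — a parent node on feature $a$
whose child node splits on feature $b$ — contributes
$IG(b)\,n(b)/n(a)$ to the directed edge $a \to b$. Weights are summed over
the whole forest. Edges therefore measure how much a feature amplifies the
discrimination begun by another, not mere correlation. `idgraph_view()`
restricts a graph to the strongest nodes and edges for display, with
lexicographic tie-breaks so output is reproducible.

## Significance cutoff

The cutoff separating informative features from chance is built by rerunning
the full procedure `n_perm = 20` times on uniformly permuted target labels
and recording each run's maximum RI. The default statistic is the 95th
percentile of those maxima: a max-statistic that controls the family-wise
chance that any random-valued feature is flagged. The alternative
`cutoff_method = "mean_t"` (mean of the maxima plus a one-sided t-interval)
is exposed as a configuration option. Features with `RI > cutoff` form the
significant set.

The max-statistic null is deliberately conservative, and one property is
worth knowing: in a label-permuted run the best chance-correlated feature
wins its projection block's root uncontested in every sweep, whereas in the
real data redundant informative features shadow one another. With many
mutually redundant planted features, few normal samples, and strong class
imbalance, the weakest planted features can fall under the cutoff even
though they rank far above all noise features. The acceptance suite
documents this behaviour quantitatively; with balanced classes the same
procedure recovers essentially all planted features.

## Determinism and tie-breaking

All randomness flows through R's RNG seeded from `mcfs_params(seed = )`;
identical parameters give bit-identical rankings, cutoffs, and graphs.
Within a tree, split thresholds are midpoints of consecutive distinct sorted
values; equal-gain splits resolve to the feature earlier in lexicographic ID
order, then to the smaller threshold. Nodes stop splitting when pure, below
`min_split = 5` samples, or when no split has positive gain.

# The experiment designs

## Main experiment

`main_experiment()` mirrors the four-run design: one selection on the joined
three-omics table restricted to samples complete across all layers (which
captures cross-omics interactions), plus one selection per omic on all
samples carrying that omic (which rescues features that would fall under the
relevance threshold inside a larger feature set). Per omic it reports the
joined-run set, the individual-run set, their intersection, and their union
— the union being the omic's final significant set — and validates the union
by training random-forest and SVM classifiers on the complete samples and
scoring weighted accuracy on the held-out (incomplete) samples only. The
random forest is bagged from the package's own trees (bootstrap rows plus a
random feature subspace per tree); the SVM is delegated to a standard radial
implementation with default hyperparameters, which are logged.

## Mass per-target regression experiments

`mass_experiments()` runs one regression-mode MCFS-ID experiment per target
mRNA with miRNAs (or same-chromosome methylation sites) as predictors. Each
target's significant set is then scored by 5-fold cross-validation of a
single regression tree; the mean held-out Pearson correlation gates targets
at 0.8 into the "well-predicted" group, and `aggregate_mass()` accumulates
`freq`, `sum_ri`, and `mean_ri = sum_ri / freq` per predictor over
well-predicted targets. The fold count (5) is a design decision; the gate is
the conventional 0.8.

A known limitation: a single regression tree is a piecewise-constant
approximator, so its cross-validated Pearson correlation sits well below the
latent predictor-target correlation when the signal is a smooth combination
of several continuous drivers; targets clear the 0.8 gate mainly when their
drivers carry a strong group (tissue) contrast that one or two splits can
capture. The acceptance script reports the achieved `mass_mean_cv_pearson`
alongside planted-driver recovery so this gap is visible rather than hidden.

# Methylation genomics

Coordinates are 0-based half-open (BED convention) throughout; `GRanges`
objects carry intervals internally.

* **CpG context.** Islands are annotated intervals; shores are their 2000-bp
  flanks, shelves the next 2000 bp, open sea everything beyond; overlapping
  flanks resolve by precedence island > shore > shelf > open sea.
* **Gene context.** Promoters are TSS ± 2000 bp, strand-aware; precedence
  promoter > gene body > intergenic; promoter and intergenic sites pair with
  the nearest TSS, ties broken lexicographically by gene ID.
* **Fold-change orientation.** For methylation,
  `log2FC = log2(mean beta normal / mean beta cancer)` with pseudocount
  `1e-6`; `log2FC <= -1` labels a site hyper-methylated in cancer,
  `>= 1` hypo-methylated, otherwise medium. For expression the orientation
  is `log2(cancer / normal)`, so "down-expressed in cancer" reads naturally
  as `log2FC <= -0.5`. Both conventions are stated in output because the two
  orientations are easy to confuse.
* **Differential testing.** Shapiro–Wilk normality is recorded per feature
  and group; the two-sided Wilcoxon rank-sum test compares groups and
  Benjamini–Hochberg FDR is applied across features. Region enrichment of
  DMS contexts against the array background uses 2×2 chi-squared tests with
  Bonferroni correction over the regions tested.
* **Chromatin-state enrichment.** The package draws `n_draws = 1000`
  size-matched site sets without replacement from the background panel (a
  draw models an alternative panel selection), and reports
  `log2(observed % / mean random %)` per state with empirical p-values
  `(1 + #extreme draws) / (1 + n_draws)` — never exactly zero. Empirical
  p-values on small site sets are conservative because state counts are
  discrete; the calibration tests use set sizes (about 5% of the panel)
  where this discreteness keeps per-state false-positive rates at or below
  nominal.
* **Cis correlation.** Gene–site pairs on the same chromosome within
  ±1 Mbp of the TSS are screened by Spearman correlation with BH-FDR;
  pairs with `|rho| >= 0.6` and `q <= 0.05` are significant.
* **Survival.** Each site is screened by a two-group log-rank test on the
  median split of its beta-values (ties to the low group); the bootstrap
  null redraws random site panels and counts sites with `p < alpha` per
  round.

# Motif analysis

PWM probabilities are floored at `1e-4` and columns renormalized before
log-odds so scores stay finite. Scan p-values are exact: per-position
log-odds contributions are discretized on a 1e-3-bit grid and convolved
position-wise into the full score distribution under the background — for
small widths this coincides with enumeration over all $4^w$ words, which is
how the tests check it. Both strands are scanned (reverse-complement PWM);
methylation-adjusted scoring is not attempted. Motif enrichment compares the
mean best-hit score of the foreground windows (41 bp around each DMS,
clipped at chromosome ends) against size-matched resamples of background
windows; the statistic and its resampling null are package design decisions
documented here because the upstream tools name no statistic. Hits are
intersected with DMS positions in genomic coordinates, so clipped windows
cannot shift the intersection.

PWM similarity is the best ungapped local alignment of columns (both
orientations, minimum overlap 4) scored by the sum of per-column Pearson
correlations of base probabilities and normalized by overlap length;
distance `1 - similarity` feeds a deterministic UPGMA (average-linkage)
agglomeration whose merge heights are half the merge distance and whose ties
resolve lexicographically. Pairwise alignment stands in for the iterative
multiple-alignment refinement of the original clustering tool; multiple
alignment of PWMs is out of scope.

# Description clustering

Documents are tokenized to lowercase unigrams plus adjacent-pair bigrams
(stopwords and tokens of length ≤ 2 removed first; a fixed stopword list
ships with the package so results are reproducible). `tf` is the term count
normalized by document length and `idf = ln(N/df)` without smoothing, so a
term present in every document weighs exactly zero — deliberate, because
cluster keywords should be discriminative. Clustering is average-linkage on
`1 - cosine` cut at a user-chosen `k` (a silhouette-based suggestion is
available); keyword scores are within-cluster minus between-cluster mean
weights. The cluster count, n-gram policy, and stopword list are declared
package decisions.

# Regulatory models

Down-expressed miRNAs (`log2FC <= -0.5`) are screened against their mapped
mRNA targets by Spearman correlation (keep `rho <= -0.2`, BH `q <= 0.05`).
The TF+DMS experiment is a single classification MCFS-ID run on concatenated
TF expressions and DMS beta-values over samples carrying both layers.
Per-target ordinary least squares models use the target's own predictor set
plus a 0/1 tissue indicator; "adjusted p" is read as BH-FDR across the
model family, and best-fitted means adjusted `p <= 0.05` with `R^2 > 0.5`.
The tissue ablation refits without the indicator (not coefficient zeroing)
and reports the Pearson correlation of fitted versus observed expression for
both fits without asserting an ordering. Edges are emitted only for
best-fitted models: TF → DMS → target, plus miRNA → target from the screen.

# The synthetic study

`generate_cohort()` draws log-normal expression (feature values $2^z$ with
Gaussian $z$) and Beta-distributed methylation with a common concentration
parameter (default 20 — realistic beta-value dispersion without a free
parameter per site). Informative features shift the cancer group by
`effect_size` standard deviations on the log scale (half up, half down);
informative methylation sites separate their group means symmetrically
around 0.5 by `beta_shift` (default `0.15 * effect_size`), half
hyper-methylated in cancer and half hypo, consistent with the fold-change
labeling convention above. Default cohort composition is 100 cancer and 20
normal samples — the imbalance of the emulated study at reduced scale — with
one third of samples complete across all three layers and the rest missing
at least one (they form the held-out validation material). Regulated mRNA
targets are noisy linear combinations of miRNA drivers drawn from the full
panel, so targets of differentially expressed drivers inherit the tissue
contrast the way the study's well-predicted genes do; noise is tuned so the
latent signal-target correlation matches `regulatory_r`.

The genome fixture emits random chromosome sequences with non-overlapping
gene and CpG-island tracks, an 8-state chromatin tiling that covers each
chromosome exactly once, and unique coordinates for every methylation site.
`plant_motifs()` writes a high-scoring word sampled from a PWM into the
sequence so that the site falls inside the planted word and the word inside
the 41-bp window. Survival times are exponential with the hazard multiplied
per high-methylation effect site and independent exponential censoring.

What the generator does **not** emulate: TCGA batch structure, tumor subtype
heterogeneity, array probe chemistry, spatial autocorrelation of
methylation, or realistic linkage between tracks. Passing the planted-truth
tests therefore shows that the algorithms do what they claim on data with
known structure, not that the biological conclusions of any particular
cohort would replicate. The distributional forms are stand-ins, not an
inference about TCGA.

# Problem sizes used by the tests

The test suite and acceptance script run the full-scale recovery study at
120 samples with 2020 features per omic and the paper-style selection
settings (`m = 200`, `mode = 2`, 20 cutoff permutations); null-calibration
runs use a 60-sample, 400-site cohort over 20 label permutations; the mass
experiments use 30 regulated targets against 100 miRNA predictors;
chromatin-state calibration uses a 2000-site panel with 100-site draws and
1000-draw nulls; survival power and size use 100 replicates of 200 samples.
These sizes were chosen so each property is measured with sensible Monte
Carlo error on a desktop machine.

# Known limitations

* The permutation cutoff is a family-wise max statistic and is conservative
  for sets of mutually redundant informative features, particularly under
  strong class imbalance (see above).
* Single-tree cross-validation understates the predictability of smooth
  multi-driver signals; the 0.8 well-predicted gate is realistic only for
  targets with strong group structure.
* Empirical resampling p-values have resolution `1/(1 + n_draws)` and
  discrete ties; they are conservative, never anti-conservative.
* The survival screen is a two-group log-rank on a median split; no
  multivariate survival modeling is attempted.
* No genome-build conversion, array normalization, or external-database
  lookups are included; annotation tracks are package inputs.
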